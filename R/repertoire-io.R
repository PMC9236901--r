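## Reading, validation, filtering and normalization of rearrangement tables.
##
## The canonical in-memory form is a tibble with one row per unique
## rearrangement: sample_id, patient_id, compartment, locus, v_family,
## j_family, cdr3_nt, frame (in/out/stop), templates, dna_mass_ug.

.airr_required <- c("junction", "v_call", "j_call", "productive", "duplicate_count")

#' Column map for the immunoSEQ-like dialect
#'
#' Maps canonical field names to the column names used by an immunoSEQ-style
#' export. Pass an edited copy to [read_rearrangements()] to accommodate
#' local dialect variants.
#'
#' @return Named character vector (canonical name -> file column name).
#' @export
immunoseq_column_map <- function() {
  c(cdr3_nt = "nucleotide", v_family = "vFamilyName", j_family = "jFamilyName",
    frame = "sequenceStatus", templates = "templates")
}

#' Read a rearrangement table
#'
#' Parses an AIRR-C rearrangement TSV or an immunoSEQ-like TSV into the
#' canonical schema. Unparseable rows (CDR3 with characters outside ACGT,
#' missing CDR3, negative template counts) are rejected with row-numbered
#' diagnostics in a warning.
#'
#' @param path TSV file.
#' @param dialect `"airr"` (columns junction, v_call, j_call, productive /
#'   vj_in_frame / stop_codon, duplicate_count) or `"immunoseq_like"`.
#' @param col_map Column map for the immunoSEQ-like dialect; defaults to
#'   [immunoseq_column_map()].
#' @param patient_id,compartment,dna_mass_ug Sample metadata used when the
#'   file does not carry it; `dna_mass_ug` defaults to 3 micrograms (with a
#'   warning) when absent, the customary input mass for bulk gDNA TCR-seq.
#'
#' @return Canonical rearrangement tibble.
#' @export
read_rearrangements <- function(path, dialect = c("airr", "immunoseq_like"),
                                col_map = immunoseq_column_map(),
                                patient_id = NULL, compartment = NULL,
                                dna_mass_ug = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "tcrdens_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))

  if (dialect == "airr") {
    missing_cols <- setdiff(.airr_required, names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf("missing mandatory AIRR column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "tcrdens_format_error")
    }
    parse_flag <- function(x) toupper(x) %in% c("T", "TRUE")
    frame <- rep("out", nrow(raw))
    if ("vj_in_frame" %in% names(raw)) frame[parse_flag(raw$vj_in_frame)] <- "in"
    else frame[parse_flag(raw$productive)] <- "in"
    if ("stop_codon" %in% names(raw)) frame[parse_flag(raw$stop_codon)] <- "stop"
    strip_allele <- function(x) sub("\\*.*$", "", x)
    tab <- tibble(
      sample_id = if ("sample_id" %in% names(raw)) raw$sample_id else
        rep(sub("\\.(airr\\.)?tsv$", "", basename(path)), nrow(raw)),
      patient_id = if ("patient_id" %in% names(raw)) raw$patient_id else
        rep(patient_id %||% NA_character_, nrow(raw)),
      compartment = if ("compartment" %in% names(raw)) raw$compartment else
        rep(compartment %||% NA_character_, nrow(raw)),
      locus = if ("locus" %in% names(raw)) raw$locus else
        locus_token(strip_allele(raw$v_call)),
      v_family = strip_allele(raw$v_call),
      j_family = strip_allele(raw$j_call),
      cdr3_nt = raw$junction,
      frame = frame,
      templates = suppressWarnings(as.integer(raw$duplicate_count)),
      dna_mass_ug = if ("dna_mass_ug" %in% names(raw))
        suppressWarnings(as.numeric(raw$dna_mass_ug)) else
        rep(NA_real_, nrow(raw))
    )
  } else {
    missing_cols <- setdiff(unname(col_map), names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf("missing mandatory column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "tcrdens_format_error")
    }
    frame_map <- c(IN = "in", OUT = "out", STOP = "stop")
    v_family <- raw[[col_map[["v_family"]]]]
    tab <- tibble(
      sample_id = rep(sub("\\.(airr\\.)?tsv$", "", basename(path)), nrow(raw)),
      patient_id = rep(patient_id %||% NA_character_, nrow(raw)),
      compartment = rep(compartment %||% NA_character_, nrow(raw)),
      locus = locus_token(v_family),
      v_family = v_family,
      j_family = raw[[col_map[["j_family"]]]],
      cdr3_nt = raw[[col_map[["cdr3_nt"]]]],
      frame = unname(frame_map[toupper(raw[[col_map[["frame"]]]])]),
      templates = suppressWarnings(as.integer(raw[[col_map[["templates"]]]])),
      dna_mass_ug = rep(NA_real_, nrow(raw))
    )
  }

  ## Row-level validation with row-numbered diagnostics.
  bad_cdr3 <- is.na(tab$cdr3_nt) | grepl("[^ACGT]", tab$cdr3_nt)
  bad_templates <- is.na(tab$templates) | tab$templates < 0
  bad_frame <- is.na(tab$frame) | !tab$frame %in% c("in", "out", "stop")
  bad <- bad_cdr3 | bad_templates | bad_frame
  if (any(bad)) {
    warn(sprintf("rejected %d unparseable row(s): %s", sum(bad),
                 paste(utils::head(which(bad), 20), collapse = ", ")))
    tab <- tab[!bad, ]
  }
  if (nrow(tab) == 0L) {
    warn(sprintf("no parseable rearrangement rows in %s", path))
  }

  if (!is.null(patient_id)) tab$patient_id <- patient_id
  if (!is.null(compartment)) tab$compartment <- compartment
  if (!is.null(dna_mass_ug)) {
    tab$dna_mass_ug <- dna_mass_ug
  } else if (all(is.na(tab$dna_mass_ug))) {
    warn("dna_mass_ug not supplied or recorded; defaulting to 3 ug")
    tab$dna_mass_ug <- 3
  }
  tab
}

#' Filter rearrangements for in-frame, locus-consistent V-J joins
#'
#' Retains exactly the rows with `frame == "in"` whose V and J families come
#' from the same locus (TRA with TRA, TRD with TRD), judged on the leading
#' locus token of the family names. Rows with stop codons count as not
#' in-frame. Row order is preserved and the input is not modified.
#'
#' @param table Canonical rearrangement tibble.
#' @return Filtered tibble (possibly empty).
#' @export
filter_rearrangements <- function(table) {
  if (nrow(table) == 0L) return(table)
  v_loc <- locus_token(table$v_family)
  j_loc <- locus_token(table$j_family)
  keep <- table$frame == "in" & v_loc == j_loc & v_loc %in% c("TRA", "TRD")
  table[keep, , drop = FALSE]
}

.summary_classes <- c("total_T", "TRA", "TRD", "TRDV1", "TRDV2")

#' Normalize template counts to cells per microgram of input gDNA
#'
#' For each sample and lineage class (total T, TRA, TRD, TRDV1, TRDV2),
#' computes `counts_per_ug = sum(templates) / dna_mass_ug` and the number of
#' unique clones (distinct CDR3 nucleotide sequences; duplicate CDR3 rows
#' within a class are aggregated so clones are never double-counted).
#' Classes are selected by V-family: TRDV1/TRDV2 by exact V family, TRA/TRD
#' by the leading locus token; apply [filter_rearrangements()] first.
#'
#' @param table Filtered canonical rearrangement tibble (one or more samples).
#' @return Tibble with columns `sample_id`, `patient_id`, `compartment`,
#'   `class`, `templates`, `counts_per_ug`, `unique_clones`.
#' @export
normalize_counts <- function(table) {
  if (nrow(table) > 0 &&
      (any(is.na(table$dna_mass_ug)) || any(table$dna_mass_ug <= 0))) {
    abort("dna_mass_ug must be positive for every row",
          class = "tcrdens_invalid_mass")
  }
  one_sample <- function(tab) {
    v_loc <- locus_token(tab$v_family)
    class_rows <- list(
      total_T = rep(TRUE, nrow(tab)),
      TRA = v_loc == "TRA",
      TRD = v_loc == "TRD",
      TRDV1 = tab$v_family == "TRDV1",
      TRDV2 = tab$v_family == "TRDV2"
    )
    mass <- tab$dna_mass_ug[1]
    out <- lapply(.summary_classes, function(cl) {
      rows <- tab[class_rows[[cl]], ]
      agg <- tapply(rows$templates, rows$cdr3_nt, sum)
      tibble(
        sample_id = tab$sample_id[1], patient_id = tab$patient_id[1],
        compartment = tab$compartment[1], class = cl,
        templates = sum(rows$templates),
        counts_per_ug = sum(rows$templates) / mass,
        unique_clones = length(agg)
      )
    })
    dplyr::bind_rows(out)
  }
  if (nrow(table) == 0L) {
    return(tibble(
      sample_id = character(), patient_id = character(),
      compartment = character(), class = character(), templates = numeric(),
      counts_per_ug = numeric(), unique_clones = integer()
    ))
  }
  dplyr::bind_rows(lapply(split(table, table$sample_id), one_sample))
}

#' Write a rearrangement table as an AIRR-C TSV
#'
#' Writes the canonical columns in AIRR order (sequence_id, locus, v_call,
#' j_call, junction, vj_in_frame, stop_codon, productive, duplicate_count)
#' plus extension columns (sample_id, patient_id, compartment, dna_mass_ug)
#' so that [read_rearrangements()] round-trips the table exactly.
#'
#' @param table Canonical rearrangement tibble (one sample).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_airr <- function(table, path) {
  flag <- function(x) ifelse(x, "T", "F")
  out <- tibble(
    sequence_id = if (nrow(table)) paste0(table$sample_id, "-", seq_len(nrow(table))) else character(),
    locus = table$locus,
    v_call = table$v_family,
    j_call = table$j_family,
    junction = table$cdr3_nt,
    vj_in_frame = flag(table$frame == "in"),
    stop_codon = flag(table$frame == "stop"),
    productive = flag(table$frame == "in"),
    duplicate_count = table$templates,
    sample_id = table$sample_id,
    patient_id = table$patient_id,
    compartment = table$compartment,
    dna_mass_ug = table$dna_mass_ug
  )
  tryCatch(
    readr::write_tsv(out, path),
    error = function(e) abort(sprintf("cannot write %s: %s", path,
                                      conditionMessage(e)),
                              class = "tcrdens_io_error")
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
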