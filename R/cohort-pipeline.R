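## End-to-end orchestration: simulate or ingest a cohort, filter and
## normalize repertoires, derive subset densities from gating trees, compute
## clone sharing and diversity, and run median-split survival associations.
## Partial failures (for example a patient without flow data) are logged and
## excluded per-analysis, never imputed.

#' Default subset definitions
#'
#' Each subset names the repertoire lineage class supplying the absolute
#' density and the ordered gating chain whose proportions multiply onto it.
#' CD4/CD8 proportions are taken relative to the CD3+ TCRgd- parent and
#' applied to the TRA density; Vd1/Vd2 chains are applied to the TRDV1/TRDV2
#' densities. T_RM is CD103+, T_EM is CD45RA-CD27-.
#'
#' @return Named list of `list(lineage, chain)` definitions.
#' @export
default_subsets <- function() {
  gd <- "CD3/TCRgdpos"; ab <- "CD3/TCRgdneg"
  em <- "CD45RAneg_CD27neg"
  list(
    Vd1_TRM = list(lineage = "TRDV1", chain = paste0(gd, "/Vd1/CD103pos")),
    Vd1_TEM = list(lineage = "TRDV1", chain = paste0(gd, "/Vd1/", em)),
    Vd2_TRM = list(lineage = "TRDV2", chain = paste0(gd, "/Vd2/CD103pos")),
    Vd2_TEM = list(lineage = "TRDV2", chain = paste0(gd, "/Vd2/", em)),
    CD4_TRM = list(lineage = "TRA",
                   chain = c(paste0(ab, "/CD4pos"), paste0(ab, "/CD4pos/CD103pos"))),
    CD4_TEM = list(lineage = "TRA",
                   chain = c(paste0(ab, "/CD4pos"), paste0(ab, "/CD4pos/", em))),
    CD8_TRM = list(lineage = "TRA",
                   chain = c(paste0(ab, "/CD8pos"), paste0(ab, "/CD8pos/CD103pos"))),
    CD8_TEM = list(lineage = "TRA",
                   chain = c(paste0(ab, "/CD8pos"), paste0(ab, "/CD8pos/", em)))
  )
}

#' Default biomarkers tested against relapse-free survival
#'
#' Effector-memory densities in tumors, tissue-resident-memory densities in
#' nontumor tissue, the tumor-minus-tissue deltas of the Vd1 subsets, and
#' the paired-compartment sharing proportions.
#'
#' @return Character vector of biomarker ids (`compartment:subset`,
#'   `delta:subset` or `sharing:chain`).
#' @export
default_biomarkers <- function() {
  c(paste0("tumor:", c("Vd1_TEM", "Vd2_TEM", "CD4_TEM", "CD8_TEM")),
    paste0("nontumor_tissue:", c("Vd1_TRM", "Vd2_TRM", "CD4_TRM", "CD8_TRM")),
    "delta:Vd1_TEM", "delta:Vd1_TRM",
    "sharing:TRDV1", "sharing:TRA")
}

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read a cohort directory written by [write_cohort()]).
#' @param cohort_config A [cohort_config()] (simulate mode).
#' @param input_dir Cohort directory (ingest mode).
#' @param subsets Named subset definitions; see [default_subsets()].
#' @param biomarkers Biomarker ids; see [default_biomarkers()].
#' @param alpha Significance level in (0, 1).
#' @param seed Seed recorded in the report (simulate mode reseeds the
#'   generator config with it).
#' @return List of class `tcrdens_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            cohort_config = tcrdens::cohort_config(),
                            input_dir = NULL,
                            subsets = default_subsets(),
                            biomarkers = default_biomarkers(),
                            alpha = 0.05,
                            seed = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, cohort_config = cohort_config,
              input_dir = input_dir, subsets = subsets,
              biomarkers = biomarkers, alpha = alpha,
              seed = seed %||% (if (mode == "simulate") cohort_config$seed else 0L))
  class(cfg) <- "tcrdens_pipeline_config"
  cfg
}

validate_pipeline_config <- function(config, gate_paths) {
  bad <- character()
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    bad <- c(bad, "alpha must be in (0, 1)")
  }
  for (nm in names(config$subsets)) {
    def <- config$subsets[[nm]]
    if (!def$lineage %in% .summary_classes) {
      bad <- c(bad, sprintf("subset '%s' references unknown lineage class '%s'",
                            nm, def$lineage))
    }
    missing_paths <- setdiff(def$chain, gate_paths)
    if (length(missing_paths) > 0) {
      bad <- c(bad, sprintf("subset '%s' references undefined gate path(s): %s",
                            nm, paste(missing_paths, collapse = ", ")))
    }
  }
  for (bm in config$biomarkers) {
    parts <- strsplit(bm, ":", fixed = TRUE)[[1]]
    kind <- if (parts[1] %in% c("tumor", "nontumor_tissue")) "density" else parts[1]
    ok <- switch(kind,
      density = , delta = parts[2] %in% names(config$subsets),
      sharing = parts[2] %in% c("TRDV1", "TRDV2", "TRA", "TRD"),
      FALSE)
    if (!isTRUE(ok)) {
      bad <- c(bad, sprintf("biomarker '%s' does not reference a defined subset or metric", bm))
    }
  }
  if (length(bad) > 0) {
    abort(c("Invalid pipeline configuration:", bad),
          class = "tcrdens_validation_error")
  }
  invisible(config)
}

## Strip reader-added attributes and order rows canonically so simulate and
## ingest paths produce identical objects.
canonical_tbl <- function(df, order_by) {
  df <- as_tibble(lapply(df, function(col) { attributes(col) <- NULL; col }))
  if (nrow(df) > 0) df <- df[do.call(order, df[order_by]), ]
  df
}

canonicalize_cohort <- function(cohort) {
  cohort$rearrangements <- canonical_tbl(
    cohort$rearrangements,
    c("sample_id", "locus", "v_family", "cdr3_nt"))
  cohort$flow <- canonical_tbl(cohort$flow,
                               c("patient_id", "compartment", "gate_path"))
  cohort$survival <- canonical_tbl(cohort$survival, "patient_id")
  cohort$samples <- canonical_tbl(cohort$samples, "sample_id")
  cohort
}

#' Run the full analysis
#'
#' Deterministic composition of every stage: filter and normalize each
#' sample's rearrangements, build gating trees, map subset densities, flag
#' the reporting floor, compute compartment deltas, clone sharing (both
#' directions) and diversity, and run a median-split Gehan-Breslow-Wilcoxon
#' survival association per configured biomarker.
#'
#' @param config A [pipeline_config()].
#' @return List of class `tcrdens_report`: `summaries`, `densities`,
#'   `deltas`, `sharing`, `diversity` (tibbles), `survival_results` (one
#'   entry per biomarker: either a [biomarker_survival_analysis()] result or
#'   a skip record with the reason), `accounting` (n_input = n_analyzed +
#'   n_excluded per analysis), `log` (one record per exclusion, with
#'   reason), `metadata` (version, seed, content hash of the cohort).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "tcrdens_pipeline_config"))
  cohort <- switch(config$mode,
    simulate = generate_cohort(config$cohort_config),
    ingest = {
      if (is.null(config$input_dir)) {
        abort("ingest mode requires input_dir", class = "tcrdens_validation_error")
      }
      read_cohort(config$input_dir)
    })
  if (nrow(cohort$samples) == 0L) {
    abort("empty cohort", class = "tcrdens_validation_error")
  }
  cohort <- canonicalize_cohort(cohort)
  validate_pipeline_config(config, unique(cohort$flow$gate_path))

  log <- list()
  note <- function(unit, stage, reason) {
    log[[length(log) + 1L]] <<- tibble(unit = unit, stage = stage,
                                       reason = reason)
  }

  ## Filter + normalize per sample.
  filtered <- filter_rearrangements(cohort$rearrangements)
  n_removed <- nrow(cohort$rearrangements) - nrow(filtered)
  if (n_removed > 0) {
    note("cohort", "filter",
         sprintf("%d rearrangement row(s) removed (out-of-frame or cross-locus V-J join)",
                 n_removed))
  }
  summaries <- normalize_counts(filtered)
  summaries <- canonical_tbl(summaries, c("sample_id", "class"))

  ## Gating trees per (patient, compartment) present in the flow table.
  flow_split <- split(cohort$flow,
                      paste(cohort$flow$patient_id, cohort$flow$compartment,
                            sep = "|"))
  trees <- lapply(flow_split, build_gating_tree)

  ## Subset densities for every repertoire sample.
  dens <- list()
  for (sid in cohort$samples$sample_id) {
    meta <- cohort$samples[cohort$samples$sample_id == sid, ]
    tree_key <- paste(meta$patient_id, meta$compartment, sep = "|")
    smry <- summaries[summaries$sample_id == sid, ]
    ld <- lineage_density(smry)
    if (!tree_key %in% names(trees)) {
      note(sid, "densities", "no flow gating data for sample")
      for (nm in names(config$subsets)) {
        def <- config$subsets[[nm]]
        dens[[length(dens) + 1L]] <- tibble(
          patient_id = meta$patient_id, compartment = meta$compartment,
          subset = nm, cells_per_ug = NA_real_, below_floor = NA,
          lineage = def$lineage,
          lineage_cells_per_ug = unname(ld[def$lineage]),
          proportion_product = NA_real_, n_proportions = length(def$chain),
          valid = FALSE)
      }
      next
    }
    tree <- trees[[tree_key]]
    for (nm in names(config$subsets)) {
      def <- config$subsets[[nm]]
      chain <- lapply(def$chain, gate_proportion, tree = tree)
      row <- map_subset_density(unname(ld[def$lineage]), chain, subset = nm,
                                patient_id = meta$patient_id,
                                compartment = meta$compartment,
                                lineage = def$lineage)
      if (!row$valid) {
        note(sid, "densities",
             sprintf("subset '%s' undefined (parent gate below ten cells)", nm))
      }
      dens[[length(dens) + 1L]] <- row
    }
  }
  densities <- apply_reporting_floor(dplyr::bind_rows(dens))
  densities <- canonical_tbl(densities,
                             c("patient_id", "compartment", "subset"))
  deltas <- canonical_tbl(delta_densities(densities),
                          c("patient_id", "subset"))

  ## Clone sharing (tumor denominator + reverse) and diversity.
  sharing <- list(); divers <- list()
  chains <- c("TRDV1", "TRA")
  by_sample <- split(filtered, filtered$sample_id)
  for (pid in unique(cohort$samples$patient_id)) {
    ids <- cohort$samples[cohort$samples$patient_id == pid, ]
    tum_id <- ids$sample_id[ids$compartment == "tumor"]
    nt_id <- ids$sample_id[ids$compartment == "nontumor_tissue"]
    for (ch in chains) {
      tum_set <- if (length(tum_id) == 1 && tum_id %in% names(by_sample))
        unique_clones(by_sample[[tum_id]], ch) else NULL
      nt_set <- if (length(nt_id) == 1 && nt_id %in% names(by_sample))
        unique_clones(by_sample[[nt_id]], ch) else NULL
      if (is.null(tum_set) || is.null(nt_set)) {
        note(pid, "sharing", sprintf("missing compartment for chain %s", ch))
        next
      }
      sharing[[length(sharing) + 1L]] <- tibble(
        patient_id = pid, chain = ch,
        n_tumor_clones = length(tum_set$clones),
        n_nt_clones = length(nt_set$clones),
        n_shared = sum(names(tum_set$clones) %in% names(nt_set$clones)),
        sharing_proportion = sharing_proportion(tum_set, nt_set),
        reverse_proportion = sharing_proportion(nt_set, tum_set)
      )
    }
  }
  for (sid in names(by_sample)) {
    for (ch in chains) {
      cs <- unique_clones(by_sample[[sid]], ch)
      if (length(cs$clones) == 0L) {
        note(sid, "diversity", sprintf("no %s clones", ch))
        next
      }
      for (m in c("shannon", "pielou_evenness", "clonality", "gini", "simpson")) {
        divers[[length(divers) + 1L]] <- tibble(
          sample_id = sid, chain = ch, metric = m,
          value = diversity(cs, m))
      }
    }
  }
  empty_sharing <- tibble(patient_id = character(), chain = character(),
                          n_tumor_clones = integer(), n_nt_clones = integer(),
                          n_shared = integer(), sharing_proportion = numeric(),
                          reverse_proportion = numeric())
  sharing <- if (length(sharing)) canonical_tbl(dplyr::bind_rows(sharing),
                                                c("patient_id", "chain"))
             else empty_sharing
  diversity_tbl <- if (length(divers))
    canonical_tbl(dplyr::bind_rows(divers), c("sample_id", "chain", "metric"))
  else tibble(sample_id = character(), chain = character(),
              metric = character(), value = numeric())

  ## Survival associations.
  surv <- cohort$survival
  survival_results <- list()
  accounting <- list()
  for (bm in config$biomarkers) {
    parts <- strsplit(bm, ":", fixed = TRUE)[[1]]
    values <- switch(parts[1],
      tumor = ,
      nontumor_tissue = {
        d <- densities[densities$compartment == parts[1] &
                         densities$subset == parts[2], ]
        stats::setNames(d$cells_per_ug, d$patient_id)
      },
      delta = {
        d <- deltas[deltas$subset == parts[2], ]
        stats::setNames(d$delta_cells_per_ug, d$patient_id)
      },
      sharing = {
        d <- sharing[sharing$chain == parts[2], ]
        stats::setNames(d$sharing_proportion, d$patient_id)
      })
    rec <- surv
    rec$value <- unname(values[rec$patient_id])
    n_input <- nrow(rec)
    res <- tryCatch(
      biomarker_survival_analysis(rec, "value"),
      tcrdens_underpowered = function(e) {
        note(bm, "survival", conditionMessage(e))
        list(skipped = TRUE, reason = conditionMessage(e))
      })
    n_analyzed <- if (isTRUE(res$skipped)) 0L else res$n_low + res$n_high
    n_excl <- n_input - n_analyzed
    if (!isTRUE(res$skipped) && res$n_excluded > 0) {
      note(bm, "survival",
           sprintf("%d patient(s) excluded (missing biomarker or outcome)",
                   res$n_excluded))
    }
    accounting[[length(accounting) + 1L]] <- tibble(
      analysis = bm, n_input = n_input, n_analyzed = n_analyzed,
      n_excluded = n_excl)
    if (!isTRUE(res$skipped)) res$biomarker <- bm
    survival_results[[bm]] <- res
  }

  log_tbl <- if (length(log)) dplyr::bind_rows(log) else
    tibble(unit = character(), stage = character(), reason = character())

  report <- list(
    summaries = summaries,
    densities = densities,
    deltas = deltas,
    sharing = sharing,
    diversity = diversity_tbl,
    survival_results = survival_results,
    accounting = dplyr::bind_rows(accounting),
    log = log_tbl,
    metadata = list(
      package = "tcrdens",
      version = as.character(utils::packageVersion("tcrdens")),
      seed = config$seed,
      alpha = config$alpha,
      biomarkers = config$biomarkers,
      cohort_hash = rlang::hash(list(cohort$rearrangements, cohort$flow,
                                     cohort$survival, cohort$samples))
    )
  )
  class(report) <- "tcrdens_report"
  report
}

#' @export
print.tcrdens_report <- function(x, ...) {
  cat("<tcrdens_report>\n")
  cat("  samples:", length(unique(x$summaries$sample_id)), "\n")
  cat("  densities:", nrow(x$densities), "rows;",
      "sharing:", nrow(x$sharing), "rows\n")
  for (bm in names(x$survival_results)) {
    r <- x$survival_results[[bm]]
    if (isTRUE(r$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", bm, r$reason))
    } else {
      cat(sprintf("  %s: p = %.4g (n = %d/%d)\n", bm, r$test$p,
                  r$n_low, r$n_high))
    }
  }
  invisible(x)
}

#' Hash of an analysis report
#'
#' Content hash over every report table and result, for end-to-end
#' determinism checks: identical (config, seed) must give identical hashes.
#'
#' @param report A `tcrdens_report`.
#' @return Character hash.
#' @export
report_hash <- function(report) {
  rlang::hash(unclass(report))
}

#' Parameter-recovery experiment over a generator grid
#'
#' For each grid cell (overlap_rho, beta) and replicate, generates a cohort,
#' estimates the mean observed TRDV1 sharing proportion from the filtered
#' repertoires, and runs the median-split Gehan-Breslow-Wilcoxon test on the
#' true biomarker to record the rejection rate.
#'
#' @param grid Data frame with columns `overlap_rho` and `beta`.
#' @param replicates Replicates per cell (>= 1).
#' @param base_config Template [cohort_config()].
#' @param alpha Rejection level.
#' @param seed Master seed; every cell and replicate derives a child seed.
#' @return Tibble per cell: `overlap_rho`, `beta`, `replicates`,
#'   `mean_sharing`, `sd_sharing` (`NA` for a single replicate),
#'   `rejection_rate`, `seed`.
#' @export
parameter_recovery_experiment <- function(grid, replicates, base_config,
                                          alpha = 0.05, seed = 1L) {
  stopifnot(nrow(grid) >= 1L, replicates >= 1L)
  out <- list()
  for (ci in seq_len(nrow(grid))) {
    rho <- grid$overlap_rho[ci]
    beta <- grid$beta[ci]
    share_means <- numeric(replicates)
    reject <- logical(replicates)
    for (rep_i in seq_len(replicates)) {
      cfg <- base_config
      cfg$overlap_rho <- rho
      cfg$beta <- beta
      cfg$seed <- child_seed(seed, ci, rep_i)
      cohort <- generate_cohort(cfg)
      filtered <- filter_rearrangements(cohort$rearrangements)
      by_sample <- split(filtered, filtered$sample_id)
      shares <- vapply(unique(cohort$samples$patient_id), function(pid) {
        tum <- by_sample[[paste0(pid, "_tum")]]
        nt <- by_sample[[paste0(pid, "_nt")]]
        if (is.null(tum) || is.null(nt)) return(NA_real_)
        sharing_proportion(unique_clones(tum, "TRDV1"),
                           unique_clones(nt, "TRDV1"))
      }, numeric(1))
      share_means[rep_i] <- mean(shares, na.rm = TRUE)
      rec <- cohort$survival
      res <- tryCatch(biomarker_survival_analysis(rec, "biomarker"),
                      tcrdens_underpowered = function(e) NULL)
      reject[rep_i] <- !is.null(res) && res$test$p < alpha
    }
    out[[ci]] <- tibble(
      overlap_rho = rho, beta = beta, replicates = replicates,
      mean_sharing = mean(share_means),
      sd_sharing = if (replicates > 1) stats::sd(share_means) else NA_real_,
      rejection_rate = mean(reject),
      seed = child_seed(seed, ci, 0L)
    )
  }
  dplyr::bind_rows(out)
}
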