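## Synthetic cohort generator: paired tumor / nontumor-tissue repertoires with
## a controlled clone-overlap fraction, hierarchical flow gating counts
## consistent with the repertoire lineage composition, and relapse-free
## survival whose hazard depends log-linearly on a chosen subset density.
## Every stochastic choice is driven by counter-derived child seeds so any
## patient or stage can be regenerated in isolation.

#' Default per-compartment lineage Dirichlet concentrations
#'
#' Concentration vectors over the five modelled lineages (CD4, CD8, Vd1, Vd2,
#' other gamma-delta) for blood, nontumor tissue and tumor. Central values
#' emulate a cohort where gamma-delta cells are a small minority of T cells
#' (a few percent in tissue), Vd2 dominates the blood gamma-delta compartment
#' while Vd1 dominates tissue and tumor.
#'
#' @return Named list of named numeric vectors.
#' @export
default_lineage_dirichlet <- function() {
  list(
    blood           = c(CD4 = 174, CD8 = 99,  Vd1 = 1.5, Vd2 = 5.4, other = 0.9),
    nontumor_tissue = c(CD4 = 156, CD8 = 136, Vd1 = 4.4, Vd2 = 1.6, other = 2.1),
    tumor           = c(CD4 = 165, CD8 = 130, Vd1 = 3.1, Vd2 = 1.1, other = 0.9)
  )
}

#' Default per-compartment gate probabilities
#'
#' True CD103+ probabilities and CD45RA x CD27 quadrant probabilities per
#' lineage and compartment. Central values emulate strong CD103 (tissue
#' residency) enrichment of CD8 and Vd1 cells in tissue and especially tumor,
#' and a tumor shift of Vd1 cells toward the CD45RA-CD27- effector-memory
#' quadrant.
#'
#' @return Nested named list: compartment -> lineage -> list(cd103, quadrants).
#'   `quadrants` is a probability vector named T_EM, T_CM, naive_like, T_EMRA.
#' @export
default_gate_probs <- function() {
  q <- function(em, cm, nv, emra) {
    c(T_EM = em, T_CM = cm, naive_like = nv, T_EMRA = emra)
  }
  list(
    blood = list(
      CD4 = list(cd103 = 0.02, quadrants = q(0.20, 0.30, 0.45, 0.05)),
      CD8 = list(cd103 = 0.03, quadrants = q(0.25, 0.20, 0.35, 0.20)),
      Vd1 = list(cd103 = 0.02, quadrants = q(0.30, 0.15, 0.35, 0.20)),
      Vd2 = list(cd103 = 0.01, quadrants = q(0.45, 0.30, 0.20, 0.05))
    ),
    nontumor_tissue = list(
      CD4 = list(cd103 = 0.10,  quadrants = q(0.45, 0.30, 0.20, 0.05)),
      CD8 = list(cd103 = 0.353, quadrants = q(0.50, 0.15, 0.15, 0.20)),
      Vd1 = list(cd103 = 0.188, quadrants = q(0.40, 0.15, 0.25, 0.20)),
      Vd2 = list(cd103 = 0.05,  quadrants = q(0.45, 0.25, 0.20, 0.10))
    ),
    tumor = list(
      CD4 = list(cd103 = 0.07,  quadrants = q(0.50, 0.30, 0.15, 0.05)),
      CD8 = list(cd103 = 0.656, quadrants = q(0.55, 0.15, 0.10, 0.20)),
      Vd1 = list(cd103 = 0.666, quadrants = q(0.60, 0.12, 0.13, 0.15)),
      Vd2 = list(cd103 = 0.103, quadrants = q(0.50, 0.20, 0.15, 0.15))
    )
  )
}

#' Synthetic cohort configuration
#'
#' Assembles and validates all generator parameters. Defaults describe a
#' cohort of surgically resected patients with paired tumor / nontumor-tissue
#' sampling: 3 ug of input gDNA per sample, a clone-overlap fraction of 0.27
#' between tumor and tissue Vd1-bearing repertoires, a protective log-hazard
#' of -0.7 per standard deviation of the log nontumor-tissue Vd1 T_RM
#' density, and administrative censoring at 72 months.
#'
#' @param n_patients Number of patients.
#' @param n_clones_tissue Clone-pool size per patient and chain (TRA and TRD).
#' @param overlap_rho Probability in `[0, 1]` that a tumor clone slot keeps
#'   the identity of the corresponding tissue clone (rather than a novel one).
#' @param abundance_alpha Power-law exponent for clone abundance ranks
#'   (frequency of rank r proportional to `r^-alpha`); `alpha = 0` is flat.
#' @param depth_templates Templates sampled per repertoire.
#' @param dna_mass_ug Input gDNA mass recorded per sample (micrograms).
#' @param lineage_dirichlet Dirichlet concentration vector over
#'   `c("CD4","CD8","Vd1","Vd2","other")`, or a per-compartment list of such
#'   vectors. A single vector is broadcast to all compartments.
#' @param gate_probs Per-lineage true CD103 and CD45RA x CD27 quadrant
#'   probabilities, or a per-compartment list (see [default_gate_probs()]).
#' @param n_flow_cells CD3+ cells acquired per flow panel.
#' @param baseline_hazard Baseline event rate (events per time unit).
#' @param beta Log-hazard per 1 SD of the standardized `log1p` biomarker.
#' @param censor_max Upper bound of uniform administrative censoring.
#' @param out_of_frame_fraction Fraction of artifact out-of-frame rows added
#'   per table, relative to the number of well-formed rows.
#' @param cross_locus_fraction Fraction of artifact cross-locus V-J join rows
#'   added per table, relative to the number of well-formed rows.
#' @param survival_biomarker Subset density driving the hazard, written as
#'   `"compartment:subset"` (for example `"nontumor_tissue:Vd1_TRM"`).
#' @param seed Integer seed for the whole cohort.
#'
#' @return A validated list of class `tcrdens_config`.
#' @export
cohort_config <- function(n_patients = 40,
                          n_clones_tissue = 1000,
                          overlap_rho = 0.27,
                          abundance_alpha = 1.2,
                          depth_templates = 50000,
                          dna_mass_ug = 3,
                          lineage_dirichlet = default_lineage_dirichlet(),
                          gate_probs = default_gate_probs(),
                          n_flow_cells = 50000,
                          baseline_hazard = 0.012,
                          beta = -0.7,
                          censor_max = 72,
                          out_of_frame_fraction = 0.15,
                          cross_locus_fraction = 0.05,
                          survival_biomarker = "nontumor_tissue:Vd1_TRM",
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, n_clones_tissue = n_clones_tissue,
    overlap_rho = overlap_rho, abundance_alpha = abundance_alpha,
    depth_templates = depth_templates, dna_mass_ug = dna_mass_ug,
    lineage_dirichlet = broadcast_compartments(lineage_dirichlet),
    gate_probs = broadcast_compartments(gate_probs),
    n_flow_cells = n_flow_cells, baseline_hazard = baseline_hazard,
    beta = beta, censor_max = censor_max,
    out_of_frame_fraction = out_of_frame_fraction,
    cross_locus_fraction = cross_locus_fraction,
    survival_biomarker = survival_biomarker,
    seed = as.integer(seed)
  )
  class(cfg) <- "tcrdens_config"
  validate_cohort_config(cfg)
  cfg
}

## Accept either one value for all compartments or a per-compartment list.
broadcast_compartments <- function(x) {
  if (is.list(x) && all(.compartments %in% names(x))) {
    return(x[.compartments])
  }
  out <- stats::setNames(rep(list(x), length(.compartments)), .compartments)
  out
}

#' Validate a synthetic cohort configuration
#'
#' Checks every invariant (fractions in `[0, 1]`, strictly positive Dirichlet
#' concentrations, positive rates and masses, well-formed gate probability
#' tables) and aborts with the full list of violations.
#'
#' @param config A `tcrdens_config` (or plain list with the same fields).
#' @return The config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  bad <- character()
  chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)

  chk(is.numeric(config$n_patients) && length(config$n_patients) == 1L &&
        config$n_patients >= 0 && config$n_patients == floor(config$n_patients),
      "n_patients must be a non-negative integer")
  chk(is_count(config$n_clones_tissue), "n_clones_tissue must be a positive integer")
  chk(is_fraction(config$overlap_rho), "overlap_rho must be in [0, 1]")
  chk(is.numeric(config$abundance_alpha) && length(config$abundance_alpha) == 1L &&
        is.finite(config$abundance_alpha) && config$abundance_alpha >= 0,
      "abundance_alpha must be a non-negative real")
  chk(is.numeric(config$depth_templates) && length(config$depth_templates) == 1L &&
        config$depth_templates >= 0 &&
        config$depth_templates == floor(config$depth_templates),
      "depth_templates must be a non-negative integer")
  chk(is_positive_scalar(config$dna_mass_ug), "dna_mass_ug must be positive")
  chk(is_count(config$n_flow_cells), "n_flow_cells must be a positive integer")
  chk(is_positive_scalar(config$baseline_hazard), "baseline_hazard must be positive")
  chk(is.numeric(config$beta) && length(config$beta) == 1L && is.finite(config$beta),
      "beta must be a finite real")
  chk(is_positive_scalar(config$censor_max), "censor_max must be positive")
  chk(is_fraction(config$out_of_frame_fraction),
      "out_of_frame_fraction must be in [0, 1]")
  chk(is_fraction(config$cross_locus_fraction),
      "cross_locus_fraction must be in [0, 1]")

  for (comp in .compartments) {
    a <- config$lineage_dirichlet[[comp]]
    chk(is.numeric(a) && length(a) == length(.lineages) && all(a > 0) &&
          setequal(names(a), .lineages),
        sprintf("lineage_dirichlet[%s] must be strictly positive and named %s",
                comp, paste(.lineages, collapse = ", ")))
    gp <- config$gate_probs[[comp]]
    for (lin in c("CD4", "CD8", "Vd1", "Vd2")) {
      g <- gp[[lin]]
      chk(!is.null(g) && is_fraction(g$cd103),
          sprintf("gate_probs[%s][%s]$cd103 must be in [0, 1]", comp, lin))
      chk(!is.null(g) && is.numeric(g$quadrants) && length(g$quadrants) == 4L &&
            all(g$quadrants >= 0) && abs(sum(g$quadrants) - 1) <= 1e-9 &&
            setequal(names(g$quadrants), names(.quadrant_gates)),
          sprintf("gate_probs[%s][%s]$quadrants must be 4 probabilities summing to 1",
                  comp, lin))
    }
  }

  chk(is.character(config$survival_biomarker) &&
        grepl("^(nontumor_tissue|tumor):", config$survival_biomarker),
      "survival_biomarker must be 'compartment:subset' with compartment tumor or nontumor_tissue")

  if (length(bad) > 0) {
    abort(c("Invalid synthetic cohort configuration:", bad),
          class = "tcrdens_invalid_parameter")
  }
  invisible(config)
}

## In-frame CDR3 nucleotide lengths: 24-60 in multiples of 3.
.cdr3_lengths_in <- seq(24L, 60L, by = 3L)
## Out-of-frame artifact rows get lengths congruent to 1 mod 3.
.cdr3_lengths_out <- seq(25L, 58L, by = 3L)

.v_families <- list(
  TRA = paste0("TRAV", 1:41),
  TRD = c("TRDV1", "TRDV2", "TRDV3")
)
.j_families <- list(
  TRA = paste0("TRAJ", 1:61),
  TRD = paste0("TRDJ", 1:4)
)

#' Generate a clone pool with power-law rank abundances
#'
#' Draws `n_clones` distinct CDR3 nucleotide strings (alphabet ACGT, lengths
#' 24-60 in multiples of 3) with V and J families from a single locus and
#' true frequencies proportional to `rank^-abundance_alpha`.
#'
#' @param n_clones Pool size (positive integer).
#' @param abundance_alpha Non-negative power-law exponent; 0 gives a flat pool.
#' @param seed Integer seed.
#' @param locus `"TRD"` (default) or `"TRA"`.
#' @param v_family_probs Optional named sampling probabilities over the locus
#'   V families (for TRD: TRDV1, TRDV2, TRDV3).
#'
#' @return Tibble with columns `clone_id`, `cdr3_nt`, `v_family`, `j_family`,
#'   `locus`, `freq` (frequencies sum to 1).
#' @export
generate_clone_pool <- function(n_clones, abundance_alpha, seed,
                                locus = c("TRD", "TRA"),
                                v_family_probs = NULL) {
  locus <- match.arg(locus)
  if (!is_count(n_clones)) {
    abort("n_clones must be a positive integer", class = "tcrdens_invalid_parameter")
  }
  if (!is.numeric(abundance_alpha) || length(abundance_alpha) != 1L ||
      !is.finite(abundance_alpha) || abundance_alpha < 0) {
    abort("abundance_alpha must be a non-negative real",
          class = "tcrdens_invalid_parameter")
  }
  set.seed(seed)
  ranks <- seq_len(n_clones)
  w <- ranks^(-abundance_alpha)
  freq <- w / sum(w)

  cdr3 <- random_cdr3_distinct(n_clones, .cdr3_lengths_in)
  vf <- .v_families[[locus]]
  vp <- v_family_probs
  if (is.null(vp)) {
    vp <- rep(1 / length(vf), length(vf))
    names(vp) <- vf
  } else {
    stopifnot(all(names(vp) %in% vf), all(vp >= 0), sum(vp) > 0)
  }
  v_family <- sample(names(vp), n_clones, replace = TRUE, prob = vp)
  j_family <- sample(.j_families[[locus]], n_clones, replace = TRUE)

  tibble(
    clone_id = paste0(locus, "_c", ranks),
    cdr3_nt = cdr3, v_family = v_family, j_family = j_family,
    locus = locus, freq = freq
  )
}

## One rearrangement table (tibble) from a pool frequency vector.
sample_rearrangement_rows <- function(pool, freq, depth, sample_id, patient_id,
                                      compartment, dna_mass_ug) {
  counts <- as.integer(rmultinom(1, depth, freq))
  keep <- counts > 0L
  tibble(
    sample_id = sample_id, patient_id = patient_id, compartment = compartment,
    locus = pool$locus[keep], v_family = pool$v_family[keep],
    j_family = pool$j_family[keep], cdr3_nt = pool$cdr3_nt[keep],
    frame = "in", templates = counts[keep], dna_mass_ug = dna_mass_ug
  )
}

## Append artifact rows exercising the downstream filter: out-of-frame rows
## (CDR3 length = 1 mod 3, frame "out") and cross-locus V-J joins (in-frame
## but V and J from different loci). Template counts are resampled from the
## clean rows so artifacts look like ordinary rearrangements.
append_malformed_rows <- function(tab, out_of_frame_fraction,
                                  cross_locus_fraction, avoid) {
  n_clean <- nrow(tab)
  if (n_clean == 0L) {
    return(list(table = tab, n_out_of_frame = 0L, n_cross_locus = 0L))
  }
  n_oof <- as.integer(round(out_of_frame_fraction * n_clean))
  n_cross <- as.integer(round(cross_locus_fraction * n_clean))
  pick_templates <- function(n) sample(tab$templates, n, replace = TRUE)
  rows <- list()
  if (n_oof > 0L) {
    loc <- sample(c("TRA", "TRD"), n_oof, replace = TRUE, prob = c(0.8, 0.2))
    rows$oof <- tibble(
      sample_id = tab$sample_id[1], patient_id = tab$patient_id[1],
      compartment = tab$compartment[1], locus = loc,
      v_family = vapply(loc, function(l) sample(.v_families[[l]], 1), ""),
      j_family = vapply(loc, function(l) sample(.j_families[[l]], 1), ""),
      cdr3_nt = random_cdr3_distinct(n_oof, .cdr3_lengths_out, avoid = avoid),
      frame = "out", templates = pick_templates(n_oof),
      dna_mass_ug = tab$dna_mass_ug[1]
    )
    avoid <- c(avoid, rows$oof$cdr3_nt)
  }
  if (n_cross > 0L) {
    vloc <- sample(c("TRA", "TRD"), n_cross, replace = TRUE)
    jloc <- ifelse(vloc == "TRA", "TRD", "TRA")
    rows$cross <- tibble(
      sample_id = tab$sample_id[1], patient_id = tab$patient_id[1],
      compartment = tab$compartment[1], locus = vloc,
      v_family = vapply(vloc, function(l) sample(.v_families[[l]], 1), ""),
      j_family = vapply(jloc, function(l) sample(.j_families[[l]], 1), ""),
      cdr3_nt = random_cdr3_distinct(n_cross, .cdr3_lengths_in, avoid = avoid),
      frame = "in", templates = pick_templates(n_cross),
      dna_mass_ug = tab$dna_mass_ug[1]
    )
  }
  out <- dplyr::bind_rows(c(list(tab), rows))
  list(table = out, n_out_of_frame = n_oof, n_cross_locus = n_cross)
}

#' Generate paired nontumor-tissue and tumor rearrangement tables
#'
#' Tumor clone slots keep the identity of the corresponding tissue clone with
#' probability `overlap_rho` and are otherwise replaced by novel clones from
#' a disjoint CDR3 namespace (so `overlap_rho = 0` gives exactly zero
#' sharing). Template counts are multinomial at `depth_templates` per
#' compartment; the configured fractions of artifact out-of-frame and
#' cross-locus rows are appended so the filter stage has known work to do.
#'
#' @param pool Clone pool from [generate_clone_pool()] (or several pools
#'   bound together with a `freq` column summing to 1).
#' @param overlap_rho Tissue-identity probability in `[0, 1]`.
#' @param depth_templates Templates per repertoire; 0 yields empty tables
#'   with a warning.
#' @param dna_mass_ug Input gDNA mass recorded on both tables.
#' @param out_of_frame_fraction,cross_locus_fraction Artifact-row fractions
#'   relative to the number of well-formed rows.
#' @param seed Integer seed.
#' @param patient_id Identifier used in `sample_id`s.
#' @param tumor_freq Optional replacement frequency vector for the tumor
#'   compartment (same slot order as `pool`); defaults to `pool$freq`.
#'
#' @return List with elements `nontumor_tissue` and `tumor` (rearrangement
#'   tibbles) and `truth` (shared-slot flags, the tumor pool, and per-table
#'   artifact row counts).
#' @export
generate_paired_repertoires <- function(pool, overlap_rho, depth_templates,
                                        dna_mass_ug,
                                        out_of_frame_fraction = 0,
                                        cross_locus_fraction = 0,
                                        seed = 1L, patient_id = "P1",
                                        tumor_freq = NULL) {
  if (is.null(pool) || nrow(pool) == 0L) {
    abort("clone pool is empty", class = "tcrdens_invalid_parameter")
  }
  if (!is_fraction(overlap_rho)) {
    abort("overlap_rho must be in [0, 1]", class = "tcrdens_invalid_parameter")
  }
  if (!is_positive_scalar(dna_mass_ug)) {
    abort("dna_mass_ug must be positive", class = "tcrdens_invalid_mass")
  }
  set.seed(seed)
  if (is.null(tumor_freq)) tumor_freq <- pool$freq

  ## Tumor pool: shared identity with probability rho, else a novel clone of
  ## the same locus and V family drawn from a disjoint CDR3 namespace.
  n <- nrow(pool)
  shared <- runif(n) < overlap_rho
  tumor_pool <- pool
  n_novel <- sum(!shared)
  if (n_novel > 0L) {
    novel_cdr3 <- random_cdr3_distinct(n_novel, .cdr3_lengths_in,
                                       avoid = pool$cdr3_nt)
    tumor_pool$cdr3_nt[!shared] <- novel_cdr3
    tumor_pool$j_family[!shared] <- vapply(
      tumor_pool$locus[!shared],
      function(l) sample(.j_families[[l]], 1), ""
    )
    tumor_pool$clone_id[!shared] <- paste0(tumor_pool$clone_id[!shared], "_novel")
  }
  tumor_pool$freq <- tumor_freq / sum(tumor_freq)

  empty_tab <- function(sample_id, compartment) {
    tibble(
      sample_id = character(), patient_id = character(),
      compartment = character(), locus = character(), v_family = character(),
      j_family = character(), cdr3_nt = character(), frame = character(),
      templates = integer(), dna_mass_ug = numeric()
    )
  }

  ids <- paste0(patient_id, c("_nt", "_tum"))
  if (depth_templates == 0L) {
    warn("depth_templates is 0; returning empty rearrangement tables")
    return(list(
      nontumor_tissue = empty_tab(ids[1], "nontumor_tissue"),
      tumor = empty_tab(ids[2], "tumor"),
      truth = list(shared = shared, tumor_pool = tumor_pool,
                   malformed = tibble(sample_id = ids,
                                      n_clean_rows = c(0L, 0L),
                                      n_out_of_frame = c(0L, 0L),
                                      n_cross_locus = c(0L, 0L)))
    ))
  }

  nt_tab <- sample_rearrangement_rows(pool, pool$freq, depth_templates,
                                      ids[1], patient_id, "nontumor_tissue",
                                      dna_mass_ug)
  tum_tab <- sample_rearrangement_rows(tumor_pool, tumor_pool$freq,
                                       depth_templates, ids[2], patient_id,
                                       "tumor", dna_mass_ug)
  avoid <- c(pool$cdr3_nt, tumor_pool$cdr3_nt)
  nt_m <- append_malformed_rows(nt_tab, out_of_frame_fraction,
                                cross_locus_fraction, avoid)
  tum_m <- append_malformed_rows(tum_tab, out_of_frame_fraction,
                                 cross_locus_fraction, avoid)

  list(
    nontumor_tissue = nt_m$table,
    tumor = tum_m$table,
    truth = list(
      shared = shared,
      tumor_pool = tumor_pool,
      malformed = tibble(
        sample_id = ids,
        n_clean_rows = c(nrow(nt_tab), nrow(tum_tab)),
        n_out_of_frame = c(nt_m$n_out_of_frame, tum_m$n_out_of_frame),
        n_cross_locus = c(nt_m$n_cross_locus, tum_m$n_cross_locus)
      )
    )
  )
}

#' Generate hierarchical flow-cytometry gate counts
#'
#' Samples a gating hierarchy CD3 -> TCRgd+/- -> lineages -> CD103 and
#' CD45RA x CD27 quadrants by a multinomial cascade, so child counts never
#' exceed parent counts. Counts (not proportions) are recorded.
#'
#' @param true_lineage_fractions Named fractions over
#'   `c("CD4","CD8","Vd1","Vd2","other")` summing to 1 (tolerance 1e-9);
#'   "other" counts toward the TCRgd+ gate but gets no child gates.
#' @param gate_probs Per-lineage list with elements `cd103` and `quadrants`
#'   (one compartment's entry of [default_gate_probs()]).
#' @param n_flow_cells CD3+ cells acquired (>= 1).
#' @param seed Integer seed.
#' @param patient_id,compartment Sample identity recorded on each record.
#'
#' @return Tibble of gating-count records: `patient_id`, `compartment`,
#'   `gate_path` (slash-separated), `cell_count`.
#' @export
generate_flow_table <- function(true_lineage_fractions, gate_probs,
                                n_flow_cells, seed = 1L,
                                patient_id = "P1", compartment = "tumor") {
  f <- true_lineage_fractions
  if (!is.numeric(f) || length(f) != length(.lineages) ||
      !setequal(names(f), .lineages) || any(f < 0) ||
      abs(sum(f) - 1) > 1e-9) {
    abort("true_lineage_fractions must be named CD4/CD8/Vd1/Vd2/other, non-negative and sum to 1",
          class = "tcrdens_invalid_parameter")
  }
  if (!is_count(n_flow_cells)) {
    abort("n_flow_cells must be a positive integer",
          class = "tcrdens_invalid_parameter")
  }
  set.seed(seed)
  f <- f[.lineages]
  counts <- as.integer(rmultinom(1, n_flow_cells, f))
  names(counts) <- .lineages

  lineage_paths <- c(
    CD4 = "CD3/TCRgdneg/CD4pos", CD8 = "CD3/TCRgdneg/CD8pos",
    Vd1 = "CD3/TCRgdpos/Vd1", Vd2 = "CD3/TCRgdpos/Vd2"
  )
  paths <- c("CD3", "CD3/TCRgdpos", "CD3/TCRgdneg")
  vals <- c(n_flow_cells,
            counts["Vd1"] + counts["Vd2"] + counts["other"],
            counts["CD4"] + counts["CD8"])
  for (lin in c("CD4", "CD8", "Vd1", "Vd2")) {
    m <- counts[[lin]]
    base <- lineage_paths[[lin]]
    gp <- gate_probs[[lin]]
    cd103 <- rbinom(1, m, gp$cd103)
    quad <- as.integer(rmultinom(1, m, gp$quadrants[names(.quadrant_gates)]))
    paths <- c(paths, base, paste0(base, "/CD103pos"),
               paste0(base, "/", .quadrant_gates))
    vals <- c(vals, m, cd103, quad)
  }
  tibble(patient_id = patient_id, compartment = compartment,
         gate_path = paths, cell_count = as.integer(vals))
}

#' Generate censored relapse-free survival records
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta * z)` where `z` is the standardized `log1p`
#' biomarker; censoring times are uniform on `(0, censor_max)`; the observed
#' time is the minimum and the event flag marks `event time <= censor time`.
#'
#' @param biomarker_values Non-negative biomarker per patient.
#' @param baseline_hazard Positive baseline event rate.
#' @param beta Log-hazard per 1 SD of the standardized log biomarker.
#' @param censor_max Positive uniform censoring bound.
#' @param seed Integer seed.
#' @param patient_ids Optional identifiers (default P1..Pn).
#'
#' @return Tibble with `patient_id`, `time`, `event` (logical), `biomarker`.
#' @export
generate_survival <- function(biomarker_values, baseline_hazard, beta,
                              censor_max, seed = 1L, patient_ids = NULL) {
  if (!is_positive_scalar(baseline_hazard)) {
    abort("baseline_hazard must be positive", class = "tcrdens_invalid_parameter")
  }
  if (!is_positive_scalar(censor_max)) {
    abort("censor_max must be positive", class = "tcrdens_invalid_parameter")
  }
  n <- length(biomarker_values)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(n))
  set.seed(seed)
  z <- log1p(biomarker_values)
  sdz <- stats::sd(z)
  z <- if (n > 1 && is.finite(sdz) && sdz > 0) (z - mean(z)) / sdz else rep(0, n)
  rate <- baseline_hazard * exp(beta * z)
  t_event <- rexp(n, rate = rate)
  t_cens <- runif(n, 0, censor_max)
  tibble(
    patient_id = patient_ids,
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    biomarker = as.numeric(biomarker_values)
  )
}

## True post-filter density (cells per ug) for one subset, from realized
## per-class frequency mass and the configured gate probabilities.
truth_subset_density <- function(class_mass, gate_probs_comp, subset,
                                 depth, dna_mass_ug) {
  parts <- strsplit(subset, "_", fixed = TRUE)[[1]]
  lin <- parts[1]
  kind <- parts[2]
  class_key <- c(CD4 = "CD4", CD8 = "CD8", Vd1 = "TRDV1", Vd2 = "TRDV2")[[lin]]
  mass <- class_mass[[class_key]]
  gp <- gate_probs_comp[[lin]]
  p <- switch(kind,
    TRM = gp$cd103,
    TEM = unname(gp$quadrants["T_EM"]),
    abort(sprintf("unknown subset kind in '%s'", subset),
          class = "tcrdens_invalid_parameter"))
  mass * depth / dna_mass_ug * p
}

#' Generate a complete synthetic cohort with ground truth
#'
#' For every patient: paired nontumor-tissue and tumor rearrangement tables
#' covering the TRA and TRD chains, gating-count tables for blood, tissue and
#' tumor, and one survival record whose hazard depends on the true value of
#' the configured biomarker subset density. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `tcrdens_cohort` with elements `rearrangements`,
#'   `flow`, `survival`, `samples` (sample metadata), `config` and `truth`
#'   (the ground-truth state: lineage fractions, per-class frequency mass and
#'   true densities, true biomarker values, artifact-row counts, shared-clone
#'   flags and per-compartment frequency vectors).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n_pat <- config$n_patients
  seed <- config$seed

  rearr <- list(); flow <- list(); samples <- list()
  truth_frac <- list(); truth_mass <- list(); truth_malformed <- list()
  truth_shared <- list(); truth_freq <- list()
  biomarker <- numeric(n_pat)
  bm_parts <- strsplit(config$survival_biomarker, ":", fixed = TRUE)[[1]]
  bm_comp <- bm_parts[1]; bm_subset <- bm_parts[2]

  patient_ids <- if (n_pat > 0) sprintf("P%03d", seq_len(n_pat)) else character()

  for (i in seq_len(n_pat)) {
    pid <- patient_ids[i]
    ## Per-compartment lineage fractions.
    fr <- list()
    for (ci in seq_along(.compartments)) {
      comp <- .compartments[ci]
      set.seed(child_seed(seed, i, 10L, ci))
      fr[[comp]] <- rdirichlet1(config$lineage_dirichlet[[comp]])[.lineages]
    }

    ## Tissue pools (one per chain), gamma-delta V families matched to the
    ## tissue lineage mix; combined frequency vector weighted by lineages.
    f_nt <- fr[["nontumor_tissue"]]
    f_tum <- fr[["tumor"]]
    gd_probs <- f_nt[c("Vd1", "Vd2", "other")]
    names(gd_probs) <- c("TRDV1", "TRDV2", "TRDV3")
    pool_a <- generate_clone_pool(config$n_clones_tissue,
                                  config$abundance_alpha,
                                  child_seed(seed, i, 20L), locus = "TRA")
    pool_d <- generate_clone_pool(config$n_clones_tissue,
                                  config$abundance_alpha,
                                  child_seed(seed, i, 21L), locus = "TRD",
                                  v_family_probs = gd_probs / sum(gd_probs))
    pool <- dplyr::bind_rows(pool_a, pool_d)
    w_ab_nt <- unname(f_nt["CD4"] + f_nt["CD8"])
    w_gd_nt <- 1 - w_ab_nt
    pool$freq <- c(pool_a$freq * w_ab_nt, pool_d$freq * w_gd_nt)

    ## Tumor frequencies: same slots, reweighted to the tumor lineage mix so
    ## tumor flow tables and tumor repertoires agree in composition.
    fam <- ifelse(pool$locus == "TRA", "TRA",
                  c(TRDV1 = "Vd1", TRDV2 = "Vd2", TRDV3 = "other")[pool$v_family])
    target <- c(TRA = unname(f_tum["CD4"] + f_tum["CD8"]),
                Vd1 = unname(f_tum["Vd1"]), Vd2 = unname(f_tum["Vd2"]),
                other = unname(f_tum["other"]))
    fam_mass <- tapply(pool$freq, fam, sum)
    missing_fam <- setdiff(names(target)[target > 0], names(fam_mass))
    if (length(missing_fam) > 0) {
      ## A tiny pool can lack a gamma-delta family; fold its weight into TRA.
      target["TRA"] <- target["TRA"] + sum(target[missing_fam])
      target[missing_fam] <- 0
    }
    tumor_freq <- pool$freq / fam_mass[fam] * target[fam]
    tumor_freq[is.na(tumor_freq)] <- 0
    tumor_freq <- as.numeric(tumor_freq / sum(tumor_freq))

    rep_out <- generate_paired_repertoires(
      pool, config$overlap_rho, config$depth_templates, config$dna_mass_ug,
      config$out_of_frame_fraction, config$cross_locus_fraction,
      seed = child_seed(seed, i, 30L), patient_id = pid,
      tumor_freq = tumor_freq
    )
    rearr[[length(rearr) + 1L]] <- rep_out$nontumor_tissue
    rearr[[length(rearr) + 1L]] <- rep_out$tumor
    truth_malformed[[pid]] <- rep_out$truth$malformed
    truth_shared[[pid]] <- rep_out$truth$shared
    truth_freq[[pid]] <- list(nontumor_tissue = pool$freq, tumor = tumor_freq)

    ## Realized per-class frequency mass and true densities per compartment.
    freqs <- list(nontumor_tissue = pool$freq, tumor = tumor_freq)
    for (comp in c("nontumor_tissue", "tumor")) {
      fq <- freqs[[comp]]
      cm <- c(
        total_T = 1,
        TRA = sum(fq[pool$locus == "TRA"]),
        TRD = sum(fq[pool$locus == "TRD"]),
        TRDV1 = sum(fq[pool$v_family == "TRDV1"]),
        TRDV2 = sum(fq[pool$v_family == "TRDV2"]),
        CD4 = unname(fr[[comp]]["CD4"]),
        CD8 = unname(fr[[comp]]["CD8"])
      )
      truth_mass[[length(truth_mass) + 1L]] <- tibble(
        patient_id = pid, compartment = comp, class = names(cm),
        freq_mass = as.numeric(cm),
        expected_templates = as.numeric(cm) * config$depth_templates,
        true_density = as.numeric(cm) * config$depth_templates / config$dna_mass_ug
      )
    }

    ## Flow tables for all three compartments.
    for (ci in seq_along(.compartments)) {
      comp <- .compartments[ci]
      flow[[length(flow) + 1L]] <- generate_flow_table(
        fr[[comp]], config$gate_probs[[comp]], config$n_flow_cells,
        seed = child_seed(seed, i, 40L, ci), patient_id = pid,
        compartment = comp
      )
    }

    for (ci in seq_along(.compartments)) {
      comp <- .compartments[ci]
      truth_frac[[length(truth_frac) + 1L]] <- tibble(
        patient_id = pid, compartment = comp, lineage = .lineages,
        fraction = as.numeric(fr[[comp]][.lineages])
      )
    }

    samples[[length(samples) + 1L]] <- tibble(
      sample_id = paste0(pid, c("_nt", "_tum")), patient_id = pid,
      compartment = c("nontumor_tissue", "tumor"),
      dna_mass_ug = config$dna_mass_ug
    )

    cm_bm <- truth_mass[[length(truth_mass) - (bm_comp == "nontumor_tissue")]]
    cm_bm <- cm_bm[cm_bm$compartment == bm_comp, ]
    mass_lookup <- stats::setNames(cm_bm$freq_mass, cm_bm$class)
    biomarker[i] <- truth_subset_density(
      as.list(mass_lookup), config$gate_probs[[bm_comp]], bm_subset,
      config$depth_templates, config$dna_mass_ug
    )
  }

  surv <- if (n_pat > 0) {
    generate_survival(biomarker, config$baseline_hazard, config$beta,
                      config$censor_max, seed = child_seed(seed, 0L, 50L),
                      patient_ids = patient_ids)
  } else {
    tibble(patient_id = character(), time = numeric(), event = logical(),
           biomarker = numeric())
  }

  empty_rearr <- tibble(
    sample_id = character(), patient_id = character(), compartment = character(),
    locus = character(), v_family = character(), j_family = character(),
    cdr3_nt = character(), frame = character(), templates = integer(),
    dna_mass_ug = numeric()
  )
  cohort <- list(
    rearrangements = if (length(rearr)) dplyr::bind_rows(rearr) else empty_rearr,
    flow = if (length(flow)) dplyr::bind_rows(flow) else
      tibble(patient_id = character(), compartment = character(),
             gate_path = character(), cell_count = integer()),
    survival = surv,
    samples = if (length(samples)) dplyr::bind_rows(samples) else
      tibble(sample_id = character(), patient_id = character(),
             compartment = character(), dna_mass_ug = numeric()),
    config = config,
    truth = list(
      overlap_rho = config$overlap_rho,
      beta = config$beta,
      lineage_fractions = if (length(truth_frac)) dplyr::bind_rows(truth_frac) else
        tibble(patient_id = character(), compartment = character(),
               lineage = character(), fraction = numeric()),
      class_mass = if (length(truth_mass)) dplyr::bind_rows(truth_mass) else
        tibble(patient_id = character(), compartment = character(),
               class = character(), freq_mass = numeric(),
               expected_templates = numeric(), true_density = numeric()),
      gate_probs = config$gate_probs,
      biomarker = tibble(patient_id = patient_ids,
                         name = config$survival_biomarker,
                         true_value = biomarker),
      malformed = if (length(truth_malformed)) dplyr::bind_rows(truth_malformed) else
        tibble(sample_id = character(), n_clean_rows = integer(),
               n_out_of_frame = integer(), n_cross_locus = integer()),
      shared = truth_shared,
      frequencies = truth_freq
    )
  )
  class(cohort) <- "tcrdens_cohort"
  cohort
}

#' @export
print.tcrdens_cohort <- function(x, ...) {
  cat("<tcrdens_cohort>", x$config$n_patients, "patients,",
      nrow(x$rearrangements), "rearrangement rows,",
      nrow(x$flow), "gating records\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes one AIRR rearrangement TSV per sample, a gating-counts TSV, a
#' survival TSV, a sample-metadata TSV and the ground truth as JSON.
#'
#' @param cohort A `tcrdens_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in cohort$samples$sample_id) {
    tab <- cohort$rearrangements[cohort$rearrangements$sample_id == sid, ]
    write_airr(tab, file.path(dir, paste0(sid, ".airr.tsv")))
  }
  readr::write_tsv(cohort$flow, file.path(dir, "gating_counts.tsv"))
  readr::write_tsv(cohort$survival, file.path(dir, "survival.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  jsonlite::write_json(
    list(
      overlap_rho = cohort$truth$overlap_rho,
      beta = cohort$truth$beta,
      lineage_fractions = cohort$truth$lineage_fractions,
      class_mass = cohort$truth$class_mass,
      biomarker = cohort$truth$biomarker,
      malformed = cohort$truth$malformed
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `samples.tsv`, per-sample AIRR TSVs,
#'   `gating_counts.tsv`, `survival.tsv` and optionally `truth.json`.
#' @return A list of class `tcrdens_cohort` (config is not reconstructed;
#'   truth tables are restored from JSON when present).
#' @export
read_cohort <- function(dir) {
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             show_col_types = FALSE)
  rearr <- dplyr::bind_rows(lapply(samples$sample_id, function(sid) {
    read_rearrangements(file.path(dir, paste0(sid, ".airr.tsv")),
                        dialect = "airr")
  }))
  flow <- readr::read_tsv(file.path(dir, "gating_counts.tsv"),
                          show_col_types = FALSE,
                          col_types = readr::cols(
                            patient_id = readr::col_character(),
                            compartment = readr::col_character(),
                            gate_path = readr::col_character(),
                            cell_count = readr::col_integer()
                          ))
  surv <- readr::read_tsv(file.path(dir, "survival.tsv"),
                          show_col_types = FALSE,
                          col_types = readr::cols(
                            patient_id = readr::col_character(),
                            time = readr::col_double(),
                            event = readr::col_logical(),
                            biomarker = readr::col_double()
                          ))
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  cohort <- list(rearrangements = rearr, flow = flow, survival = surv,
                 samples = samples, config = NULL, truth = truth)
  class(cohort) <- "tcrdens_cohort"
  cohort
}
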