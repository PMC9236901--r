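## Mapping flow gate proportions onto per-microgram repertoire counts to
## derive absolute subset densities, plus compartment deltas and the
## visualization floor flag.

#' Lineage densities from a repertoire summary
#'
#' Passes through the per-microgram densities of the repertoire lineage
#' classes (total_T, TRA, TRD, TRDV1, TRDV2) for one sample.
#'
#' @param summary One sample's rows of a [normalize_counts()] result.
#' @return Named numeric vector of cells per microgram; zero for classes
#'   absent from the summary.
#' @export
lineage_density <- function(summary) {
  out <- stats::setNames(rep(0, length(.summary_classes)), .summary_classes)
  if (nrow(summary) > 0) {
    stopifnot(length(unique(summary$sample_id)) == 1L)
    out[summary$class] <- summary$counts_per_ug
  }
  out
}

#' Map a chain of gate proportions onto a lineage density
#'
#' The absolute subset density is the lineage density multiplied by the
#' product of the proportion values along the gating chain (for example
#' `p(CD103+ | Vd1)` applied to the TRDV1 density, or
#' `p(CD4 | CD3+gd-) * p(CD45RA-CD27- | CD4)` applied to the TRA density).
#' If any proportion in the chain is undefined (parent gate below ten
#' cells), the density is missing — never imputed.
#'
#' @param lineage_cells_per_ug Lineage density (cells per microgram).
#' @param proportion_chain List of [gate_proportion()] objects, ordered from
#'   lineage to subset.
#' @param subset Subset label (e.g. `"Vd1_TRM"`).
#' @param patient_id,compartment Sample identity.
#' @param lineage Lineage class the density came from (provenance).
#' @return One-row tibble: `patient_id`, `compartment`, `subset`,
#'   `cells_per_ug` (or `NA`), `below_floor` (`NA` until
#'   [apply_reporting_floor()]), and provenance columns `lineage`,
#'   `lineage_cells_per_ug`, `proportion_product`, `n_proportions`, `valid`.
#' @export
map_subset_density <- function(lineage_cells_per_ug, proportion_chain, subset,
                               patient_id = NA_character_,
                               compartment = NA_character_,
                               lineage = NA_character_) {
  if (inherits(proportion_chain, "gate_proportion")) {
    proportion_chain <- list(proportion_chain)
  }
  stopifnot(length(proportion_chain) >= 1L)
  vals <- vapply(proportion_chain, function(p) {
    stopifnot(inherits(p, "gate_proportion"))
    if (p$valid && (p$value < 0 || p$value > 1)) {
      abort("gate proportion outside [0, 1]",
            class = "tcrdens_invalid_proportion")
    }
    if (p$valid) p$value else NA_real_
  }, numeric(1))
  all_valid <- !anyNA(vals)
  prod_val <- if (all_valid) prod(vals) else NA_real_
  tibble(
    patient_id = patient_id, compartment = compartment, subset = subset,
    cells_per_ug = if (all_valid) lineage_cells_per_ug * prod_val else NA_real_,
    below_floor = NA,
    lineage = lineage,
    lineage_cells_per_ug = lineage_cells_per_ug,
    proportion_product = prod_val,
    n_proportions = length(vals),
    valid = all_valid
  )
}

#' Flag densities below the reporting floor
#'
#' Densities below the floor (default 1 cell per microgram, exclusive) are
#' flagged `below_floor = TRUE`. The flag affects plotting only; values are
#' retained unchanged and statistics use unfloored values.
#'
#' @param densities Tibble with a `cells_per_ug` column.
#' @param floor Non-negative floor (cells per microgram).
#' @return `densities` with `below_floor` filled in (`NA` where the density
#'   is missing).
#' @export
apply_reporting_floor <- function(densities, floor = 1) {
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) || floor < 0) {
    abort("floor must be a non-negative number",
          class = "tcrdens_invalid_parameter")
  }
  densities$below_floor <- ifelse(is.na(densities$cells_per_ug), NA,
                                  densities$cells_per_ug < floor)
  densities
}

#' Tumor-minus-tissue density delta
#'
#' `delta = tumor - nontumor tissue` for one patient and subset; missing if
#' either side is missing.
#'
#' @param tumor_density,nt_density One-row density tibbles from
#'   [map_subset_density()] for the same patient and subset.
#' @return Signed numeric (or `NA`).
#' @export
delta_density <- function(tumor_density, nt_density) {
  stopifnot(nrow(tumor_density) == 1L, nrow(nt_density) == 1L)
  if (!identical(tumor_density$subset, nt_density$subset)) {
    abort(sprintf("subset mismatch: '%s' vs '%s'",
                  tumor_density$subset, nt_density$subset),
          class = "tcrdens_invalid_parameter")
  }
  if (!identical(tumor_density$patient_id, nt_density$patient_id)) {
    abort("patient mismatch in delta_density",
          class = "tcrdens_invalid_parameter")
  }
  tumor_density$cells_per_ug - nt_density$cells_per_ug
}

#' Per-patient density deltas for a whole density table
#'
#' @param densities Density tibble covering tumor and nontumor_tissue rows.
#' @return Tibble `patient_id`, `subset`, `delta_cells_per_ug` (tumor minus
#'   tissue; `NA` when either side is missing).
#' @export
delta_densities <- function(densities) {
  wide <- tidyr::pivot_wider(
    densities[, c("patient_id", "compartment", "subset", "cells_per_ug")],
    names_from = "compartment", values_from = "cells_per_ug"
  )
  if (!"tumor" %in% names(wide)) wide$tumor <- NA_real_
  if (!"nontumor_tissue" %in% names(wide)) wide$nontumor_tissue <- NA_real_
  tibble(
    patient_id = wide$patient_id, subset = wide$subset,
    delta_cells_per_ug = wide$tumor - wide$nontumor_tissue
  )
}
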