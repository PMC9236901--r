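## Clone-level statistics: unique-clone sets keyed by CDR3 nucleotide
## sequence, paired-compartment sharing and repertoire diversity.

#' Unique clones of a chain restriction
#'
#' Distinct CDR3 nucleotide sequences among rows matching the restriction,
#' with template counts aggregated per clone. Clones are keyed by CDR3
#' nucleotide sequence alone; V-restricted subsets (e.g. TRDV1) are selected
#' before keying.
#'
#' @param table Filtered canonical rearrangement tibble (one sample).
#' @param chain_restriction `"TRDV1"` or `"TRDV2"` (exact V family),
#'   `"TRA"` or `"TRD"` (locus, judged on the V-family prefix).
#' @return Object of class `clone_set`: `chain`, and `clones` — a named
#'   numeric vector of aggregated template counts keyed by CDR3.
#' @export
unique_clones <- function(table, chain_restriction) {
  rows <- switch(chain_restriction,
    TRDV1 = ,
    TRDV2 = table[table$v_family == chain_restriction, , drop = FALSE],
    TRA = ,
    TRD = table[locus_token(table$v_family) == chain_restriction, , drop = FALSE],
    abort(sprintf("unknown chain restriction '%s'", chain_restriction),
          class = "tcrdens_invalid_parameter")
  )
  clones <- if (nrow(rows) > 0) {
    agg <- tapply(rows$templates, rows$cdr3_nt, sum)
    stats::setNames(as.numeric(agg), names(agg))
  } else {
    stats::setNames(numeric(), character())
  }
  structure(list(chain = chain_restriction, clones = clones),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("<clone_set>", x$chain, "-", length(x$clones), "unique clones,",
      sum(x$clones), "templates\n")
  invisible(x)
}

#' Proportion of tumor clones also found in paired tissue
#'
#' `|tumor intersect NT| / |tumor|` on presence/absence of unique CDR3
#' nucleotide sequences (no abundance weighting). Undefined (`NA`) when the
#' tumor set is empty. Note the statistic is directional: the tumor unique
#' clone count is the denominator; swap the arguments for the reverse
#' direction.
#'
#' @param tumor_set,nt_set [unique_clones()] results with the same chain
#'   restriction.
#' @return Fraction in `[0, 1]`, or `NA` if the tumor set is empty.
#' @export
sharing_proportion <- function(tumor_set, nt_set) {
  stopifnot(inherits(tumor_set, "clone_set"), inherits(nt_set, "clone_set"))
  if (!identical(tumor_set$chain, nt_set$chain)) {
    abort(sprintf("chain restriction mismatch: '%s' vs '%s'",
                  tumor_set$chain, nt_set$chain),
          class = "tcrdens_invalid_parameter")
  }
  n_tumor <- length(tumor_set$clones)
  if (n_tumor == 0L) return(NA_real_)
  sum(names(tumor_set$clones) %in% names(nt_set$clones)) / n_tumor
}

#' Repertoire diversity and clonal-focusing metrics
#'
#' Clone frequencies are template counts normalized to sum to 1. Metrics:
#' Shannon entropy `H = -sum(p * log2(p))` in bits; Pielou evenness
#' `H / log2(K)`; clonality `1 - H / log2(K)` (the clonal-focusing statistic:
#' 0 for a uniform repertoire, 1 for a single dominant clone); Gini
#' coefficient of the frequency distribution; and the Gini-Simpson index
#' `1 - sum(p^2)`. For a single clone, evenness is 0 and clonality 1 by
#' convention (the `log2(1) = 0` limit is guarded).
#'
#' @param clone_set A non-empty [unique_clones()] result.
#' @param metric One of `"shannon"`, `"pielou_evenness"`, `"clonality"`,
#'   `"gini"`, `"simpson"`.
#' @return Non-negative real.
#' @export
diversity <- function(clone_set,
                      metric = c("shannon", "pielou_evenness", "clonality",
                                 "gini", "simpson")) {
  metric <- match.arg(metric)
  stopifnot(inherits(clone_set, "clone_set"))
  counts <- clone_set$clones
  if (length(counts) == 0L) {
    abort("diversity is undefined for an empty clone set",
          class = "tcrdens_undefined_diversity")
  }
  if (any(counts <= 0)) {
    abort("clone template counts must be positive",
          class = "tcrdens_invalid_parameter")
  }
  p <- counts / sum(counts)
  K <- length(p)
  shannon <- -sum(p * log2(p))
  switch(metric,
    shannon = shannon,
    pielou_evenness = if (K == 1L) 0 else shannon / log2(K),
    clonality = if (K == 1L) 1 else 1 - shannon / log2(K),
    gini = {
      ps <- sort(p)
      (2 * sum(seq_len(K) * ps) - (K + 1)) / K
    },
    simpson = 1 - sum(p^2)
  )
}
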