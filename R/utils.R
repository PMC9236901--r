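## Internal helpers: deterministic seed fan-out, random CDR3 strings,
## Dirichlet draws and small validators.

## Counter-based child seed: mixes a parent seed with integer counters so any
## patient/stage subset of a cohort can be regenerated in isolation. All
## arithmetic stays below 2^53 so doubles are exact; result is a valid
## 32-bit seed.
child_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) * 16807 + 1) %% 2147483647
  }
  as.integer(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_positive_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

## n random CDR3 nucleotide strings with the given per-string lengths.
random_nt <- function(n, lengths) {
  out <- character(n)
  for (L in unique(lengths)) {
    idx <- which(lengths == L)
    m <- matrix(sample(c("A", "C", "G", "T"), length(idx) * L, replace = TRUE),
                nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out
}

## n distinct random CDR3s, lengths resampled from `lengths_pool`, avoiding
## collisions with `avoid` (a disjoint namespace is guaranteed by redrawing).
random_cdr3_distinct <- function(n, lengths_pool, avoid = character()) {
  if (n == 0L) return(character())
  draw_lengths <- function(k) lengths_pool[sample.int(length(lengths_pool), k, replace = TRUE)]
  out <- random_nt(n, draw_lengths(n))
  bad <- duplicated(out) | out %in% avoid
  while (any(bad)) {
    out[bad] <- random_nt(sum(bad), draw_lengths(sum(bad)))
    bad <- duplicated(out) | out %in% avoid
  }
  out
}

rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha > 0))
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  out <- g / sum(g)
  names(out) <- names(alpha)
  out
}

## Locus token ("TRA"/"TRD") from a V or J family name.
locus_token <- function(x) substr(x, 1L, 3L)
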