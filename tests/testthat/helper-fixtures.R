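## Shared fixtures and independent oracles, all built in code.

## A small canonical rearrangement table with known composition.
make_rearr_table <- function(rows, sample_id = "S1", patient_id = "P1",
                             compartment = "tumor", dna_mass_ug = 3) {
  defaults <- tibble::tibble(
    sample_id = sample_id, patient_id = patient_id, compartment = compartment,
    locus = "TRD", v_family = "TRDV1", j_family = "TRDJ1",
    cdr3_nt = NA_character_, frame = "in", templates = 1L,
    dna_mass_ug = dna_mass_ug
  )
  out <- lapply(rows, function(r) {
    row <- defaults
    for (nm in names(r)) row[[nm]] <- r[[nm]]
    row
  })
  dplyr::bind_rows(out)
}

## Flow count records for one sample from explicit path counts.
make_flow_records <- function(counts, patient_id = "P1", compartment = "tumor") {
  tibble::tibble(patient_id = patient_id, compartment = compartment,
                 gate_path = names(counts),
                 cell_count = as.integer(unname(counts)))
}

## Monte-Carlo label-permutation oracle for the Gehan-Breslow-Wilcoxon
## score: samples random group assignments (independent of the package's
## complete-enumeration path) and returns the two-sided tail of |U|.
gbw_mc_oracle <- function(a, b, n_mc = 1e5, seed = 1) {
  set.seed(seed)
  time <- c(a$time, b$time)
  event <- as.logical(c(a$event, b$event))
  na <- nrow(a); n <- length(time)
  ev <- sort(unique(time[event]))
  R <- outer(time, ev, ">=") * 1
  D <- outer(time, ev, "==") * event
  n_i <- colSums(R); d_i <- colSums(D); w <- n_i
  obs_in_a <- rep(c(TRUE, FALSE), c(na, n - na))
  U_obs <- sum(w * (colSums(D[obs_in_a, , drop = FALSE]) -
                      d_i * colSums(R[obs_in_a, , drop = FALSE]) / n_i))
  idx <- vapply(seq_len(n_mc), function(i) sample.int(n, na), integer(na))
  G <- matrix(0, n_mc, n)
  G[cbind(rep(seq_len(n_mc), each = na), as.vector(idx))] <- 1
  U_all <- as.numeric((G %*% D) %*% w - (G %*% R) %*% (w * d_i / n_i))
  mean(abs(U_all) >= abs(U_obs) - 1e-9)
}

## Decode permutation number k (0-based) to a permutation of 1..n via the
## factorial number system — an enumeration route independent of the
## package's recursive generator.
lehmer_permutation <- function(k, n) {
  avail <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    d <- k %/% f
    k <- k %% f
    out[i] <- avail[d + 1]
    avail <- avail[-(d + 1)]
  }
  out
}

## Naive direct-summation diversity oracle.
naive_diversity <- function(counts, metric) {
  p <- counts / sum(counts)
  K <- length(p)
  H <- 0
  for (pi in p) H <- H - pi * log2(pi)
  switch(metric,
    shannon = H,
    pielou_evenness = if (K == 1) 0 else H / log2(K),
    clonality = if (K == 1) 1 else 1 - H / log2(K),
    gini = {
      s <- 0
      for (i in seq_len(K)) for (j in seq_len(K)) s <- s + abs(p[i] - p[j])
      s / (2 * K)
    },
    simpson = 1 - sum(p^2)
  )
}

## Default-sized survival fixture.
surv_tbl <- function(time, event) tibble::tibble(time = time, event = event)
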