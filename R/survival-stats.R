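## From-scratch censored-outcome and nonparametric statistics:
## Kaplan-Meier product-limit estimation, the Gehan-Breslow-Wilcoxon
## weighted rank test (with a complete-enumeration exact option for small
## groups), median-split biomarker analysis, Mann-Whitney U,
## Kruskal-Wallis with Dunn's post-hoc test, and Spearman correlation.
##
## Conventions (documented defaults): censored subjects at an event time
## remain at risk for the event at that time; ties at the biomarker median
## go to the low group.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times <= t of (1 - d_i / n_i)`. Censored-only
#' data give `S == 1` everywhere.
#'
#' @param records Tibble with positive `time` and logical `event`.
#' @return Object of class `km_curve`: tibble `steps` with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`), plus the sample size `n`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1L)
  if (any(is.na(records$time)) || any(records$time <= 0)) {
    abort("survival times must be positive", class = "tcrdens_invalid_parameter")
  }
  time <- records$time
  event <- as.logical(records$event)
  ev_times <- sort(unique(time[event]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(ev_times, function(t) sum(time == t & !event), numeric(1))
  survival <- cumprod(1 - n_event / n_risk)
  structure(
    list(steps = tibble(time = ev_times, n_risk = n_risk, n_event = n_event,
                        n_censor = n_censor, survival = survival),
         n = length(time)),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step function starting at 1.
#'
#' @param curve A [km_estimate()] result.
#' @param times Evaluation times.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  steps <- curve$steps
  vapply(times, function(t) {
    idx <- which(steps$time <= t)
    if (length(idx) == 0L) 1 else steps$survival[max(idx)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", x$n, "subjects,", nrow(x$steps), "event times\n")
  invisible(x)
}

## Shared event-table machinery: distinct event times with totals and
## group-a members at risk / dying, plus the weighted score U and its
## hypergeometric variance V. weights: n_i (Gehan) or 1 (log-rank).
gbw_event_table <- function(time, event, in_a, weight_type) {
  ev_times <- sort(unique(time[event]))
  k <- length(ev_times)
  n_i <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  d_i <- vapply(ev_times, function(t) sum(time == t & event), numeric(1))
  n_ai <- vapply(ev_times, function(t) sum(time >= t & in_a), numeric(1))
  d_ai <- vapply(ev_times, function(t) sum(time == t & event & in_a), numeric(1))
  w_i <- if (weight_type == "gehan") n_i else rep(1, k)
  tibble(time = ev_times, n_risk = n_i, n_risk_a = n_ai,
         n_event = d_i, n_event_a = d_ai, weight = w_i)
}

gbw_uv <- function(et) {
  U <- sum(et$weight * (et$n_event_a - et$n_event * et$n_risk_a / et$n_risk))
  vterm <- ifelse(et$n_risk > 1,
                  et$weight^2 * et$n_event * (et$n_risk_a / et$n_risk) *
                    (1 - et$n_risk_a / et$n_risk) *
                    (et$n_risk - et$n_event) / (et$n_risk - 1),
                  0)
  c(U = U, V = sum(vterm))
}

## All-assignment enumeration of the weighted score U: every choose(n, n_a)
## label vector is evaluated through risk/death indicator matrices, so the
## returned tail probability is exact for the score statistic.
gbw_exact_p <- function(time, event, in_a, weight_type, U_obs) {
  ev_times <- sort(unique(time[event]))
  n <- length(time)
  R <- outer(time, ev_times, ">=") * 1
  D <- outer(time, ev_times, "==") * event
  n_i <- colSums(R)
  d_i <- colSums(D)
  w_i <- if (weight_type == "gehan") n_i else rep(1, length(ev_times))
  G <- t(combn(n, sum(in_a), FUN = function(idx) {
    g <- numeric(n); g[idx] <- 1; g
  }))
  n_a <- G %*% R
  d_a <- G %*% D
  U_all <- as.numeric(d_a %*% w_i - n_a %*% (w_i * d_i / n_i))
  mean(abs(U_all) >= abs(U_obs) - 1e-9)
}

#' Gehan-Breslow-Wilcoxon two-group test
#'
#' A weighted censored-data rank test: each distinct event time is weighted
#' by the total number at risk, emphasizing early survival differences. The
#' score is `U = sum_i n_i (d_ai - d_i n_ai / n_i)` with hypergeometric
#' variance `V = sum_i n_i^2 d_i (n_ai/n_i)(1 - n_ai/n_i)(n_i - d_i)/(n_i - 1)`
#' (terms with `n_i = 1` contribute 0). The default p-value comes from the
#' chi-square(1) distribution of `(U/sqrt(V))^2`; for small samples (at most
#' `exact_limit` distinct label assignments) the p-value is instead the
#' exact tail of the complete label-permutation distribution of `|U|`.
#' Setting all weights to 1 (`weights = "logrank"`) reduces the statistic to
#' the log-rank score — a cross-check mode for the event-table machinery.
#'
#' @param group_a_records,group_b_records Tibbles with `time` and `event`.
#' @param weights `"gehan"` (number at risk, the default) or `"logrank"`.
#' @param exact `"auto"` (exact permutation when feasible), `"never"`, or
#'   `"always"` (error if infeasible).
#' @param exact_limit Maximum number of label assignments enumerated.
#' @return Object of class `gbw_test`: `U`, `V`, `z`, `chisq`, `p`,
#'   `p_method`, `degenerate`, and the per-event-time table `event_table`.
#' @export
gbw_test <- function(group_a_records, group_b_records,
                     weights = c("gehan", "logrank"),
                     exact = c("auto", "never", "always"),
                     exact_limit = 20000) {
  weights <- match.arg(weights)
  exact <- match.arg(exact)
  stopifnot(nrow(group_a_records) >= 1L, nrow(group_b_records) >= 1L)
  time <- c(group_a_records$time, group_b_records$time)
  event <- as.logical(c(group_a_records$event, group_b_records$event))
  if (any(is.na(time)) || any(time <= 0)) {
    abort("survival times must be positive", class = "tcrdens_invalid_parameter")
  }
  in_a <- rep(c(TRUE, FALSE), c(nrow(group_a_records), nrow(group_b_records)))

  degenerate <- FALSE
  if (!any(event)) {
    return(structure(
      list(U = 0, V = 0, z = 0, chisq = 0, p = 1, p_method = "degenerate",
           degenerate = TRUE,
           event_table = gbw_event_table(time, event, in_a, weights)),
      class = "gbw_test"
    ))
  }
  et <- gbw_event_table(time, event, in_a, weights)
  uv <- gbw_uv(et)
  U <- unname(uv["U"]); V <- unname(uv["V"])
  if (V <= 0) {
    return(structure(
      list(U = U, V = V, z = 0, chisq = 0, p = 1, p_method = "degenerate",
           degenerate = TRUE, event_table = et),
      class = "gbw_test"
    ))
  }
  z <- U / sqrt(V)
  chisq <- z^2

  n_assign <- choose(length(time), sum(in_a))
  use_exact <- switch(exact,
    auto = n_assign <= exact_limit,
    never = FALSE,
    always = {
      if (n_assign > exact_limit) {
        abort(sprintf("exact enumeration infeasible: %.0f label assignments",
                      n_assign), class = "tcrdens_invalid_parameter")
      }
      TRUE
    })
  if (use_exact) {
    p <- gbw_exact_p(time, event, in_a, weights, U)
    p_method <- "exact_permutation"
  } else {
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
    p_method <- "chisq"
  }
  structure(
    list(U = U, V = V, z = z, chisq = chisq, p = p, p_method = p_method,
         degenerate = degenerate, event_table = et),
    class = "gbw_test"
  )
}

#' @export
print.gbw_test <- function(x, ...) {
  cat(sprintf("<gbw_test> U = %.4g, V = %.4g, chisq(1) = %.4g, p = %.4g (%s)\n",
              x$U, x$V, x$chisq, x$p, x$p_method))
  invisible(x)
}

#' Median split of a biomarker
#'
#' Values at or below the sample median go to the low group, values above it
#' to the high group (ties at the median go low). Missing values are
#' excluded and counted.
#'
#' @param values Numeric biomarker values.
#' @return List: `labels` (factor low/high aligned with `values`, `NA` for
#'   missing), `cut` (the median), `n_low`, `n_high`, `n_missing`,
#'   `degenerate` (all non-missing values identical).
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    abort("median split needs at least 2 non-missing values",
          class = "tcrdens_invalid_parameter")
  }
  cut <- median(values[ok])
  labels <- rep(NA_character_, length(values))
  labels[ok] <- ifelse(values[ok] <= cut, "low", "high")
  degenerate <- length(unique(values[ok])) == 1L
  list(
    labels = factor(labels, levels = c("low", "high")),
    cut = cut,
    n_low = sum(labels == "low", na.rm = TRUE),
    n_high = sum(labels == "high", na.rm = TRUE),
    n_missing = sum(!ok),
    degenerate = degenerate
  )
}

#' Median-split survival association for one biomarker
#'
#' Splits patients at the median biomarker value, fits a Kaplan-Meier curve
#' per group and compares the groups with the Gehan-Breslow-Wilcoxon test.
#' Patients with a missing biomarker are excluded and counted.
#'
#' @param records Tibble with `time`, `event` and the biomarker column.
#' @param biomarker_name Name of the biomarker column.
#' @param ... Passed to [gbw_test()].
#' @return List of class `biomarker_survival`: `biomarker`, `cut`, `n_low`,
#'   `n_high`, `n_excluded`, `km_low`, `km_high`, `test`.
#' @export
biomarker_survival_analysis <- function(records, biomarker_name, ...) {
  if (!biomarker_name %in% names(records)) {
    abort(sprintf("biomarker '%s' not attached to records", biomarker_name),
          class = "tcrdens_invalid_parameter")
  }
  values <- records[[biomarker_name]]
  keep <- !is.na(values) & !is.na(records$time) & !is.na(records$event)
  rec <- records[keep, ]
  if (nrow(rec) < 4L) {
    abort("underpowered: fewer than 4 patients with complete data",
          class = "tcrdens_underpowered")
  }
  split <- median_split(rec[[biomarker_name]])
  low <- rec[split$labels == "low", ]
  high <- rec[split$labels == "high", ]
  if (nrow(low) < 2L || nrow(high) < 2L) {
    abort("underpowered: fewer than 2 patients in a median-split group",
          class = "tcrdens_underpowered")
  }
  structure(
    list(
      biomarker = biomarker_name, cut = split$cut,
      n_low = nrow(low), n_high = nrow(high),
      n_excluded = sum(!keep), degenerate_split = split$degenerate,
      km_low = km_estimate(low), km_high = km_estimate(high),
      test = gbw_test(low, high, ...)
    ),
    class = "biomarker_survival"
  )
}

#' @export
print.biomarker_survival <- function(x, ...) {
  cat(sprintf("<biomarker_survival> %s: cut = %.4g, n = %d low / %d high, p = %.4g\n",
              x$biomarker, x$cut, x$n_low, x$n_high, x$test$p))
  invisible(x)
}

## Number of ways each value of the Mann-Whitney U arises, via the standard
## two-sample recurrence f(u; m, n) = f(u - n; m - 1, n) + f(u; m, n - 1).
mwu_exact_distribution <- function(m, n) {
  ## Iterative DP: d[[mm]][[nn]] is the count vector over u = 0..mm*nn.
  d <- vector("list", m + 1)
  for (mm in 0:m) d[[mm + 1]] <- vector("list", n + 1)
  for (mm in 0:m) d[[mm + 1]][[1]] <- 1
  for (nn in 0:n) d[[1]][[nn + 1]] <- 1
  for (mm in 1:m) {
    for (nn in 1:n) {
      left <- d[[mm]][[nn + 1]]                 # f(u - nn; mm - 1, nn)
      down <- d[[mm + 1]][[nn]]                 # f(u; mm, nn - 1)
      len <- mm * nn + 1
      v <- numeric(len)
      v[seq_along(down)] <- down
      v[nn + seq_along(left)] <- v[nn + seq_along(left)] + left
      d[[mm + 1]][[nn + 1]] <- v
    }
  }
  d[[m + 1]][[n + 1]]
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum statistic with midrank ties. The p-value is exact (by full
#' enumeration of the U distribution) when `n_a * n_b <= 400` and there are
#' no ties; otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List: `U` (statistic for sample a), `p`, `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  n_a <- length(sample_a); n_b <- length(sample_b)
  if (n_a == 0L || n_b == 0L) {
    abort("both samples must be non-empty", class = "tcrdens_invalid_parameter")
  }
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(pooled))

  if (!ties && n_a * n_b <= 400) {
    counts <- mwu_exact_distribution(n_a, n_b)
    total <- sum(counts)
    u_int <- round(U)
    p_le <- sum(counts[seq_len(u_int + 1)]) / total
    p_ge <- sum(counts[(u_int + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    N <- n_a + n_b
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- (n_a * n_b / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(U = U, p = 1, method = "degenerate"))
    }
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(sigma2)
    if (abs(U - mu) < 0.5) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(U = U, p = p, method = method)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H against chi-square(k - 1), and pairwise
#' Dunn z statistics using the pooled-rank variance with tie correction;
#' adjusted p-values are Bonferroni over all pairwise comparisons.
#'
#' @param groups Named list of non-empty numeric vectors (>= 2 groups).
#' @return List: `H`, `df`, `p`, and `pairs` — a tibble with `group1`,
#'   `group2`, `z`, `p`, `p_adj`.
#' @export
kruskal_wallis_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("need at least 2 groups", class = "tcrdens_invalid_parameter")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    abort("every group must contain at least one observation",
          class = "tcrdens_invalid_parameter")
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(names(groups), sizes)
  rbar <- tapply(r, grp, mean)[names(groups)]
  H_raw <- 12 / (N * (N + 1)) * sum(sizes * rbar^2) - 3 * (N + 1)
  tie_tab <- table(pooled)
  Tsum <- sum(tie_tab^3 - tie_tab)
  C <- 1 - Tsum / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H_raw / C
    p <- pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }

  pair_idx <- combn(length(groups), 2)
  var_base <- N * (N + 1) / 12 - Tsum / (12 * (N - 1))
  n_pairs <- ncol(pair_idx)
  pairs <- lapply(seq_len(n_pairs), function(k) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_pair <- if (se > 0) 2 * pnorm(-abs(z)) else 1
    tibble(group1 = names(groups)[i], group2 = names(groups)[j],
           z = unname(z), p = unname(p_pair),
           p_adj = min(1, unname(p_pair) * n_pairs))
  })
  list(H = H, df = length(groups) - 1, p = p,
       pairs = dplyr::bind_rows(pairs))
}

## All permutations of 1..n as an (n! x n) matrix, built recursively.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation (two-tailed)
#'
#' Midrank-based rho. The p-value is exact (full enumeration of all `n!`
#' pairings) when `n <= 9`, otherwise from the t-approximation with `n - 2`
#' degrees of freedom. Missing pairs are dropped.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return List: `rho`, `p`, `n`, `method`, `degenerate` (`TRUE` with `rho`
#'   and `p` `NA` when either vector has zero rank variance).
#' @export
spearman_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    abort("need at least 3 complete pairs", class = "tcrdens_invalid_parameter")
  }
  rx <- rank(x); ry <- rank(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate",
                degenerate = TRUE))
  }
  rho <- stats::cov(rx, ry) / (sx * sy)

  if (n <= 9L) {
    P <- all_permutations(n)
    s_all <- matrix(rx[P], nrow(P), n) %*% ry
    rho_all <- (s_all / (n - 1) - n / (n - 1) * mean(rx) * mean(ry)) / (sx * sy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t_approximation"
  }
  list(rho = rho, p = p, n = n, method = method, degenerate = FALSE)
}

#' Spearman correlation matrix of subset densities vs gene expression
#'
#' One Spearman correlation per (gene, subset) pair over samples matched by
#' `sample_id`. Pairs with fewer than 3 matched complete observations, or
#' with zero variance, are reported missing. Per-cell significance is
#' flagged at `alpha` without multiplicity correction (cells are marked
#' individually, as in a correlation heat map).
#'
#' @param density_table Tibble: `sample_id`, `subset`, `cells_per_ug`.
#' @param expression_table Tibble: `sample_id`, `gene`, `expression`.
#' @param alpha Per-cell significance level.
#' @return Tibble: `gene`, `subset`, `n`, `rho`, `p`, `significant`.
#' @export
correlation_matrix <- function(density_table, expression_table, alpha = 0.05) {
  shared <- intersect(unique(density_table$sample_id),
                      unique(expression_table$sample_id))
  if (length(shared) == 0L) {
    abort("no matched samples between density and expression tables",
          class = "tcrdens_invalid_parameter")
  }
  genes <- unique(expression_table$gene)
  subsets <- unique(density_table$subset)
  out <- list()
  for (g in genes) {
    e <- expression_table[expression_table$gene == g, ]
    for (s in subsets) {
      d <- density_table[density_table$subset == s, ]
      m <- merge(d[, c("sample_id", "cells_per_ug")],
                 e[, c("sample_id", "expression")], by = "sample_id")
      m <- m[!is.na(m$cells_per_ug) & !is.na(m$expression), ]
      if (nrow(m) < 3L) {
        out[[length(out) + 1L]] <- tibble(gene = g, subset = s, n = nrow(m),
                                          rho = NA_real_, p = NA_real_,
                                          significant = NA)
        next
      }
      sc <- spearman_correlation(m$cells_per_ug, m$expression)
      out[[length(out) + 1L]] <- tibble(
        gene = g, subset = s, n = sc$n, rho = sc$rho, p = sc$p,
        significant = if (is.na(sc$p)) NA else sc$p < alpha
      )
    }
  }
  dplyr::bind_rows(out)
}
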