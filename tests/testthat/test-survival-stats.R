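test_that("Kaplan-Meier matches hand computation and the empirical survivor", {
  ## hand product-limit: events at 1 and 3, censoring at 2
  km <- km_estimate(surv_tbl(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  expect_equal(km$steps$time, c(1, 3))
  expect_equal(km$steps$survival, c(2 / 3, 0))

  ## no censoring: S equals the empirical survival fraction
  set.seed(1)
  t <- rexp(40)
  km2 <- km_estimate(surv_tbl(t, rep(TRUE, 40)))
  emp <- vapply(km2$steps$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km2$steps$survival, emp, tolerance = 1e-12)

  ## all censored: S identically 1
  km3 <- km_estimate(surv_tbl(t[1:10], rep(FALSE, 10)))
  expect_equal(nrow(km3$steps), 0)
  expect_equal(km_survival_at(km3, c(0.5, 2)), c(1, 1))

  expect_error(km_estimate(surv_tbl(c(1, -2), c(TRUE, TRUE))),
               class = "tcrdens_invalid_parameter")
})

test_that("Kaplan-Meier agrees with survival::survfit under censoring", {
  library(survival)
  set.seed(2)
  t <- rexp(60); e <- runif(60) < 0.6
  km <- km_estimate(surv_tbl(t, e))
  sf <- summary(survfit(Surv(t, e) ~ 1))
  expect_equal(km$steps$time, sf$time)
  expect_equal(km$steps$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$steps$n_risk, sf$n.risk)
})

test_that("GBW is symmetric, degenerate-safe, and z^2 equals chi-square", {
  set.seed(3)
  a <- surv_tbl(rexp(12), runif(12) < 0.7)
  res_same <- gbw_test(a, a, exact = "never")
  expect_equal(res_same$U, 0)
  expect_equal(res_same$p, 1)

  res_noev <- gbw_test(surv_tbl(1:3, rep(FALSE, 3)), surv_tbl(1:3, rep(FALSE, 3)))
  expect_true(res_noev$degenerate)
  expect_equal(res_noev$p, 1)

  b <- surv_tbl(rexp(12, 2), runif(12) < 0.7)
  res <- gbw_test(a, b, exact = "never")
  expect_equal(res$chisq, res$z^2, tolerance = 1e-12)
  expect_true(res$p >= 0 && res$p <= 1)
  ## event table accounting: per-time events split across groups
  expect_true(all(res$event_table$n_event_a <= res$event_table$n_event))
  expect_true(all(res$event_table$weight == res$event_table$n_risk))
})

test_that("GBW with unit weights reduces to the log-rank score", {
  library(survival)
  set.seed(4)
  for (i in 1:5) {
    t <- rexp(30); e <- runif(30) < 0.7; g <- rep(0:1, 15)
    res <- gbw_test(surv_tbl(t[g == 0], e[g == 0]),
                    surv_tbl(t[g == 1], e[g == 1]),
                    weights = "logrank", exact = "never")
    sd_ref <- survdiff(Surv(t, e) ~ g)
    expect_equal(res$chisq, unname(sd_ref$chisq), tolerance = 1e-9)
  }
})

test_that("small-sample GBW p matches an independent MC permutation oracle", {
  set.seed(5)
  for (i in 1:4) {
    a <- surv_tbl(rexp(7), runif(7) < 0.75)
    b <- surv_tbl(rexp(7, 1.8), runif(7) < 0.75)
    res <- gbw_test(a, b)
    expect_equal(res$p_method, "exact_permutation")
    p_mc <- gbw_mc_oracle(a, b, n_mc = 2e4, seed = 100 + i)
    expect_lt(abs(res$p - p_mc), 0.02)  # ~6 MC sd at 2e4 draws
  }
})

test_that("median split uses the documented tie and degeneracy conventions", {
  sp <- median_split(1:10)
  expect_equal(sp$cut, 5.5)
  expect_equal(as.integer(table(sp$labels)), c(5L, 5L))

  ## ties at the median go to the low group
  sp2 <- median_split(c(1, 2, 3, 3, 9))
  expect_equal(sp2$cut, 3)
  expect_equal(as.character(sp2$labels), c("low", "low", "low", "low", "high"))

  sp3 <- median_split(c(7, 7, 7))
  expect_true(sp3$degenerate)
  expect_equal(sp3$n_high, 0)

  sp4 <- median_split(c(1, NA, 2, 5))
  expect_equal(sp4$n_missing, 1)
  expect_error(median_split(c(NA, 1)), class = "tcrdens_invalid_parameter")
})

test_that("biomarker survival analysis composes split, KM and GBW", {
  set.seed(6)
  bm <- rlnorm(30)
  rec <- generate_survival(bm, 0.05, -1.5, 40, seed = 7)
  res <- biomarker_survival_analysis(rec, "biomarker")
  expect_equal(res$n_low + res$n_high, 30)
  expect_s3_class(res$km_low, "km_curve")
  expect_equal(res$test$p,
               gbw_test(rec[res$cut >= rec$biomarker, ],
                        rec[res$cut < rec$biomarker, ])$p)

  ## protective effect: high group sits above the low group in large n
  bm_big <- rlnorm(400)
  rec_big <- generate_survival(bm_big, 0.05, -1.5, 40, seed = 8)
  res_big <- biomarker_survival_analysis(rec_big, "biomarker")
  tq <- median(rec_big$time)
  expect_gt(km_survival_at(res_big$km_high, tq),
            km_survival_at(res_big$km_low, tq))

  rec$biomarker[3:30] <- NA
  expect_error(biomarker_survival_analysis(rec, "biomarker"),
               class = "tcrdens_underpowered")
  expect_error(biomarker_survival_analysis(rec, "nope"),
               class = "tcrdens_invalid_parameter")
})

test_that("Mann-Whitney exact p equals enumeration; ties use the approximation", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)          # 2/20 orderings
  expect_equal(mw$method, "exact")

  ## identical samples (ties): U = n_a n_b / 2 and p = 1
  mw2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p, 1)
  expect_equal(mw2$method, "normal_approximation")

  ## exact path matches wilcox.test on untied data
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(9)
    expect_equal(mann_whitney_u(x, y)$p, wilcox.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
  ## approximation path matches wilcox.test's corrected normal approximation
  set.seed(10)
  x <- round(rnorm(30), 1); y <- round(rnorm(35, 0.3), 1)
  expect_equal(mann_whitney_u(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  ## strongly separated large samples
  expect_lt(mann_whitney_u(rnorm(60), rnorm(60, 10))$p, 1e-6)
  expect_error(mann_whitney_u(numeric(), 1:3),
               class = "tcrdens_invalid_parameter")
})

test_that("Kruskal-Wallis H and Dunn z match direct formula recomputation", {
  set.seed(11)
  groups <- list(a = round(rnorm(7), 1), b = round(rnorm(8, 0.5), 1),
                 c = round(rnorm(6), 1))
  res <- kruskal_wallis_dunn(groups)

  ## independent recomputation from first principles
  pooled <- unlist(groups)
  r <- rank(pooled)
  N <- length(pooled)
  grp <- rep(names(groups), lengths(groups))
  rbar <- tapply(r, grp, mean)
  H_raw <- 12 / (N * (N + 1)) * sum(lengths(groups) * rbar[names(groups)]^2) -
    3 * (N + 1)
  ties <- table(pooled)
  H_ref <- H_raw / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(res$H, H_ref, tolerance = 1e-12)
  expect_equal(res$H, unname(kruskal.test(groups)$statistic), tolerance = 1e-12)
  expect_equal(res$p, kruskal.test(groups)$p.value, tolerance = 1e-12)

  sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
  z_ab <- (rbar[["a"]] - rbar[["b"]]) / sqrt(sig2 * (1 / 7 + 1 / 8))
  expect_equal(res$pairs$z[res$pairs$group1 == "a" & res$pairs$group2 == "b"],
               z_ab, tolerance = 1e-12)
  expect_equal(res$pairs$p_adj, pmin(1, res$pairs$p * 3))

  ## identical constants: H = 0, p = 1
  res0 <- kruskal_wallis_dunn(list(a = rep(2, 4), b = rep(2, 5)))
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
  expect_error(kruskal_wallis_dunn(list(a = 1:3, b = numeric())),
               class = "tcrdens_invalid_parameter")
})

test_that("Spearman rho and exact permutation p match enumeration", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_correlation(x, x)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)

  set.seed(12)
  xr <- rnorm(6); yr <- rnorm(6)
  res <- spearman_correlation(xr, yr)
  expect_equal(res$method, "exact_permutation")

  ## independent full enumeration via Lehmer-code decoding
  rx <- rank(xr); ry <- rank(yr)
  rhos <- vapply(0:(factorial(6) - 1), function(k) {
    suppressWarnings(stats::cor(rx[lehmer_permutation(k, 6)], ry))
  }, numeric(1))
  p_ref <- mean(abs(rhos) >= abs(res$rho) - 1e-12)
  expect_equal(res$p, p_ref, tolerance = 1e-12)
  expect_equal(res$p, cor.test(xr, yr, method = "spearman")$p.value,
               tolerance = 1e-12)

  ## t-approximation path for larger n
  set.seed(13)
  xl <- rnorm(30); yl <- xl + rnorm(30)
  rl <- spearman_correlation(xl, yl)
  expect_equal(rl$method, "t_approximation")
  expect_equal(rl$rho, unname(cor(xl, yl, method = "spearman")))

  ## degenerate input flagged
  dg <- spearman_correlation(rep(1, 5), rnorm(5))
  expect_true(dg$degenerate)
  expect_error(spearman_correlation(1:2, 2:3),
               class = "tcrdens_invalid_parameter")
})

test_that("correlation matrix flags sparse and constant cells", {
  set.seed(14)
  sids <- paste0("S", 1:10)
  dens <- tibble::tibble(sample_id = rep(sids, 2),
                         subset = rep(c("Vd1_TEM", "Vd1_TRM"), each = 10),
                         cells_per_ug = c(rnorm(10, 50, 10), rnorm(10, 20, 5)))
  expr <- tibble::tibble(
    sample_id = rep(sids, 2), gene = rep(c("MICA", "FLAT"), each = 10),
    expression = c(dens$cells_per_ug[1:10], rep(3, 10)))
  cm <- correlation_matrix(dens, expr)
  ## expression identical to the Vd1_TEM density: rho = 1
  expect_equal(cm$rho[cm$gene == "MICA" & cm$subset == "Vd1_TEM"], 1)
  ## constant gene: degenerate, reported missing
  expect_true(all(is.na(cm$rho[cm$gene == "FLAT"])))
  expect_error(
    correlation_matrix(dens,
                       tibble::tibble(sample_id = "other", gene = "g",
                                      expression = 1)),
    class = "tcrdens_invalid_parameter")
})

test_that("rank tests hold their type-I error under the null", {
  n_rep <- 2000
  set.seed(15)
  rej <- matrix(FALSE, n_rep, 3)
  for (i in seq_len(n_rep)) {
    x <- rnorm(10); y <- rnorm(10)
    rej[i, 1] <- mann_whitney_u(x, y)$p < 0.05
    rej[i, 2] <- kruskal_wallis_dunn(list(rnorm(12), rnorm(12), rnorm(12)))$p < 0.05
    rej[i, 3] <- spearman_correlation(rnorm(12), rnorm(12))$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("median-split GBW power matches the frozen regression constant", {
  ## frozen value from the 1000-replicate simulation oracle at n = 200,
  ## beta = -0.7 (lognormal biomarker, exponential hazard, uniform censoring)
  frozen_power <- 0.978
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    set.seed(60000 + i)
    bm <- rlnorm(200, 2, 1)
    surv <- generate_survival(bm, 0.012, -0.7, 72, seed = 70000 + i)
    biomarker_survival_analysis(surv, "biomarker")$test$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - frozen_power), 0.03)
})
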