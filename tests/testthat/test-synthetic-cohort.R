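test_that("clone pool frequencies follow the rank power law", {
  ## closed-form re-derivation at alpha = 1.2
  pool <- generate_clone_pool(1000, 1.2, seed = 3)
  expected <- (1:1000)^(-1.2) / sum((1:1000)^(-1.2))
  expect_equal(pool$freq, expected, tolerance = 1e-12)

  expect_equal(generate_clone_pool(1, 2, seed = 1)$freq, 1.0)
  expect_equal(generate_clone_pool(4, 0, seed = 1)$freq, rep(0.25, 4))
})

test_that("clone pool CDR3s are distinct, in-frame-length, single locus", {
  pool <- generate_clone_pool(500, 1, seed = 9, locus = "TRD")
  expect_false(any(duplicated(pool$cdr3_nt)))
  lens <- nchar(pool$cdr3_nt)
  expect_true(all(lens %% 3 == 0 & lens >= 24 & lens <= 60))
  expect_false(any(grepl("[^ACGT]", pool$cdr3_nt)))
  expect_true(all(substr(pool$v_family, 1, 3) == "TRD"))
  expect_true(all(substr(pool$j_family, 1, 3) == "TRD"))

  expect_error(generate_clone_pool(0, 1, seed = 1),
               class = "tcrdens_invalid_parameter")
  expect_error(generate_clone_pool(5, -1, seed = 1),
               class = "tcrdens_invalid_parameter")
})

test_that("paired repertoires respect the overlap limit cases", {
  pool <- generate_clone_pool(20, 0.5, seed = 2)
  ## rho = 1, deep sampling: every observed tumor clone also observed in NT
  pr <- generate_paired_repertoires(pool, 1, 20000, 3, seed = 4)
  expect_true(all(pr$tumor$cdr3_nt %in% pr$nontumor_tissue$cdr3_nt))
  ## rho = 0: novel namespace is disjoint, sharing exactly zero
  pr0 <- generate_paired_repertoires(pool, 0, 20000, 3, seed = 4)
  expect_length(intersect(pr0$tumor$cdr3_nt, pr0$nontumor_tissue$cdr3_nt), 0)

  expect_error(generate_paired_repertoires(pool[0, ], 0.5, 100, 3, seed = 1),
               class = "tcrdens_invalid_parameter")
  expect_warning(pr_empty <- generate_paired_repertoires(pool, 0.5, 0, 3, seed = 1),
                 "depth")
  expect_equal(nrow(pr_empty$tumor), 0)
})

test_that("malformed artifact rows are counted and carry the right shapes", {
  pool <- generate_clone_pool(100, 1, seed = 7)
  pr <- generate_paired_repertoires(pool, 0.5, 5000, 3,
                                    out_of_frame_fraction = 0.2,
                                    cross_locus_fraction = 0.1, seed = 11)
  tr <- pr$truth$malformed
  for (k in 1:2) {
    tab <- list(pr$nontumor_tissue, pr$tumor)[[k]]
    expect_equal(nrow(tab),
                 tr$n_clean_rows[k] + tr$n_out_of_frame[k] + tr$n_cross_locus[k])
    oof <- tab[tab$frame == "out", ]
    expect_equal(nrow(oof), tr$n_out_of_frame[k])
    expect_true(all(nchar(oof$cdr3_nt) %% 3 == 1))
    cross <- tab[tab$frame == "in" &
                   substr(tab$v_family, 1, 3) != substr(tab$j_family, 1, 3), ]
    expect_equal(nrow(cross), tr$n_cross_locus[k])
  }
  expect_true(all(pr$nontumor_tissue$dna_mass_ug == 3))
})

test_that("flow tables are multinomial cascades with children <= parents", {
  f <- c(CD4 = 0.5, CD8 = 0.3, Vd1 = 0.1, Vd2 = 0.06, other = 0.04)
  gp <- default_gate_probs()$tumor
  for (s in 1:5) {
    rec <- generate_flow_table(f, gp, 10000, seed = s)
    tree <- build_gating_tree(rec)  # errors if any child exceeds its parent
    expect_s3_class(tree, "gating_tree")
    expect_equal(unname(tree$counts["CD3"]), 10000)
  }
  ## gate prob 0 yields an empty child gate
  gp0 <- gp
  gp0$Vd1$cd103 <- 0
  rec0 <- generate_flow_table(f, gp0, 10000, seed = 1)
  expect_equal(rec0$cell_count[rec0$gate_path == "CD3/TCRgdpos/Vd1/CD103pos"], 0L)

  ## seeded replay: identical output for identical seed
  expect_identical(generate_flow_table(f, gp, 5000, seed = 42),
                   generate_flow_table(f, gp, 5000, seed = 42))
  expect_error(generate_flow_table(f * 2, gp, 100, seed = 1),
               class = "tcrdens_invalid_parameter")
})

test_that("survival generation honours the hazard model", {
  ## beta = 0: event rates exchangeable between biomarker halves
  surv0 <- generate_survival(rlnorm(2000), 0.05, 0, 30, seed = 1)
  hi <- surv0$biomarker > median(surv0$biomarker)
  expect_lt(abs(mean(surv0$event[hi]) - mean(surv0$event[!hi])), 0.05)

  ## protective beta: fewer events in the high-biomarker half
  surv1 <- generate_survival(rlnorm(200), 0.05, -0.7, 30, seed = 5)
  hi1 <- surv1$biomarker > median(surv1$biomarker)
  expect_lt(mean(surv1$event[hi1]), mean(surv1$event[!hi1]))

  ## tiny censoring bound: everything censored near zero
  surv2 <- generate_survival(rlnorm(50), 0.001, 0, 1e-6, seed = 2)
  expect_false(any(surv2$event))
  expect_true(all(surv2$time < 1e-6))

  expect_error(generate_survival(1:5, 0, 0, 10), class = "tcrdens_invalid_parameter")
})

test_that("generate_cohort is deterministic and conserves frequencies", {
  cfg <- cohort_config(n_patients = 3, n_clones_tissue = 80,
                       depth_templates = 2000, n_flow_cells = 4000, seed = 13)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))

  for (pid in names(co1$truth$frequencies)) {
    for (comp in names(co1$truth$frequencies[[pid]])) {
      expect_equal(sum(co1$truth$frequencies[[pid]][[comp]]), 1, tolerance = 1e-9)
    }
  }
  expect_equal(co1$truth$beta, cfg$beta)
  expect_equal(co1$truth$overlap_rho, cfg$overlap_rho)

  ## empty cohort
  co0 <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_equal(nrow(co0$rearrangements), 0)
  expect_equal(nrow(co0$survival), 0)
})

test_that("invalid configurations are rejected with the full violation list", {
  expect_error(cohort_config(overlap_rho = 1.2),
               class = "tcrdens_invalid_parameter")
  expect_error(cohort_config(dna_mass_ug = 0),
               class = "tcrdens_invalid_parameter")
  err <- tryCatch(cohort_config(overlap_rho = -1, baseline_hazard = -2),
                  error = function(e) e)
  expect_match(paste(c(conditionMessage(err), err$body), collapse = "\n"),
               "overlap_rho")
  expect_match(paste(c(conditionMessage(err), err$body), collapse = "\n"),
               "baseline_hazard")
})
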