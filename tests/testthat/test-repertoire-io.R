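test_that("AIRR round trip is lossless", {
  pool <- generate_clone_pool(40, 1, seed = 1)
  pr <- generate_paired_repertoires(pool, 0.5, 1000, 3,
                                    out_of_frame_fraction = 0.1,
                                    cross_locus_fraction = 0.1, seed = 2)
  tab <- pr$tumor
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr(tab, path)
  expect_equal(length(readLines(path)), nrow(tab) + 1)
  back <- read_rearrangements(path, dialect = "airr")
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("missing mandatory columns raise a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(junction = "AAA", v_call = "TRDV1",
                                  j_call = "TRDJ1", productive = "T"), path)
  expect_error(read_rearrangements(path, "airr"), "duplicate_count",
               class = "tcrdens_format_error")

  ## header-only file: empty-table warning
  readr::write_tsv(tibble::tibble(junction = character(), v_call = character(),
                                  j_call = character(), productive = character(),
                                  duplicate_count = integer()), path)
  expect_warning(read_rearrangements(path, "airr", dna_mass_ug = 3),
                 "no parseable")
})

test_that("the immunoSEQ-like dialect maps to the canonical schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    nucleotide = c("ACGACGACGACGACGACGACGACG", "ACGTACGTACGTACGTACGTACGTA"),
    vFamilyName = c("TRDV1", "TRAV12"),
    jFamilyName = c("TRDJ1", "TRAJ4"),
    sequenceStatus = c("In", "Out"),
    templates = c(10, 5)
  ), path)
  tab <- read_rearrangements(path, "immunoseq_like", patient_id = "P1",
                             compartment = "tumor", dna_mass_ug = 3)
  expect_equal(tab$frame, c("in", "out"))
  expect_equal(tab$locus, c("TRD", "TRA"))
  expect_equal(tab$v_family, c("TRDV1", "TRAV12"))
  expect_equal(tab$templates, c(10L, 5L))
})

test_that("unparseable rows are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    junction = c("ACGACG", "ACGNNN", "ACGACG"),
    v_call = "TRDV1*01", j_call = "TRDJ1*01",
    productive = "T", duplicate_count = c("4", "2", "-1")
  ), path)
  expect_warning(tab <- read_rearrangements(path, "airr", dna_mass_ug = 3),
                 "rejected 2")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$v_family, "TRDV1")  # allele stripped
})

test_that("filter keeps exactly in-frame locus-consistent joins", {
  tab <- make_rearr_table(list(
    list(cdr3_nt = "AAACCC", v_family = "TRAV2", j_family = "TRAJ9",
         locus = "TRA"),                                   # keep
    list(cdr3_nt = "AAACCG", v_family = "TRDV1", j_family = "TRAJ9"),  # cross
    list(cdr3_nt = "AAACCT", v_family = "TRDV1", j_family = "TRDJ1",
         frame = "out"),                                   # out of frame
    list(cdr3_nt = "AAACCA", v_family = "TRDV1", j_family = "TRDJ1",
         frame = "stop"),                                  # stop codon
    list(cdr3_nt = "AAAGGG", v_family = "TRDV2", j_family = "TRDJ3")   # keep
  ))
  out <- filter_rearrangements(tab)
  expect_equal(out$cdr3_nt, c("AAACCC", "AAAGGG"))
  ## idempotence and non-mutation
  expect_identical(filter_rearrangements(out), out)
  expect_equal(nrow(tab), 5)
  expect_identical(filter_rearrangements(tab[0, ]), tab[0, ])
})

test_that("filter count matches generator-recorded truth", {
  pool <- generate_clone_pool(150, 1.1, seed = 21)
  pr <- generate_paired_repertoires(pool, 0.4, 8000, 3,
                                    out_of_frame_fraction = 0.15,
                                    cross_locus_fraction = 0.05, seed = 22)
  for (k in 1:2) {
    tab <- list(pr$nontumor_tissue, pr$tumor)[[k]]
    expect_equal(nrow(filter_rearrangements(tab)),
                 pr$truth$malformed$n_clean_rows[k])
  }
})

test_that("normalization divides template sums by the DNA mass", {
  tab <- make_rearr_table(list(
    list(cdr3_nt = "AAACCC", v_family = "TRDV1", templates = 400L),
    list(cdr3_nt = "AAACCG", v_family = "TRDV1", templates = 200L),
    list(cdr3_nt = "AAACCT", v_family = "TRDV2", templates = 90L),
    list(cdr3_nt = "AAAGGG", v_family = "TRAV3", j_family = "TRAJ1",
         locus = "TRA", templates = 300L)
  ), dna_mass_ug = 3)
  s <- normalize_counts(tab)
  get <- function(cl, col) s[[col]][s$class == cl]
  expect_equal(get("TRDV1", "counts_per_ug"), 200)        # 600 templates / 3 ug
  expect_equal(get("TRDV2", "counts_per_ug"), 30)
  expect_equal(get("TRA", "counts_per_ug"), 100)
  expect_equal(get("total_T", "counts_per_ug"),
               get("TRA", "counts_per_ug") + get("TRD", "counts_per_ug"))
  expect_equal(get("TRDV1", "unique_clones"), 2L)

  ## duplicate CDR3 rows aggregate to one clone
  tab2 <- make_rearr_table(list(
    list(cdr3_nt = "AAACCC", templates = 5L),
    list(cdr3_nt = "AAACCC", templates = 7L)
  ))
  s2 <- normalize_counts(tab2)
  expect_equal(s2$unique_clones[s2$class == "TRDV1"], 1L)
  expect_equal(s2$templates[s2$class == "TRDV1"], 12)

  ## linearity in mass
  tab3 <- tab
  tab3$dna_mass_ug <- 6
  s3 <- normalize_counts(tab3)
  expect_equal(s3$counts_per_ug, s$counts_per_ug / 2, tolerance = 1e-12)

  expect_equal(nrow(normalize_counts(tab[0, ])), 0)
  tab_bad <- tab
  tab_bad$dna_mass_ug <- 0
  expect_error(normalize_counts(tab_bad), class = "tcrdens_invalid_mass")
})
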