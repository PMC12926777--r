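# Synthetic fixture generators: determinism, limits, and statistical sanity.

test_that("generators are seed-deterministic down to the written bytes", {
  a <- sim_cohort(n_samples = 6, n_variants = 80, seed = 99)
  b <- sim_cohort(n_samples = 6, n_variants = 80, seed = 99)
  expect_identical(a$variants, b$variants)
  expect_identical(a$panel, b$panel)
  fa <- withr::local_tempfile(fileext = ".vcf")
  fb <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(a$variants, fa)
  write_vcf(b$variants, fb)
  expect_identical(read_file_bytes(fa), read_file_bytes(fb))
  # a different seed changes the data
  expect_false(identical(
    sim_cohort(n_samples = 6, n_variants = 80, seed = 100)$variants, a$variants
  ))
})

test_that("generators leave no trace on the session RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(sim_cohort(n_samples = 3, n_variants = 10, seed = 7))
  expect_identical(stats::runif(1), before)
})

test_that("zero missingness yields complete call rates", {
  sim <- sim_cohort(n_samples = 10, n_variants = 60, seed = 3, missing_rate = 0)
  m <- gt_matrix(sim$variants)
  expect_true(all(call_rate(m, "sample") == 1))
  expect_true(all(call_rate(m, "variant") == 1))
})

test_that("genotype frequencies match Hardy-Weinberg expectations at large n", {
  sim <- sim_cohort(
    n_samples = 10000, n_variants = 30, seed = 77,
    missing_rate = 0, hwe_outlier_rate = 0
  )
  m <- gt_matrix(sim$variants)
  p <- sim$variants$p_alt
  exp_het <- 2 * p * (1 - p)
  obs_het <- rowMeans(m == 1)
  se <- sqrt(exp_het * (1 - exp_het) / ncol(m))
  expect_true(all(abs(obs_het - exp_het) <= 3 * se))
  # planted outliers violate equilibrium hard
  sim2 <- sim_cohort(
    n_samples = 200, n_variants = 200, seed = 78,
    missing_rate = 0, hwe_outlier_rate = 0.1
  )
  m2 <- gt_matrix(sim2$variants)
  gc <- geno_counts(m2)
  p_hwe <- hwe_exact_p(gc$n_homref, gc$n_het, gc$n_homalt)
  expect_true(all(p_hwe[sim2$variants$hwe_outlier] < 1e-6))
})

test_that("the cohort truth table predicts panel membership positionally", {
  sim <- sim_cohort(n_samples = 4, n_variants = 150, seed = 31)
  idx <- region_index(sim$panel)
  expect_identical(
    overlap_count(sim$variants, idx) >= 1,
    sim$variants$in_panel
  )
})

test_that("trios have a well-formed pedigree and Mendelian-consistent genotypes", {
  trio <- sim_trio(n_variants = 200, seed = 15, missing_rate = 0)
  expect_identical(nrow(trio$ped), 3L)
  child <- trio$ped[trio$ped$father != "0", ]
  expect_identical(nrow(child), 1L)
  expect_identical(child$father, "FATHER")
  expect_identical(child$mother, "MOTHER")
  m <- gt_matrix(trio$variants)
  # child dosage is bounded by what the parents can transmit
  expect_true(all(m[, "PROBAND"] <= ceiling(m[, "FATHER"] / 2) + ceiling(m[, "MOTHER"] / 2)))
  expect_true(all(m[, "PROBAND"] >= floor(m[, "FATHER"] / 2) + floor(m[, "MOTHER"] / 2)))
  f <- withr::local_tempfile(fileext = ".ped")
  write_ped(trio$ped, f)
  expect_identical(length(readLines(f)), 3L)
})

test_that("planted low-GQ genotypes flip all-samples vs any-sample as the truth table predicts", {
  trio <- sim_trio(n_variants = 300, seed = 42, low_gq_rate = 0.3)
  # truth-table replay, straight off the generated per-sample values
  gq_pass <- t(vapply(
    trio$variants$samples,
    function(s) {
      !is.na(s$GT) & !is.na(s$GQ) & s$GQ >= 20
    }, logical(3)
  ))
  want_all <- rowSums(gq_pass) == 3
  want_any <- rowSums(gq_pass) >= 1
  doc <- function(agg) {
    qv_file(
      meta = minimal_meta(),
      filters = list(qv_filter("gq", "keep_if", qv_condition("FORMAT/GQ", ">=", 20),
        sample_aggregation = agg
      ))
    )
  }
  kept_all <- apply_qv(doc("all_samples"), trio$variants)$kept
  kept_any <- apply_qv(doc("any_sample"), trio$variants)$kept
  expect_identical(kept_all$id, trio$variants$id[want_all])
  expect_identical(kept_any$id, trio$variants$id[want_any])
  # the two aggregations genuinely differ on this fixture
  expect_gt(nrow(kept_any), nrow(kept_all))
})
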