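# Call rates, MAF, the exact HWE test, and the QV-driven GWAS QC chain.

test_that("call rates are non-missing fractions along each axis", {
  m <- matrix(c(0, 1, NA, 2, NA, NA), nrow = 2, byrow = TRUE,
    dimnames = list(c("v1", "v2"), c("s1", "s2", "s3"))
  )
  expect_equal(unname(call_rate(m, "variant")), c(2 / 3, 1 / 3))
  expect_equal(unname(call_rate(m, "sample")), c(1, 0.5, 0))
  expect_error(call_rate(matrix(nrow = 0, ncol = 0)), "empty")

  set.seed(21)
  r <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 20)
  brute <- vapply(seq_len(nrow(r)), function(i) sum(!is.na(r[i, ])) / ncol(r), 0)
  expect_equal(unname(call_rate(r, "variant")), brute)
})

test_that("MAF matches a brute-force allele tally", {
  expect_equal(maf(1, 1, 1), 0.5)
  expect_equal(maf(10, 0, 0), 0)
  expect_true(is.na(maf(0, 0, 0)))
  set.seed(31)
  for (i in 1:50) {
    cnt <- sample(0:40, 3, replace = TRUE)
    if (sum(cnt) == 0) next
    alleles <- c(rep(0, 2 * cnt[1]), rep(0:1, cnt[2]), rep(1, 2 * cnt[3]))
    p <- mean(alleles)
    expect_equal(maf(cnt[1], cnt[2], cnt[3]), min(p, 1 - p))
  }
})

test_that("the exact HWE test has its boundary, range and symmetry properties", {
  expect_equal(hwe_exact_p(10, 0, 0), 1) # monomorphic: one attainable configuration
  expect_equal(hwe_exact_p(0, 0, 25), 1)
  set.seed(41)
  for (i in 1:100) {
    cnt <- sample(0:60, 3, replace = TRUE)
    if (sum(cnt) == 0) next
    p <- hwe_exact_p(cnt[1], cnt[2], cnt[3])
    expect_true(p > 0 && p <= 1)
    expect_identical(p, hwe_exact_p(cnt[3], cnt[2], cnt[1])) # allele relabeling
  }
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
})

test_that("the exact HWE p-value agrees with the direct-factorial oracle", {
  # exhaustive over all configurations with n <= 30
  for (n in 1:30) {
    for (aa in 0:n) {
      for (ab in 0:(n - aa)) {
        bb <- n - aa - ab
        got <- hwe_exact_p(aa, ab, bb)
        want <- oracle_hwe_p(aa, ab, bb)
        expect_true(abs(got - want) <= 1e-12 * want,
          info = paste(aa, ab, bb)
        )
      }
    }
  }
})

test_that("the exact test approaches the chi-square test for large balanced counts", {
  cases <- list(c(1230, 2520, 1250), c(3550, 4430, 1420), c(820, 960, 220))
  for (cnt in cases) {
    n <- sum(cnt)
    p <- (cnt[2] + 2 * cnt[3]) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi <- sum((cnt - e)^2 / e)
    p_chi <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    expect_lt(abs(hwe_exact_p(cnt[1], cnt[2], cnt[3]) - p_chi), 0.05)
  }
})

test_that("QV-driven GWAS QC equals the hard-coded oracle and is idempotent", {
  sim <- sim_cohort(n_samples = 30, n_variants = 250, seed = 13, missing_rate = 0.05)
  m <- gt_matrix(sim$variants)

  # vacuous thresholds remove nothing
  qc0 <- apply_gwas_qc(qv_gwas_doc(0, 0, 0, 0), m)
  expect_identical(length(qc0$kept_samples), ncol(m))
  expect_identical(length(qc0$kept_variants), nrow(m))

  set.seed(51)
  for (i in 1:10) {
    thr <- list(
      scr = stats::runif(1, 0.85, 0.99), vcr = stats::runif(1, 0.85, 0.99),
      maf = stats::runif(1, 0, 0.1), hwe = 10^stats::runif(1, -8, -1)
    )
    doc <- qv_gwas_doc(thr$scr, thr$vcr, thr$maf, thr$hwe)
    qc <- apply_gwas_qc(doc, m)
    o <- oracle_gwas_qc(m, thr$scr, thr$vcr, thr$maf, thr$hwe)
    expect_identical(qc$kept_samples, o$kept_samples)
    expect_identical(qc$kept_variants, o$kept_variants)
    # re-running on its own output removes nothing further
    m2 <- m[qc$kept_variants, qc$kept_samples, drop = FALSE]
    if (length(qc$kept_variants) && length(qc$kept_samples)) {
      qc2 <- apply_gwas_qc(doc, m2)
      expect_identical(qc2$kept_variants, qc$kept_variants)
      expect_identical(qc2$kept_samples, qc$kept_samples)
    }
  }
})

test_that("a planted low-call-rate sample is removed exactly", {
  sim <- sim_cohort(n_samples = 12, n_variants = 150, seed = 17, missing_rate = 0)
  m <- gt_matrix(sim$variants)
  m[sample(nrow(m), 30), "S005"] <- NA # 20% missing in one sample
  qc <- apply_gwas_qc(qv_gwas_doc(0.95, 0, 0, 0), m)
  expect_identical(setdiff(colnames(m), qc$kept_samples), "S005")
})

test_that("GWAS QC requires every threshold field in the document", {
  doc <- qv_gwas_doc()
  doc$filters <- doc$filters[-4]
  m <- gt_matrix(sim_cohort(n_samples = 4, n_variants = 10, seed = 1)$variants)
  expect_error(apply_gwas_qc(doc, m), "HWE_P")
  qc <- apply_gwas_qc(qv_gwas_doc(), m)
  expect_s3_class(tidy(qc), "tbl_df")
  expect_identical(glance(qc)$n_steps, 4L)
  expect_s3_class(autoplot(qc), "ggplot")
})
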