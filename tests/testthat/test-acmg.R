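# ACMG-style criterion flags and compound-heterozygote detection.

test_that("annotation criteria evaluate from record annotations", {
  rec <- make_rec(
    gt = "0/1",
    CLASS = "P", GENE = "GENE001", popAF = 0.05,
    known_pathogenic_aa = TRUE, functional_evidence = FALSE
  )
  flags <- assign_acmg_criteria(rec)
  by_name <- function(nm) flags$flag[flags$criterion == nm][1]
  expect_true(by_name("ACMG_PS1"))
  expect_false(by_name("ACMG_PS3"))
  expect_false(by_name("ACMG_PM2")) # popAF 0.05 is not < 1e-4
  rare <- make_rec(
    gt = "0/1", CLASS = "VUS", GENE = "GENE001", popAF = 5e-6,
    known_pathogenic_aa = FALSE, functional_evidence = TRUE
  )
  flags2 <- assign_acmg_criteria(rare)
  expect_true(flags2$flag[flags2$criterion == "ACMG_PM2"][1])
  expect_true(flags2$flag[flags2$criterion == "ACMG_PS3"][1])
})

test_that("PS2/PS4 are reported as not applicable, never silently false", {
  flags <- assign_acmg_criteria(make_rec(
    gt = "0/1", CLASS = "B", GENE = "G", popAF = 0.1,
    known_pathogenic_aa = FALSE, functional_evidence = FALSE
  ))
  for (nm in c("ACMG_PS2", "ACMG_PS4")) {
    rows <- flags[flags$criterion == nm, ]
    expect_identical(nrow(rows), 1L)
    expect_true(is.na(rows$flag))
    expect_match(rows$evidence, "not applicable")
  }
})

make_gene_table <- function(gts, genes, classes = NULL) {
  n <- length(genes)
  samples <- lapply(seq_len(n), function(i) {
    tibble::tibble(sample = sprintf("S%d", seq_along(gts[[i]])), GT = gts[[i]],
      DP = NA_real_, GQ = NA_real_)
  })
  tibble::tibble(
    chrom = "chr1", pos = 100L + seq_len(n), id = NA_character_,
    ref = "A", alt = "T", qual = 50, filter = NA_character_,
    info = rep(list(list()), n), samples = samples,
    GENE = genes, CLASS = classes %||% rep("VUS", n),
    popAF = 0.01, known_pathogenic_aa = FALSE, functional_evidence = FALSE
  )
}

test_that("compound heterozygotes are all unordered het pairs per sample and gene", {
  # two het loci in one gene: one pair, both partners flagged
  tbl <- make_gene_table(list(c("0/1"), c("0/1")), c("GENE1", "GENE1"))
  ch <- detect_compound_het(tbl)
  expect_identical(nrow(ch), 1L)
  flags <- assign_acmg_criteria(tbl)
  ps5 <- flags[flags$criterion == "ACMG_PS5", ]
  expect_identical(sum(ps5$flag), 2L)

  # a single het locus has no partner
  expect_identical(nrow(detect_compound_het(make_gene_table(
    list(c("0/1")), "GENE1"
  ))), 0L)

  # hom-alt and missing genotypes never pair
  tbl2 <- make_gene_table(list("1/1", "0/1", NA_character_), rep("GENE1", 3))
  expect_identical(nrow(detect_compound_het(tbl2)), 0L)
})

test_that("k het loci per gene yield choose(k, 2) pairs, matching a double loop", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 30
    genes <- sample(sprintf("G%d", 1:4), n, replace = TRUE)
    gts <- lapply(seq_len(n), function(i) {
      sample(c("0/0", "0/1", "1/1", NA), 2, replace = TRUE, prob = c(.3, .45, .15, .1))
    })
    tbl <- make_gene_table(gts, genes)
    got <- detect_compound_het(tbl)
    # brute-force double loop, independent of the implementation
    want <- 0L
    for (s in 1:2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          hi <- !is.na(gts[[i]][s]) && gts[[i]][s] == "0/1"
          hj <- !is.na(gts[[j]][s]) && gts[[j]][s] == "0/1"
          if (hi && hj && genes[i] == genes[j]) want <- want + 1L
        }
      }
    }
    expect_identical(nrow(got), want)
    # per (sample, gene): flagged partner count is never exactly 1
    per <- table(paste(got$sample, got$gene))
    partners <- tapply(
      c(got$key_a, got$key_b), paste(c(got$sample, got$sample), c(got$gene, got$gene)),
      function(x) length(unique(x))
    )
    expect_true(all(partners >= 2))
  }
})

test_that("PM3 requires a pathogenic partner in the same gene", {
  tbl <- make_gene_table(
    list("0/1", "0/1", "0/1"),
    c("GENE1", "GENE1", "GENE2"),
    classes = c("VUS", "P", "P")
  )
  flags <- assign_acmg_criteria(tbl)
  pm3 <- flags[flags$criterion == "ACMG_PM3", ]
  key <- function(i) paste("chr1", 100 + i, "A", "T", sep = ":")
  flag_of <- function(i) pm3$flag[paste(pm3$chrom, pm3$pos, pm3$ref, pm3$alt, sep = ":") == key(i)]
  expect_true(flag_of(1)) # partner (locus 2) is P
  expect_false(flag_of(2)) # partner (locus 1) is VUS
  expect_false(flag_of(3)) # no partner in GENE2
})

test_that("phase-aware mode only counts phased trans pairs", {
  cis <- make_gene_table(list("0|1", "0|1"), c("G", "G"))
  trans <- make_gene_table(list("0|1", "1|0"), c("G", "G"))
  unphased <- make_gene_table(list("0/1", "0/1"), c("G", "G"))
  expect_identical(nrow(detect_compound_het(cis, require_phase = TRUE)), 0L)
  expect_identical(nrow(detect_compound_het(trans, require_phase = TRUE)), 1L)
  expect_identical(nrow(detect_compound_het(unphased, require_phase = TRUE)), 0L)
  expect_identical(nrow(detect_compound_het(unphased, require_phase = FALSE)), 1L)
})

test_that("flags are reproducible and match a hard-coded per-criterion check", {
  sim <- sim_cohort(n_samples = 6, n_variants = 150, seed = 23)
  f1 <- assign_acmg_criteria(sim$variants)
  f2 <- assign_acmg_criteria(sim$variants)
  expect_identical(f1, f2)
  v <- sim$variants
  expect_identical(
    f1$flag[f1$criterion == "ACMG_PS1"],
    unname(v$known_pathogenic_aa)
  )
  expect_identical(
    f1$flag[f1$criterion == "ACMG_PM2"],
    unname(v$popAF < 1e-4)
  )
  score <- acmg_score(f1)
  expect_identical(nrow(score), nrow(v))
  expect_true(all(score$score >= 0))
})
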