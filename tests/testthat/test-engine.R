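# Field resolution, tri-state evaluation, aggregation, and the apply pipeline.

test_that("fields resolve across all declared namespaces", {
  rec <- make_rec(
    qual = 51.3, info = list(DP = 60, AF = 0.01),
    gt = c("0/1", "0/0"), dp = c(10, 20), gq = c(99, NA),
    CLASS = "LP", popAF = 2e-5
  )
  expect_identical(resolve_field(rec, "QUAL"), 51.3)
  expect_identical(resolve_field(rec, "INFO/AF"), 0.01)
  expect_identical(resolve_field(rec, "FORMAT/DP", sample = "S2"), 20)
  expect_true(is.na(resolve_field(rec, "FORMAT/GQ", sample = "S2")))
  expect_identical(resolve_field(rec, "CLASS"), "LP")
  expect_error(resolve_field(rec, "NOPE"), "unknown field")
  expect_error(resolve_field(rec, "FORMAT/DP"), "requires a sample")
  idx <- region_index(tibble::tibble(chrom = "chr1", start = 90L, end = 110L))
  expect_identical(
    resolve_field(rec, "OVERLAP(panel.bed)", regions = list(`panel.bed` = idx)),
    1L
  )
})

test_that("site depth prefers INFO/DP and falls back to summed FORMAT/DP", {
  with_info <- make_rec(info = list(DP = 60), gt = rep("0/1", 3), dp = c(10, 10, 10))
  without <- make_rec(info = list(), gt = rep("0/1", 3), dp = c(10, 20, NA))
  none <- make_rec(info = list(), gt = rep("0/1", 2), dp = c(NA, NA))
  expect_identical(site_depth(with_info), 60)
  expect_identical(site_depth(without), 30)
  expect_true(is.na(site_depth(none)))
  # INFO/DP conditions see the computed site depth
  expect_identical(resolve_field(without, "INFO/DP"), 30)
})

test_that("condition evaluation is tri-state with genotype exclusion dominating", {
  rec <- make_rec(
    qual = 51.3, gt = c(NA, "0/1"), dp = c(40, 40), gq = c(99, 15),
    CLASS = "VUS"
  )
  expect_identical(eval_condition(qv_condition("QUAL", ">=", 30), rec), "pass")
  expect_identical(eval_condition(qv_condition("QUAL", ">", 60), rec), "fail")
  # sample S1 has DP=40 but a missing genotype: missing wins
  expect_identical(
    eval_condition(qv_condition("FORMAT/DP", ">=", 10), rec, sample = "S1"),
    "missing"
  )
  expect_identical(
    eval_condition(qv_condition("FORMAT/DP", ">=", 10), rec, sample = "S2"),
    "pass"
  )
  expect_identical(
    eval_group(qv_group("any_of", list(
      qv_condition("CLASS", "==", "P"), qv_condition("CLASS", "==", "LP")
    )), rec),
    "fail"
  )
  expect_identical(
    eval_condition(qv_condition("CLASS", "in", c("VUS", "LB")), rec), "pass"
  )
  qual_missing <- make_rec(qual = NA)
  expect_identical(
    eval_condition(qv_condition("QUAL", ">=", 30), qual_missing), "missing"
  )
  expect_error(
    eval_condition(qv_condition("CLASS", ">=", 30), rec),
    "type-incomparable"
  )
})

test_that("group logic matches the exhaustive three-valued truth table up to k = 4", {
  states <- c("pass", "fail", "missing")
  for (k in 1:4) {
    grid <- do.call(expand.grid, c(rep(list(states), k), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      assignment <- unlist(grid[i, ], use.names = FALSE)
      fx <- state_fixture(assignment)
      for (mode in c("any_of", "all_of")) {
        expect_identical(
          eval_group(qv_group(mode, fx$conds), fx$rec),
          kleene_combine(mode, assignment),
          info = paste(mode, paste(assignment, collapse = ","))
        )
      }
    }
  }
})

test_that("nested random groups agree with a recursive Kleene oracle", {
  set.seed(4)
  random_tree <- function(depth, leaf_states) {
    if (depth == 0 || stats::runif(1) < 0.4) {
      i <- sample(length(leaf_states), 1)
      return(list(
        node = qv_condition(paste0("s", i), "==", 1),
        state = leaf_states[i]
      ))
    }
    mode <- sample(c("any_of", "all_of"), 1)
    kids <- lapply(seq_len(sample(2:3, 1)), function(j) {
      random_tree(depth - 1, leaf_states)
    })
    list(
      node = qv_group(mode, lapply(kids, `[[`, "node")),
      state = kleene_combine(mode, vapply(kids, `[[`, "", "state"))
    )
  }
  for (rep in 1:40) {
    leaf_states <- sample(c("pass", "fail", "missing"), 4, replace = TRUE)
    fx <- state_fixture(leaf_states)
    tree <- random_tree(3, leaf_states)
    expect_identical(eval_group(tree$node, fx$rec), tree$state)
  }
})

test_that("filter aggregation across samples follows all/any with missing non-pass", {
  rec <- make_rec(gt = c("0/1", "0/1", NA), gq = c(10, 35, 50))
  rule <- function(agg) {
    qv_filter("gq", "keep_if", qv_condition("FORMAT/GQ", ">=", 20),
      sample_aggregation = agg
    )
  }
  expect_identical(eval_filter(rule("any_sample"), rec), "keep")
  expect_identical(eval_filter(rule("all_samples"), rec), "drop")
  # default aggregation is all_samples
  expect_identical(eval_filter(qv_filter("gq", "keep_if",
    qv_condition("FORMAT/GQ", ">=", 20)
  ), rec), "drop")
  # missing site operand: keep_if drops, drop_if retains
  qm <- make_rec(qual = NA)
  expect_identical(eval_filter(qv_filter("q", "keep_if", qv_condition("QUAL", ">=", 30)), qm), "drop")
  expect_identical(eval_filter(qv_filter("q", "drop_if", qv_condition("QUAL", ">=", 30)), qm), "keep")
})

test_that("apply_qv pipelines filters conjunctively and only flags criteria", {
  sim <- sim_cohort(n_samples = 8, n_variants = 120, seed = 5)
  # empty filter list: identity pipeline, flags still computed
  doc0 <- qv_file(
    meta = minimal_meta(),
    criteria = list(qv_criterion("pathogenic", "or", list(
      qv_condition("CLASS", "==", "P"), qv_condition("CLASS", "==", "LP")
    )))
  )
  res0 <- apply_qv(doc0, sim$variants)
  expect_identical(nrow(res0$kept), nrow(sim$variants))
  expect_identical(
    sum(res0$flags$flag),
    sum(sim$variants$CLASS %in% c("P", "LP"))
  )

  doc <- qv_file(
    meta = minimal_meta(),
    filters = list(
      qv_filter("qual", "keep_if", qv_condition("QUAL", ">=", 30)),
      qv_filter("common", "drop_if", qv_condition("popAF", ">", 0.2)),
      qv_filter("depth", "keep_if", qv_condition("INFO/DP", ">=", 100))
    )
  )
  res <- apply_qv(doc, sim$variants)
  expect_true(all(res$summary$evaluated == res$summary$kept + res$summary$dropped))
  expect_true(all(res$summary$dropped_missing <= res$summary$dropped))

  # idempotence: reapplying to its own output changes nothing
  res2 <- apply_qv(doc, res$kept)
  expect_identical(res2$kept, res$kept)
  expect_identical(sum(res2$summary$dropped), 0L)

  # the kept SET is invariant under filter permutation
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    docp <- doc
    docp$filters <- doc$filters[perm]
    expect_setequal(
      paste(res$kept$chrom, res$kept$pos),
      with(apply_qv(docp, sim$variants)$kept, paste(chrom, pos))
    )
  }
})

test_that("raising a keep_if threshold never enlarges the kept set", {
  sim <- sim_cohort(n_samples = 6, n_variants = 150, seed = 9)
  prev <- NULL
  for (thr in c(10, 30, 50, 80)) {
    doc <- qv_file(
      meta = minimal_meta(),
      filters = list(qv_filter("qual", "keep_if", qv_condition("QUAL", ">=", thr)))
    )
    kept <- apply_qv(doc, sim$variants)$kept
    keys <- paste(kept$chrom, kept$pos)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("invalid documents and unknown fields abort with informative errors", {
  sim <- sim_cohort(n_samples = 3, n_variants = 10, seed = 2)
  bad <- qv_file(
    meta = minimal_meta(),
    filters = list(qv_filter("f", "keep_maybe", qv_condition("QUAL", ">=", 1)))
  )
  expect_error(apply_qv(bad, sim$variants), "invalid QV document")
  doc <- qv_file(
    meta = minimal_meta(),
    filters = list(qv_filter("f", "keep_if", qv_condition("NOT_A_FIELD", "==", 1)))
  )
  expect_error(apply_qv(doc, sim$variants), "rule.*NOT_A_FIELD")
  doc2 <- qv_file(
    meta = minimal_meta(),
    filters = list(qv_filter(
      "f", "keep_if",
      qv_condition("OVERLAP(absent.bed)", ">=", 1)
    ))
  )
  expect_error(apply_qv(doc2, sim$variants), "no region index")
})

test_that("tidiers and autoplot summarize apply results", {
  sim <- sim_cohort(n_samples = 5, n_variants = 60, seed = 6)
  doc <- qv_file(
    meta = minimal_meta(),
    filters = list(qv_filter("qual", "keep_if", qv_condition("QUAL", ">=", 30))),
    criteria = list(qv_criterion("rare", "and", list(qv_condition("popAF", "<", 0.01))))
  )
  res <- apply_qv(doc, sim$variants)
  td <- tidy(res)
  expect_identical(td$rule, "qual")
  gl <- glance(res)
  expect_identical(gl$n_kept, nrow(res$kept))
  expect_s3_class(autoplot(res), "ggplot")
  rules <- tidy(doc)
  expect_identical(nrow(rules), 2L)
  expect_setequal(rules$component, c("filter", "criterion"))
})
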