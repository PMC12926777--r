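# Cohort-level QC: call rates, minor allele frequency, exact Hardy-Weinberg
# test, and the QV-driven GWAS QC chain.

#' Call rate per sample or per variant
#'
#' Fraction of non-missing genotype calls along the chosen axis.
#'
#' @param m Genotype dosage matrix (variants x samples; `NA` = missing), as
#'   from [gt_matrix()].
#' @param axis `"sample"` (columns) or `"variant"` (rows).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
call_rate <- function(m, axis = c("sample", "variant")) {
  axis <- match.arg(axis)
  if (!nrow(m) || !ncol(m)) stop("empty genotype matrix", call. = FALSE)
  if (axis == "sample") colMeans(!is.na(m)) else rowMeans(!is.na(m))
}

#' Genotype counts per variant
#'
#' @param m Genotype dosage matrix.
#' @return Tibble with `n_homref`, `n_het`, `n_homalt` per variant (missing
#'   calls excluded).
#' @export
geno_counts <- function(m) {
  tibble::tibble(
    n_homref = rowSums(m == 0L, na.rm = TRUE),
    n_het = rowSums(m == 1L, na.rm = TRUE),
    n_homalt = rowSums(m == 2L, na.rm = TRUE)
  )
}

#' Minor allele frequency from genotype counts
#'
#' `min(p, 1 - p)` with `p = (n_het + 2 n_homalt) / (2 total)` over called
#' genotypes. Vectorized; a total of zero yields `NA`.
#'
#' @param n_homref,n_het,n_homalt Called genotype counts.
#' @return Numeric vector of MAFs.
#' @examples
#' maf(1, 1, 1) # 0.5
#' maf(10, 0, 0) # monomorphic: 0
#' @export
maf <- function(n_homref, n_het, n_homalt) {
  total <- n_homref + n_het + n_homalt
  p <- (n_het + 2 * n_homalt) / (2 * total)
  out <- pmin(p, 1 - p)
  out[total == 0] <- NA_real_
  out
}

#' Conditional distribution of heterozygote counts under Hardy-Weinberg
#'
#' Given `n` called genotypes and `n_a` copies of one allele, heterozygote
#' counts compatible with the allele counts follow the standard conditional
#' (Levene) distribution. Probabilities are computed with a ratio recurrence
#' anchored at the distribution mode (no factorials, numerically stable), then
#' normalized. The exact-test p-value of each configuration is the sum of
#' probabilities of all configurations no more probable than it (ties included
#' with a relative tolerance of 1e-9).
#'
#' @param n Number of called genotypes (>= 1).
#' @param n_a Count of one allele (0..2n); the distribution is symmetric in
#'   the two alleles.
#' @return Tibble with columns `n_het`, `prob`, `p_value`, covering every
#'   attainable heterozygote count.
#' @export
hwe_het_distribution <- function(n, n_a) {
  stopifnot(length(n) == 1, length(n_a) == 1)
  if (n < 1 || n_a < 0 || n_a > 2 * n) {
    stop("need n >= 1 and 0 <= n_a <= 2n", call. = FALSE)
  }
  n_b <- 2L * n - n_a
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  k <- length(hets)
  probs <- numeric(k)
  # mode of the conditional distribution
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, hets[1]), rare)
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # products of the two homozygote counts are grouped so the recursion is
  # bit-identical under allele relabeling (n_aa and n_bb swap)
  if (i_mid < k) {
    for (i in i_mid:(k - 1)) {
      h <- hets[i]
      n_aa <- (n_a - h) / 2
      n_bb <- (n_b - h) / 2
      probs[i + 1] <- probs[i] * (4 * (n_aa * n_bb)) / ((h + 1) * (h + 2))
    }
  }
  if (i_mid > 1) {
    for (i in i_mid:2) {
      h <- hets[i]
      n_aa <- (n_a - h) / 2
      n_bb <- (n_b - h) / 2
      probs[i - 1] <- probs[i] * (h * (h - 1)) / (4 * ((n_aa + 1) * (n_bb + 1)))
    }
  }
  probs <- probs / sum(probs)
  # p-value: total probability of configurations with prob <= observed
  sp <- sort(probs)
  cum <- cumsum(sp)
  p <- cum[findInterval(probs * (1 + 1e-9), sp)]
  tibble::tibble(n_het = hets, prob = probs, p_value = pmin(1, p))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test p-value from called genotype counts: the sum of the conditional
#' probabilities (given allele counts) of all heterozygote configurations no
#' more probable than the observed one. Monomorphic counts give p = 1. The
#' test is symmetric under allele relabeling. Vectorized over configurations.
#'
#' @param n_homref,n_het,n_homalt Called genotype counts (non-negative).
#' @return Numeric vector of p-values in `(0, 1]`; `NA` where no genotypes
#'   were called.
#' @examples
#' hwe_exact_p(50, 21, 29)
#' hwe_exact_p(10, 0, 0) # monomorphic: 1
#' @export
hwe_exact_p <- function(n_homref, n_het, n_homalt) {
  if (any(c(n_homref, n_het, n_homalt) < 0, na.rm = TRUE)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  mapply(function(aa, ab, bb) {
    if (anyNA(c(aa, ab, bb))) {
      return(NA_real_)
    }
    n <- aa + ab + bb
    if (n == 0) {
      return(NA_real_)
    }
    dist <- hwe_het_distribution(n, 2L * aa + ab)
    dist$p_value[match(ab, dist$n_het)]
  }, n_homref, n_het, n_homalt, USE.NAMES = FALSE)
}

#' Build a QV document encoding standard GWAS QC thresholds
#'
#' Filters over the derived per-axis statistics `SAMPLE_CALL_RATE`,
#' `VARIANT_CALL_RATE`, `MAF`, and `HWE_P`, as consumed by [apply_gwas_qc()].
#'
#' @param sample_call_rate,variant_call_rate Minimum call-rate fractions.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum exact HWE p-value.
#' @param qv_set_id,title,version Document metadata.
#' @return A `qv_file`.
#' @export
qv_gwas_doc <- function(sample_call_rate = 0.95, variant_call_rate = 0.95,
                        maf_min = 0.01, hwe_p_min = 1e-6,
                        qv_set_id = "qv_gwas_qc_v1_20250828",
                        title = "GWAS quality control", version = "1.0.0") {
  qv_file(
    meta = list(qv_set_id = qv_set_id, title = title, version = version),
    filters = list(
      qv_filter(
        "sample_call_rate", "keep_if",
        qv_condition("SAMPLE_CALL_RATE", ">=", sample_call_rate)
      ),
      qv_filter(
        "variant_call_rate", "keep_if",
        qv_condition("VARIANT_CALL_RATE", ">=", variant_call_rate)
      ),
      qv_filter("maf", "keep_if", qv_condition("MAF", ">=", maf_min)),
      qv_filter("hwe", "keep_if", qv_condition("HWE_P", ">=", hwe_p_min))
    )
  )
}

qc_fields <- c(
  sample_call_rate = "SAMPLE_CALL_RATE",
  variant_call_rate = "VARIANT_CALL_RATE",
  maf = "MAF",
  hwe = "HWE_P"
)

qc_rule_for <- function(doc, field) {
  for (f in doc$filters) {
    if (inherits(f$condition, "qv_condition") && f$condition$field == field) {
      return(f)
    }
  }
  stop("QV document defines no filter on required QC field ", dQuote(field),
    call. = FALSE
  )
}

#' Apply QV-defined GWAS QC to a genotype matrix
#'
#' Steps run in the standard order -- sample call rate, then variant call
#' rate, minor allele frequency, and Hardy-Weinberg equilibrium -- with
#' variant statistics recomputed on the samples surviving step one. The QV
#' document must define one filter per derived field `SAMPLE_CALL_RATE`,
#' `VARIANT_CALL_RATE`, `MAF`, `HWE_P` (see [qv_gwas_doc()]).
#'
#' @param doc A `qv_file` with the four QC filters.
#' @param m Genotype dosage matrix (variants x samples) from [gt_matrix()].
#' @return A `qv_qc` object: `kept_samples`, `kept_variants`, and a `steps`
#'   tibble of per-step counts.
#' @export
apply_gwas_qc <- function(doc, m) {
  stopifnot(inherits(doc, "qv_file"), is.matrix(m))
  rules <- lapply(qc_fields, qc_rule_for, doc = doc)
  pass_rule <- function(rule, vals) {
    state <- compare_outcome(rule$condition$operator, vals, rule$condition$value)
    pass <- state == "pass"
    if (identical(rule$logic, "drop_if")) !pass else pass
  }
  steps <- list()
  note_step <- function(step, axis, rule, before, after) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = step, axis = axis, field = rule$condition$field,
      operator = rule$condition$operator,
      threshold = as.numeric(rule$condition$value),
      n_before = before, n_removed = before - after, n_after = after
    )
  }

  # a fully emptied axis yields zero call rates rather than an error
  rate_or_zero <- function(m, axis) {
    k <- if (axis == "sample") ncol(m) else nrow(m)
    if (!nrow(m) || !ncol(m)) {
      return(rep(0, k))
    }
    call_rate(m, axis)
  }
  keep_s <- pass_rule(rules$sample_call_rate, rate_or_zero(m, "sample"))
  m1 <- m[, keep_s, drop = FALSE]
  note_step("sample_call_rate", "sample", rules$sample_call_rate, ncol(m), ncol(m1))

  keep_v <- pass_rule(rules$variant_call_rate, rate_or_zero(m1, "variant"))
  m2 <- m1[keep_v, , drop = FALSE]
  note_step("variant_call_rate", "variant", rules$variant_call_rate, nrow(m1), nrow(m2))

  gc2 <- geno_counts(m2)
  mafs <- maf(gc2$n_homref, gc2$n_het, gc2$n_homalt)
  keep_m <- pass_rule(rules$maf, mafs)
  keep_m[is.na(mafs)] <- FALSE
  m3 <- m2[keep_m, , drop = FALSE]
  note_step("maf", "variant", rules$maf, nrow(m2), nrow(m3))

  gc3 <- geno_counts(m3)
  hwe <- hwe_exact_p(gc3$n_homref, gc3$n_het, gc3$n_homalt)
  keep_h <- pass_rule(rules$hwe, hwe)
  keep_h[is.na(hwe)] <- FALSE
  m4 <- m3[keep_h, , drop = FALSE]
  note_step("hwe", "variant", rules$hwe, nrow(m3), nrow(m4))

  sample_ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  variant_ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  structure(
    list(
      kept_samples = sample_ids[keep_s],
      kept_variants = variant_ids[keep_v][keep_m][keep_h],
      steps = dplyr::bind_rows(steps)
    ),
    class = "qv_qc"
  )
}

#' @export
print.qv_qc <- function(x, ...) {
  cat("<qv_qc> ", length(x$kept_samples), " samples, ",
    length(x$kept_variants), " variants kept\n",
    sep = ""
  )
  print(x$steps)
  invisible(x)
}
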