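# Clean-room oracle filters: directly hard-coded implementations of the
# validation scenarios, sharing no evaluation code with the QV engine or the
# QC module. Deliberately plain base-R loops, so that record-identical
# agreement between the engine and this path is a meaningful equivalence
# check, not a tautology.

#' Hard-coded panel-overlap filter (oracle)
#'
#' Keeps records whose reference span intersects at least `min_overlap`
#' intervals, using its own 1-based/0-based coordinate arithmetic and a plain
#' scan over the interval list.
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`).
#' @param intervals Data frame of BED intervals (`chrom`, `start` 0-based,
#'   `end` exclusive).
#' @param min_overlap Minimum number of overlapping intervals.
#' @return Logical keep vector.
#' @export
oracle_panel_filter <- function(variants, intervals, min_overlap = 1) {
  n <- nrow(variants)
  keep <- logical(n)
  for (i in seq_len(n)) {
    span_lo <- variants$pos[i]
    span_hi <- variants$pos[i] + max(1L, nchar(variants$ref[i])) - 1L
    cnt <- 0L
    for (j in seq_len(nrow(intervals))) {
      if (variants$chrom[i] != intervals$chrom[j]) next
      iv_lo <- intervals$start[j] + 1L # BED start is 0-based
      iv_hi <- intervals$end[j] # BED end is exclusive == 1-based inclusive end
      if (span_lo <= iv_hi && span_hi >= iv_lo) cnt <- cnt + 1L
    }
    keep[i] <- cnt >= min_overlap
  }
  keep
}

#' Hard-coded pathogenicity-class flag (oracle)
#'
#' @param variants Variant table with a `CLASS` column.
#' @param classes Flagging classes.
#' @return Logical flag vector.
#' @export
oracle_class_flags <- function(variants, classes = c("P", "LP")) {
  flags <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    flags[i] <- !is.na(variants$CLASS[i]) && variants$CLASS[i] %in% classes
  }
  flags
}

#' Hard-coded trio quality filter (oracle)
#'
#' Site thresholds on QUAL and site depth (INFO/DP, falling back to the sum of
#' per-sample FORMAT/DP), and per-sample thresholds on FORMAT/DP and FORMAT/GQ
#' with missing genotypes excluded, aggregated across samples with
#' all-samples-pass or any-sample-pass logic. Any missing operand fails the
#' test it feeds.
#'
#' @param variants Variant table.
#' @param min_qual,min_site_dp Site-level minimums (`NULL` to skip).
#' @param min_dp,min_gq Per-sample minimums (`NULL` to skip the per-sample
#'   stage).
#' @param aggregation `"all_samples"` or `"any_sample"`.
#' @return Logical keep vector.
#' @export
oracle_trio_filter <- function(variants, min_qual = NULL, min_site_dp = NULL,
                               min_dp = NULL, min_gq = NULL,
                               aggregation = "all_samples") {
  n <- nrow(variants)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (!is.null(min_qual)) {
      q <- variants$qual[i]
      ok <- ok && !is.na(q) && q >= min_qual
    }
    if (ok && !is.null(min_site_dp)) {
      sdp <- variants$info[[i]][["DP"]]
      if (is.null(sdp)) {
        dps <- variants$samples[[i]]$DP
        sdp <- if (all(is.na(dps))) NA_real_ else sum(dps, na.rm = TRUE)
      }
      ok <- ok && !is.na(sdp) && sdp >= min_site_dp
    }
    if (ok && (!is.null(min_dp) || !is.null(min_gq))) {
      s <- variants$samples[[i]]
      sample_pass <- logical(nrow(s))
      for (j in seq_len(nrow(s))) {
        gt <- s$GT[j]
        if (is.na(gt) || grepl(".", gt, fixed = TRUE)) {
          sample_pass[j] <- FALSE # missing genotype is excluded
          next
        }
        p <- TRUE
        if (!is.null(min_dp)) p <- p && !is.na(s$DP[j]) && s$DP[j] >= min_dp
        if (!is.null(min_gq)) p <- p && !is.na(s$GQ[j]) && s$GQ[j] >= min_gq
        sample_pass[j] <- p
      }
      ok <- ok && if (aggregation == "any_sample") {
        any(sample_pass)
      } else {
        all(sample_pass)
      }
    }
    keep[i] <- ok
  }
  keep
}

#' Exact Hardy-Weinberg p-value by direct factorial evaluation (oracle)
#'
#' Independent of [hwe_exact_p()]: enumerates every attainable heterozygote
#' count and evaluates the conditional probability of each directly through
#' log-factorials (`lgamma`), then sums the probabilities no greater than the
#' observed configuration's (ties within a relative 1e-9).
#'
#' @param n_homref,n_het,n_homalt Called genotype counts (scalars).
#' @return Exact-test p-value.
#' @export
oracle_hwe_p <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  if (n == 0) {
    return(NA_real_)
  }
  n_a <- 2 * n_homref + n_het
  n_b <- 2 * n - n_a
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log weight of each configuration; the h-independent factorial terms
  # (n!, n_a!, n_b!, (2n)!) cancel in the normalized distribution
  logw <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    h * log(2) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1)
  }, numeric(1))
  probs <- exp(logw - max(logw))
  probs <- probs / sum(sort(probs))
  obs <- probs[match(n_het, hets)]
  min(1, sum(sort(probs[probs <= obs * (1 + 1e-9)])))
}

#' Hard-coded GWAS QC chain (oracle)
#'
#' Sample call rate, then variant call rate, minor allele frequency and exact
#' Hardy-Weinberg equilibrium on the surviving samples, all recomputed with
#' local loops and [oracle_hwe_p()].
#'
#' @param m Genotype dosage matrix (variants x samples).
#' @param sample_call_rate,variant_call_rate,maf_min,hwe_p_min Thresholds
#'   (values below the minimum are removed; HWE removes p < `hwe_p_min`).
#' @return List with `kept_samples` and `kept_variants` (names).
#' @export
oracle_gwas_qc <- function(m, sample_call_rate = 0.95, variant_call_rate = 0.95,
                           maf_min = 0.01, hwe_p_min = 1e-6) {
  sample_ids <- if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m)
  variant_ids <- if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m)
  scr <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) scr[j] <- mean(!is.na(m[, j]))
  m <- m[, scr >= sample_call_rate, drop = FALSE]
  sample_ids <- sample_ids[scr >= sample_call_rate]

  vcr <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    vcr[i] <- if (ncol(m)) mean(!is.na(m[i, ])) else 0
  }
  m <- m[vcr >= variant_call_rate, , drop = FALSE]
  variant_ids <- variant_ids[vcr >= variant_call_rate]

  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    g <- m[i, ]
    g <- g[!is.na(g)]
    if (!length(g)) {
      keep[i] <- FALSE
      next
    }
    p <- sum(g) / (2 * length(g))
    keep[i] <- min(p, 1 - p) >= maf_min
  }
  m <- m[keep, , drop = FALSE]
  variant_ids <- variant_ids[keep]

  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    g <- m[i, ]
    g <- g[!is.na(g)]
    p <- oracle_hwe_p(sum(g == 0), sum(g == 1), sum(g == 2))
    keep[i] <- !is.na(p) && p >= hwe_p_min
  }
  variant_ids <- variant_ids[keep]
  list(kept_samples = sample_ids, kept_variants = variant_ids)
}
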