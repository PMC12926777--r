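# ACMG-style criterion flags. Annotation-driven criteria (PS1, PS3, PM2) are
# ordinary QV criteria evaluated by the engine; compound heterozygosity
# (PS5, and PM3 when the partner is pathogenic) is the one relational
# computation and is implemented here directly.

#' Default ACMG-style criteria as QV criterion objects
#'
#' PS1 (known pathogenic amino-acid change) and PS3 (supporting functional
#' evidence) read logical annotation columns; PM2 (rare in population
#' references) compares the population allele frequency against a threshold.
#' PS5/PM3 are relational (compound heterozygosity) and handled by
#' [detect_compound_het()]; PS2/PS4 are recognized names that evaluate to
#' not-applicable.
#'
#' @param pm2_max_af PM2 population-frequency threshold (flag set when the
#'   frequency is strictly below it).
#' @param af_field Annotation column holding the population allele frequency.
#' @return Named list of `qv_criterion` objects.
#' @export
acmg_criteria <- function(pm2_max_af = 1e-4, af_field = "popAF") {
  list(
    ACMG_PS1 = qv_criterion(
      "ACMG_PS1", "and",
      list(qv_condition("known_pathogenic_aa", "==", TRUE)),
      description = "Known pathogenic amino acid change"
    ),
    ACMG_PS3 = qv_criterion(
      "ACMG_PS3", "and",
      list(qv_condition("functional_evidence", "==", TRUE)),
      description = "Supporting functional evidence"
    ),
    ACMG_PM2 = qv_criterion(
      "ACMG_PM2", "and",
      list(qv_condition(af_field, "<", pm2_max_af)),
      description = "Absent or very rare in population references"
    )
  )
}

acmg_not_applicable <- c("ACMG_PS2", "ACMG_PS4")

#' Evaluate one annotation-driven criterion on a variant table
#'
#' @param criterion A `qv_criterion` whose conditions reference annotation
#'   columns present on `variants`.
#' @param variants A variant table.
#' @return Tibble with one row per variant: keys, `criterion`, `state`,
#'   `flag`.
#' @export
assign_annotation_criterion <- function(criterion, variants) {
  stopifnot(inherits(criterion, "qv_criterion"))
  grp <- qv_group(
    if (identical(criterion$logic, "or")) "any_of" else "all_of",
    criterion$conditions
  )
  state <- eval_tree_vec(grp, eval_ctx(tibble::as_tibble(variants)))
  evidence_text <- criterion$description %||% criterion$name
  tibble::tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    sample = NA_character_, criterion = criterion$name,
    state = state, flag = state == "pass",
    evidence = ifelse(state == "pass", evidence_text, NA_character_)
  )
}

#' Detect compound-heterozygous variant pairs
#'
#' For each sample and gene, every unordered pair of distinct loci at which
#' the sample is heterozygous. Phase is assumed trans for unphased genotypes;
#' with `require_phase = TRUE` (e.g. when parental phasing from a trio is
#' available) only phased pairs with the alternate allele on opposite
#' haplotypes are reported.
#'
#' @param variants A variant table with a `GENE` annotation column and
#'   per-sample `GT`.
#' @param require_phase Only count phased trans pairs.
#' @return Tibble with columns `sample`, `gene`, `key_a`, `key_b`
#'   (`chrom:pos:ref:alt` keys, `key_a` < `key_b` by table order).
#' @export
detect_compound_het <- function(variants, require_phase = FALSE) {
  if (!"GENE" %in% names(variants)) {
    stop("detect_compound_het requires a GENE annotation column", call. = FALSE)
  }
  n <- nrow(variants)
  keys <- variant_key(variants)
  ids <- if (n) variants$samples[[1]]$sample else character()
  gt <- matrix(NA_character_, nrow = n, ncol = length(ids))
  for (i in seq_len(n)) gt[i, ] <- variants$samples[[i]]$GT
  out <- list()
  for (j in seq_along(ids)) {
    g <- gt[, j]
    het <- !is.na(g) & g %in% c("0/1", "1/0", "0|1", "1|0")
    idx <- which(het & !is.na(variants$GENE))
    if (length(idx) < 2) next
    for (gene in unique(variants$GENE[idx])) {
      gi <- idx[variants$GENE[idx] == gene]
      if (length(gi) < 2) next
      pairs <- utils::combn(gi, 2)
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1, p]
        b <- pairs[2, p]
        if (require_phase) {
          phased <- g[a] %in% c("0|1", "1|0") && g[b] %in% c("0|1", "1|0")
          if (!phased || g[a] == g[b]) next
        }
        out[[length(out) + 1]] <- tibble::tibble(
          sample = ids[j], gene = gene, key_a = keys[a], key_b = keys[b]
        )
      }
    }
  }
  dplyr::bind_rows(
    tibble::tibble(
      sample = character(), gene = character(),
      key_a = character(), key_b = character()
    ),
    out
  )
}

#' Assign ACMG-style criterion flags to a variant table
#'
#' Annotation criteria (PS1, PS3, PM2) are evaluated through the QV engine;
#' PS5 flags both partners of each compound-heterozygous pair; PM3 flags a
#' variant (per sample) when a compound-het partner is classified P or LP;
#' PS2 and PS4 are reported as not applicable (`NA` flags) rather than
#' silently false. Flags are pure functions of the record, sample, and
#' configuration.
#'
#' @param variants A variant table with the expected annotation columns
#'   (`GENE`, `CLASS`, `popAF`, `known_pathogenic_aa`, `functional_evidence`;
#'   names configurable through `criteria`).
#' @param criteria Named list of annotation criteria, see [acmg_criteria()].
#' @param pathogenic_classes `CLASS` values that make a partner count for PM3.
#' @param require_phase Passed to [detect_compound_het()].
#' @return Long tibble of flags: variant keys, `sample` (`NA` for site-level
#'   criteria), `criterion`, `state`, `flag`, `evidence`.
#' @export
assign_acmg_criteria <- function(variants, criteria = acmg_criteria(),
                                 pathogenic_classes = c("P", "LP"),
                                 require_phase = FALSE) {
  variants <- tibble::as_tibble(variants)
  flags <- lapply(criteria, assign_annotation_criterion, variants = variants)

  keys <- variant_key(variants)
  ch <- detect_compound_het(variants, require_phase = require_phase)
  pairs_long <- dplyr::bind_rows(
    dplyr::transmute(ch, sample = .data$sample, key = .data$key_a, partner = .data$key_b),
    dplyr::transmute(ch, sample = .data$sample, key = .data$key_b, partner = .data$key_a)
  )
  class_of <- if ("CLASS" %in% names(variants)) {
    stats::setNames(as.character(variants$CLASS), keys)
  } else {
    stats::setNames(rep(NA_character_, length(keys)), keys)
  }
  ids <- if (nrow(variants)) variants$samples[[1]]$sample else character()
  grid <- tidyr::expand_grid(key = keys, sample = ids)
  ch_flags <- dplyr::group_by(pairs_long, .data$sample, .data$key)
  ch_flags <- dplyr::summarise(ch_flags,
    partners = paste(sort(unique(.data$partner)), collapse = ","),
    pm3 = any(class_of[.data$partner] %in% pathogenic_classes),
    .groups = "drop"
  )
  grid <- dplyr::left_join(grid, ch_flags, by = c("key", "sample"))
  key_info <- tibble::tibble(
    key = keys, chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt
  )
  grid <- dplyr::left_join(grid, key_info, by = "key")
  ps5 <- dplyr::transmute(grid,
    chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
    sample = .data$sample, criterion = "ACMG_PS5",
    state = ifelse(!is.na(.data$partners), "pass", "fail"),
    flag = !is.na(.data$partners),
    evidence = ifelse(!is.na(.data$partners),
      paste0("compound heterozygous with ", .data$partners), NA_character_
    )
  )
  pm3 <- dplyr::transmute(grid,
    chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
    sample = .data$sample, criterion = "ACMG_PM3",
    state = ifelse(!is.na(.data$pm3) & .data$pm3, "pass", "fail"),
    flag = !is.na(.data$pm3) & .data$pm3,
    evidence = ifelse(!is.na(.data$pm3) & .data$pm3,
      "in trans with pathogenic/likely pathogenic partner", NA_character_
    )
  )
  na_rows <- lapply(acmg_not_applicable, function(nm) {
    tibble::tibble(
      chrom = variants$chrom, pos = variants$pos,
      ref = variants$ref, alt = variants$alt,
      sample = NA_character_, criterion = nm,
      state = "missing", flag = NA,
      evidence = "not applicable in this analysis"
    )
  })
  dplyr::bind_rows(c(flags, list(ps5, pm3), na_rows))
}

#' Per-variant criterion-count score
#'
#' Number of criteria flagged `TRUE` for each variant (per-sample flags count
#' through their maximum over samples), usable for ranking. No ACMG
#' combining/classification rules are applied.
#'
#' @param flags Output of [assign_acmg_criteria()].
#' @return Tibble with variant keys and `score`.
#' @export
acmg_score <- function(flags) {
  site <- dplyr::filter(flags, is.na(.data$sample))
  site <- dplyr::group_by(site, .data$chrom, .data$pos, .data$ref, .data$alt)
  site <- dplyr::summarise(site, score_site = sum(.data$flag, na.rm = TRUE), .groups = "drop")
  per <- dplyr::filter(flags, !is.na(.data$sample))
  if (nrow(per)) {
    per <- dplyr::group_by(per, .data$chrom, .data$pos, .data$ref, .data$alt, .data$sample)
    per <- dplyr::summarise(per, s = sum(.data$flag, na.rm = TRUE), .groups = "drop")
    per <- dplyr::group_by(per, .data$chrom, .data$pos, .data$ref, .data$alt)
    per <- dplyr::summarise(per, score_sample = max(.data$s), .groups = "drop")
    out <- dplyr::full_join(site, per, by = c("chrom", "pos", "ref", "alt"))
  } else {
    out <- dplyr::mutate(site, score_sample = 0L)
  }
  dplyr::transmute(out,
    chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
    score = dplyr::coalesce(.data$score_site, 0L) + dplyr::coalesce(.data$score_sample, 0L)
  )
}
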