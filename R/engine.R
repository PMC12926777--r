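# QV evaluation engine: field resolution, three-valued condition logic,
# per-sample aggregation, and the filter/criteria pipeline.
#
# Outcomes are tri-state: "pass", "fail", "missing". Missing is never pass, so
# keep_if drops records (or samples) with missing operands while drop_if
# retains them. A per-sample condition evaluated on a sample with a missing
# genotype is "missing" regardless of the tested FORMAT value (exclusion of
# missing genotypes).

field_kind <- function(field) {
  if (field == "QUAL") {
    return(list(kind = "qual"))
  }
  if (startsWith(field, "INFO/")) {
    return(list(kind = "info", key = substring(field, 6)))
  }
  if (startsWith(field, "FORMAT/")) {
    return(list(kind = "format", key = substring(field, 8)))
  }
  m <- regmatches(field, regexec("^OVERLAP\\((.+)\\)$", field))[[1]]
  if (length(m)) {
    return(list(kind = "overlap", key = m[2]))
  }
  list(kind = "annotation", key = field)
}

condition_fields <- function(x) {
  if (inherits(x, "qv_group")) {
    return(unlist(lapply(x$members, condition_fields)))
  }
  x$field
}

condition_is_per_sample <- function(x) {
  any(startsWith(condition_fields(x), "FORMAT/"))
}

overlap_paths <- function(doc) {
  fields <- unlist(c(
    lapply(doc$filters, function(f) condition_fields(f$condition)),
    lapply(doc$criteria, function(cr) unlist(lapply(cr$conditions, condition_fields)))
  ))
  hits <- regmatches(fields, regexec("^OVERLAP\\((.+)\\)$", fields))
  unique(unlist(lapply(hits, function(m) if (length(m)) m[2] else NULL)))
}

# Evaluation context: caches per-table FORMAT matrices, genotype-missingness,
# and overlap counts so vectorized evaluation does each extraction once.
eval_ctx <- function(variants, regions = list(), bed_root = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$variants <- variants
  ctx$regions <- regions
  ctx$bed_root <- bed_root
  ctx$fmt <- list()
  ctx$overlaps <- list()
  ctx$sample_ids <- if (nrow(variants) && "samples" %in% names(variants)) {
    variants$samples[[1]]$sample
  } else {
    character()
  }
  ctx
}

ctx_region_index <- function(ctx, path) {
  idx <- ctx$regions[[path]]
  if (is.null(idx)) {
    if (is.null(ctx$bed_root)) {
      stop("no region index supplied for OVERLAP(", path, ")", call. = FALSE)
    }
    idx <- load_bed(file.path(ctx$bed_root, path))
    ctx$regions[[path]] <- idx
  }
  idx
}

ctx_overlap_counts <- function(ctx, path) {
  if (is.null(ctx$overlaps[[path]])) {
    ctx$overlaps[[path]] <- overlap_count(ctx$variants, ctx_region_index(ctx, path))
  }
  ctx$overlaps[[path]]
}

ctx_fmt_matrix <- function(ctx, key) {
  if (is.null(ctx$fmt[[key]])) {
    tbl <- ctx$variants
    ids <- ctx$sample_ids
    template <- if (key == "GT") NA_character_ else NA_real_
    m <- matrix(template,
      nrow = nrow(tbl), ncol = length(ids),
      dimnames = list(NULL, ids)
    )
    for (i in seq_len(nrow(tbl))) {
      s <- tbl$samples[[i]]
      if (!is.null(s[[key]])) m[i, ] <- s[[key]]
    }
    ctx$fmt[[key]] <- m
  }
  ctx$fmt[[key]]
}

ctx_gt_missing <- function(ctx) {
  if (is.null(ctx$gt_missing)) {
    gt <- ctx_fmt_matrix(ctx, "GT")
    miss <- is.na(gt) | grepl(".", gt, fixed = TRUE)
    dim(miss) <- dim(gt)
    colnames(miss) <- colnames(gt)
    ctx$gt_missing <- miss
  }
  ctx$gt_missing
}

resolve_field_vec <- function(ctx, field, sample = NULL) {
  fk <- field_kind(field)
  tbl <- ctx$variants
  switch(fk$kind,
    qual = tbl$qual,
    info = if (fk$key == "DP") {
      site_depth(tbl) # computed site depth stands in when INFO/DP is absent
    } else {
      info_values(tbl$info, fk$key)
    },
    format = {
      if (is.null(sample)) {
        stop("FORMAT field ", field, " requires a sample", call. = FALSE)
      }
      m <- ctx_fmt_matrix(ctx, fk$key)
      if (!sample %in% colnames(m)) {
        stop("unknown sample ", dQuote(sample), call. = FALSE)
      }
      unname(m[, sample])
    },
    overlap = ctx_overlap_counts(ctx, fk$key),
    annotation = {
      if (!fk$key %in% setdiff(names(tbl), variant_core_cols)) {
        stop(
          "unknown field ", dQuote(field),
          ": not QUAL, INFO/*, FORMAT/*, OVERLAP(), or an annotation column",
          call. = FALSE
        )
      }
      tbl[[fk$key]]
    }
  )
}

info_values <- function(info, key) {
  vals <- lapply(info, `[[`, key)
  simplify_values(vals)
}

#' Resolve a condition field on one variant record
#'
#' @param rec One-row variant table.
#' @param field Field expression (`QUAL`, `INFO/<key>`, `FORMAT/<key>`,
#'   annotation column, or `OVERLAP(<path>)`). `INFO/DP` resolves through
#'   [site_depth()], falling back to the sum of per-sample depths when the
#'   site INFO field is absent.
#' @param sample Sample id, required for `FORMAT/*` fields.
#' @param regions Named list of `qv_regions`, keyed by the `OVERLAP()` path.
#' @return The resolved value, or `NA` when missing.
#' @export
resolve_field <- function(rec, field, sample = NULL, regions = list()) {
  stopifnot(nrow(rec) == 1)
  resolve_field_vec(eval_ctx(rec, regions = regions), field, sample = sample)[1]
}

#' Site read depth with per-sample fallback
#'
#' `INFO/DP` when present; otherwise the sum of per-sample `FORMAT/DP` over
#' samples where depth is present; `NA` when neither exists.
#'
#' @param variants A variant table.
#' @return Numeric vector of site depths.
#' @export
site_depth <- function(variants) {
  info_dp <- suppressWarnings(as.numeric(vapply(
    variants$info %||% rep(list(NULL), nrow(variants)),
    function(x) {
      v <- x[["DP"]]
      if (is.null(v)) NA_real_ else as.numeric(v)[1]
    }, numeric(1)
  )))
  fmt_dp <- vapply(seq_len(nrow(variants)), function(i) {
    s <- variants$samples[[i]]
    if (is.null(s) || is.null(s$DP) || all(is.na(s$DP))) {
      return(NA_real_)
    }
    sum(s$DP, na.rm = TRUE)
  }, numeric(1))
  dplyr::coalesce(info_dp, fmt_dp)
}

compare_outcome <- function(op, vals, target) {
  if (is.list(target)) target <- unlist(target)
  out <- rep("fail", length(vals))
  out[is.na(vals)] <- "missing"
  ok <- !is.na(vals)
  if (!any(ok)) {
    return(out)
  }
  v <- vals[ok]
  if (op %in% c(">", ">=", "<", "<=")) {
    if (!is.numeric(v) || !is.numeric(target)) {
      stop(
        "type-incomparable operands for ", op, ": ",
        class(v)[1], " vs ", class(target)[1],
        call. = FALSE
      )
    }
    hit <- switch(op,
      ">" = v > target,
      ">=" = v >= target,
      "<" = v < target,
      "<=" = v <= target
    )
  } else if (op %in% c("==", "!=")) {
    if (is.logical(target) || is.logical(v)) {
      hit <- as.logical(v) == as.logical(target)
    } else if (is.numeric(target) && is.numeric(v)) {
      hit <- v == target
    } else if (is.character(target) && is.character(v)) {
      hit <- v == target
    } else {
      stop(
        "type-incomparable operands for ", op, ": ",
        class(v)[1], " vs ", class(target)[1],
        call. = FALSE
      )
    }
    if (op == "!=") hit <- !hit
  } else if (op %in% c("in", "not_in")) {
    hit <- as.character(v) %in% as.character(target)
    if (op == "not_in") hit <- !hit
  } else {
    stop("unknown operator ", dQuote(op), call. = FALSE)
  }
  out[ok][hit] <- "pass"
  out
}

eval_condition_vec <- function(cond, ctx, sample = NULL) {
  vals <- resolve_field_vec(ctx, cond$field, sample = sample)
  out <- compare_outcome(cond$operator, vals, cond$value)
  if (!is.null(sample) && startsWith(cond$field, "FORMAT/")) {
    gtm <- ctx_gt_missing(ctx)
    if (sample %in% colnames(gtm)) {
      out[gtm[, sample]] <- "missing" # genotype exclusion dominates
    }
  }
  out
}

eval_tree_vec <- function(x, ctx, sample = NULL) {
  if (inherits(x, "qv_group")) {
    states <- vapply(
      x$members, eval_tree_vec,
      character(nrow(ctx$variants)),
      ctx = ctx, sample = sample
    )
    if (nrow(ctx$variants) == 1) states <- matrix(states, nrow = 1)
    return(combine_states(x$mode, states))
  }
  eval_condition_vec(x, ctx, sample = sample)
}

combine_states <- function(mode, states) {
  if (!is.matrix(states)) states <- matrix(states, ncol = 1)
  if (mode == "all_of") {
    out <- rep("pass", nrow(states))
    out[rowSums(states == "missing") > 0] <- "missing"
    out[rowSums(states == "fail") > 0] <- "fail"
  } else if (mode == "any_of") {
    out <- rep("fail", nrow(states))
    out[rowSums(states == "missing") > 0] <- "missing"
    out[rowSums(states == "pass") > 0] <- "pass"
  } else {
    stop("unknown group mode ", dQuote(mode), call. = FALSE)
  }
  out
}

#' Evaluate a single condition on one record
#'
#' @param cond A `qv_condition`.
#' @param rec One-row variant table.
#' @param sample Sample id for per-sample (`FORMAT/*`) conditions; a missing
#'   genotype in that sample yields `"missing"` regardless of the tested
#'   value.
#' @param regions Named list of region indexes for `OVERLAP()` fields.
#' @return `"pass"`, `"fail"`, or `"missing"`.
#' @export
eval_condition <- function(cond, rec, sample = NULL, regions = list()) {
  stopifnot(inherits(cond, "qv_condition"), nrow(rec) == 1)
  eval_condition_vec(cond, eval_ctx(rec, regions = regions), sample = sample)[1]
}

#' Evaluate a condition group on one record
#'
#' Three-valued logic: `all_of` fails if any member fails, else is missing if
#' any member is missing, else passes; `any_of` passes if any member passes,
#' else is missing if any member is missing, else fails.
#'
#' @param group A `qv_group` (or single `qv_condition`).
#' @inheritParams eval_condition
#' @return `"pass"`, `"fail"`, or `"missing"`.
#' @export
eval_group <- function(group, rec, sample = NULL, regions = list()) {
  stopifnot(nrow(rec) == 1)
  eval_tree_vec(group, eval_ctx(rec, regions = regions), sample = sample)[1]
}

eval_filter_vec <- function(rule, ctx) {
  cond <- rule$condition
  n <- nrow(ctx$variants)
  if (condition_is_per_sample(cond)) {
    ids <- ctx$sample_ids
    agg <- rule$sample_aggregation %||% "all_samples"
    if (!length(ids)) {
      pass <- rep(FALSE, n)
      missing_any <- rep(TRUE, n)
    } else {
      states <- vapply(ids, function(s) eval_tree_vec(cond, ctx, sample = s),
        character(n)
      )
      if (n == 1) states <- matrix(states, nrow = 1)
      pass <- if (agg == "any_sample") {
        rowSums(states == "pass") > 0
      } else {
        rowSums(states == "pass") == length(ids)
      }
      missing_any <- rowSums(states == "missing") > 0
    }
  } else {
    state <- eval_tree_vec(cond, ctx)
    pass <- state == "pass"
    missing_any <- state == "missing"
  }
  keep <- if (rule$logic == "drop_if") !pass else pass
  list(keep = keep, missing_any = missing_any)
}

#' Evaluate a filter rule on one record
#'
#' Per-sample conditions are aggregated across samples according to the rule's
#' `sample_aggregation` (`all_samples` by default: every sample outcome must
#' be pass; `any_sample`: at least one pass). Missing outcomes are never pass,
#' so `keep_if` drops on missing and `drop_if` retains.
#'
#' @param rule A `qv_filter`.
#' @inheritParams eval_condition
#' @return `"keep"` or `"drop"`.
#' @export
eval_filter <- function(rule, rec, regions = list()) {
  stopifnot(inherits(rule, "qv_filter"), nrow(rec) == 1)
  res <- eval_filter_vec(rule, eval_ctx(rec, regions = regions))
  if (res$keep[1]) "keep" else "drop"
}

#' Apply a QV document to a variant table
#'
#' Filters run as a conjunctive pipeline in document order: a record must
#' survive every rule. Criteria never remove records; they are evaluated on
#' the surviving records and returned as boolean flags (per variant, or per
#' variant-sample pair when a criterion touches `FORMAT/*` fields).
#'
#' @param doc A valid `qv_file` (validated on entry; errors abort).
#' @param variants A variant table ([read_vcf()] or a simulator).
#' @param regions Named list of `qv_regions`, keyed by the `OVERLAP()` path
#'   string used in the document.
#' @param bed_root Directory in which to look up `OVERLAP()` paths not already
#'   present in `regions`.
#' @return A `qv_result`: list with `kept` (surviving records), `flags` (long
#'   tibble of criterion flags), `summary` (per-rule counts: `evaluated`,
#'   `kept`, `dropped`, `dropped_missing`), `n_input`, and `qv_set_id`.
#' @examples
#' doc <- qv_file(
#'   meta = list(
#'     qv_set_id = "qv_x_v1_20250101",
#'     title = "x", version = "1.0.0"
#'   ),
#'   filters = list(qv_filter("min_qual", "keep_if", qv_condition("QUAL", ">=", 30)))
#' )
#' sim <- sim_cohort(n_samples = 4, n_variants = 20, seed = 1)
#' res <- apply_qv(doc, sim$variants)
#' tidy(res)
#' @export
apply_qv <- function(doc, variants, regions = list(), bed_root = NULL) {
  stopifnot(inherits(doc, "qv_file"))
  report <- validate_qv(doc)
  if (!qv_is_valid(report)) {
    bad <- report[report$severity == "error", ]
    stop("invalid QV document: ", bad$path[1], ": ", bad$message[1],
      if (nrow(bad) > 1) sprintf(" (and %d more violations)", nrow(bad) - 1),
      call. = FALSE
    )
  }
  variants <- tibble::as_tibble(variants)
  tbl <- variants
  summary_rows <- list()
  for (f in doc$filters) {
    ctx <- eval_ctx(tbl, regions = regions, bed_root = bed_root)
    res <- tryCatch(eval_filter_vec(f, ctx), error = function(e) {
      stop("rule ", dQuote(f$name), ": ", conditionMessage(e), call. = FALSE)
    })
    regions <- ctx$regions # keep BED files loaded once
    kept_n <- sum(res$keep)
    summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
      rule = f$name, logic = f$logic,
      evaluated = nrow(tbl), kept = kept_n, dropped = nrow(tbl) - kept_n,
      dropped_missing = sum(!res$keep & res$missing_any)
    )
    tbl <- tbl[res$keep, , drop = FALSE]
  }

  flags <- list()
  ctx <- eval_ctx(tbl, regions = regions, bed_root = bed_root)
  key_cols <- tibble::tibble(
    chrom = tbl$chrom, pos = tbl$pos, ref = tbl$ref, alt = tbl$alt
  )
  for (cr in doc$criteria) {
    grp <- qv_group(if (identical(cr$logic, "or")) "any_of" else "all_of", cr$conditions)
    per_sample <- condition_is_per_sample(grp)
    if (per_sample) {
      for (s in ctx$sample_ids) {
        state <- eval_tree_vec(grp, ctx, sample = s)
        flags[[length(flags) + 1]] <- dplyr::bind_cols(
          key_cols,
          tibble::tibble(
            sample = s, criterion = cr$name,
            state = state, flag = state == "pass"
          )
        )
      }
    } else {
      state <- eval_tree_vec(grp, ctx)
      flags[[length(flags) + 1]] <- dplyr::bind_cols(
        key_cols,
        tibble::tibble(
          sample = NA_character_, criterion = cr$name,
          state = state, flag = state == "pass"
        )
      )
    }
  }
  flags <- if (length(flags)) {
    dplyr::bind_rows(flags)
  } else {
    tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), sample = character(), criterion = character(),
      state = character(), flag = logical()
    )
  }

  structure(
    list(
      kept = tbl,
      flags = flags,
      summary = dplyr::bind_rows(
        tibble::tibble(
          rule = character(), logic = character(), evaluated = integer(),
          kept = integer(), dropped = integer(), dropped_missing = integer()
        ),
        summary_rows
      ),
      n_input = nrow(variants),
      qv_set_id = doc$meta$qv_set_id %||% NA_character_
    ),
    class = "qv_result"
  )
}

#' @export
print.qv_result <- function(x, ...) {
  cat("<qv_result> ", x$qv_set_id %|na|% "<unnamed QV set>", "\n", sep = "")
  cat("  records: ", x$n_input, " in, ", nrow(x$kept), " kept\n", sep = "")
  if (nrow(x$summary)) {
    cat("  rules:\n")
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf(
        "    %-20s %s: %d -> %d (dropped %d, of which %d via missing)\n",
        x$summary$rule[i], x$summary$logic[i], x$summary$evaluated[i],
        x$summary$kept[i], x$summary$dropped[i], x$summary$dropped_missing[i]
      ))
    }
  }
  if (nrow(x$flags)) {
    tally <- dplyr::count(x$flags[x$flags$flag, ], .data$criterion)
    cat(
      "  criterion flags: ",
      paste(sprintf("%s=%d", tally$criterion, tally$n), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Records flagged by a named criterion
#'
#' Criteria only label records; use this to realize the stricter
#' "retain only flagged" step as a second-stage filter.
#'
#' @param result A `qv_result`.
#' @param criterion Criterion name.
#' @return The subset of `result$kept` flagged `TRUE` (in any sample, for
#'   per-sample criteria).
#' @export
filter_flagged <- function(result, criterion) {
  stopifnot(inherits(result, "qv_result"))
  hits <- result$flags[result$flags$criterion == criterion & result$flags$flag, ]
  keys <- unique(paste(hits$chrom, hits$pos, hits$ref, hits$alt, sep = ":"))
  result$kept[variant_key(result$kept) %in% keys, , drop = FALSE]
}

#' @rdname write_vcf
#' @export
write_vcf.qv_result <- function(x, path, include_command = FALSE, ...) {
  tbl <- x$kept
  for (cr in unique(x$flags$criterion)) {
    hits <- x$flags[x$flags$criterion == cr & x$flags$flag, ]
    keys <- unique(paste(hits$chrom, hits$pos, hits$ref, hits$alt, sep = ":"))
    tbl[[paste0("QV_", cr)]] <- variant_key(tbl) %in% keys
  }
  write_vcf.data.frame(tbl, path,
    qv_set_id = if (is.na(x$qv_set_id)) NULL else x$qv_set_id,
    include_command = include_command, ...
  )
}
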