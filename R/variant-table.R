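# Tidy variant tables: one row per VCF record, with an `info` list-column of
# named site fields, a `samples` list-column of per-sample FORMAT tibbles, and
# promoted annotation columns (CLASS, GENE, ...) for bare-name conditions.

#' Default INFO keys promoted to annotation columns on read
#' @export
qv_annotation_fields <- c(
  "CLASS", "GENE", "popAF", "known_pathogenic_aa", "functional_evidence"
)

variant_core_cols <- c(
  "chrom", "pos", "id", "ref", "alt", "qual", "filter", "info", "samples"
)

#' Read a VCF file into a variant table
#'
#' Parsing is delegated to `vcfR`; the result is a tibble with one row per
#' record. INFO becomes a named list-column (`info`), per-sample FORMAT values
#' become a list-column of tibbles (`samples`, columns `sample`, `GT`, plus
#' any other FORMAT keys), and INFO keys listed in `annotation_fields` are
#' additionally promoted to top-level columns so bare condition fields such as
#' `CLASS` resolve.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param annotation_fields INFO keys to promote; defaults to
#'   [qv_annotation_fields].
#' @return A tibble.
#' @export
read_vcf <- function(path, annotation_fields = qv_annotation_fields) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  info <- lapply(seq_len(n), function(i) parse_info_string(fix[i, "INFO"]))
  info <- retype_info(info)
  has_gt <- ncol(v@gt) > 1
  samples <- if (has_gt) {
    ids <- colnames(v@gt)[-1]
    lapply(seq_len(n), function(i) {
      parse_format_row(v@gt[i, 1], v@gt[i, -1, drop = TRUE], ids)
    })
  } else {
    rep(list(tibble::tibble(sample = character())), n)
  }
  tbl <- tibble::tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = dot_na(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = dot_na(fix[, "FILTER"]),
    info = info,
    samples = samples
  )
  # header declarations let all-absent Flag keys promote to all-FALSE columns
  flag_keys <- header_flag_info_keys(v@meta)
  present <- unique(unlist(lapply(info, names)))
  for (key in intersect(annotation_fields, union(present, flag_keys))) {
    vals <- lapply(info, `[[`, key)
    if (key %in% flag_keys ||
      all(vapply(vals, function(x) is.null(x) || is.logical(x), logical(1)))) {
      tbl[[key]] <- vapply(vals, function(x) isTRUE(x), logical(1))
    } else {
      tbl[[key]] <- simplify_values(vals)
    }
  }
  tbl
}

header_flag_info_keys <- function(meta_lines) {
  info_lines <- grep("^##INFO=", meta_lines, value = TRUE)
  flags <- grep("Type=Flag", info_lines, value = TRUE)
  hits <- regmatches(flags, regexec("ID=([^,>]+)", flags))
  vapply(hits, function(m) if (length(m)) m[2] else NA_character_, "")
}

dot_na <- function(x) {
  x <- as.character(x)
  x[x == "." | is.na(x)] <- NA_character_
  x
}

parse_info_string <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) {
    return(list())
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(parts, 1, eq - 1), parts)
  vals <- lapply(seq_along(parts), function(i) {
    if (eq[i] > 0) substr(parts[i], eq[i] + 1, nchar(parts[i])) else TRUE
  })
  stats::setNames(vals, keys)
}

# Per key: if every non-missing value across records parses as a number,
# store numbers.
retype_info <- function(info) {
  keys <- unique(unlist(lapply(info, names)))
  numeric_key <- vapply(keys, function(k) {
    vals <- unlist(lapply(info, function(x) {
      if (is.character(x[[k]] %||% NULL)) x[[k]] else NULL
    }))
    length(vals) > 0 && !any(is.na(suppressWarnings(as.numeric(vals))))
  }, logical(1))
  lapply(info, function(x) {
    for (k in names(x)) {
      if (is.character(x[[k]]) && isTRUE(numeric_key[k])) {
        x[[k]] <- as.numeric(x[[k]])
      }
    }
    x
  })
}

parse_format_row <- function(format, values, ids) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  split <- strsplit(as.character(values), ":", fixed = TRUE)
  out <- tibble::tibble(sample = ids)
  for (j in seq_along(keys)) {
    col <- vapply(split, function(x) if (length(x) >= j) x[j] else NA_character_, "")
    col[col == "."] <- NA_character_
    if (keys[j] != "GT") {
      num <- suppressWarnings(as.numeric(col))
      if (!any(is.na(num) & !is.na(col))) col <- num
    }
    out[[keys[j]]] <- col
  }
  out
}

simplify_values <- function(vals) {
  vals <- lapply(vals, function(x) if (is.null(x)) NA else x)
  if (all(vapply(vals, is.numeric, logical(1)) |
    vapply(vals, function(x) length(x) == 1 && is.na(x), logical(1)))) {
    return(vapply(vals, function(x) as.numeric(x)[1], numeric(1)))
  }
  vapply(vals, function(x) as.character(x)[1], character(1))
}

# ---- writing ---------------------------------------------------------------

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) {
      return(".")
    }
    if (is.numeric(v) && v == round(v) && abs(v) < .Machine$integer.max) {
      return(format(as.integer(v)))
    }
    format(v, scientific = FALSE, trim = TRUE, digits = 10)
  }, "")
  out
}

info_field_string <- function(rec_info, extra) {
  fields <- c(rec_info, extra)
  fields <- fields[!vapply(fields, function(v) is.null(v) ||
    (length(v) == 1 && is.na(v)) || isFALSE(v), logical(1))]
  if (!length(fields)) {
    return(".")
  }
  fields <- fields[order(names(fields))]
  parts <- vapply(names(fields), function(k) {
    v <- fields[[k]]
    if (isTRUE(v)) k else paste0(k, "=", paste(fmt_num_or_chr(v), collapse = ","))
  }, "")
  paste(parts, collapse = ";")
}

fmt_num_or_chr <- function(v) {
  if (is.numeric(v)) fmt_num(v) else as.character(v)
}

#' Write variant data as VCF text
#'
#' Writes VCF 4.2 plain text. Output is deterministic: INFO keys are sorted,
#' no timestamp or command line is added to the header unless
#' `include_command = TRUE`, so repeated runs on identical inputs are
#' byte-identical and checksum-comparable.
#'
#' @param x A variant table (tibble as produced by [read_vcf()] or the
#'   simulators) or a `qv_result` from [apply_qv()].
#' @param path Output path.
#' @param qv_set_id Optional QV set identifier recorded as a `##QV_SET_ID`
#'   header line.
#' @param include_command Add a `##qvtools_command` header line (with a
#'   timestamp; off by default to keep outputs comparable).
#' @param ... Passed between methods.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, ...) UseMethod("write_vcf")

#' @rdname write_vcf
#' @export
write_vcf.data.frame <- function(x, path, qv_set_id = NULL,
                                 include_command = FALSE, ...) {
  tbl <- x
  ann_cols <- setdiff(names(tbl), variant_core_cols)
  n <- nrow(tbl)
  sample_ids <- if (n && "samples" %in% names(tbl)) tbl$samples[[1]]$sample else character()
  fmt_keys <- if (n && "samples" %in% names(tbl)) {
    setdiff(names(tbl$samples[[1]]), "sample")
  } else {
    character()
  }
  fmt_keys <- c(intersect("GT", fmt_keys), sort(setdiff(fmt_keys, "GT")))

  info_keys <- sort(unique(c(
    unlist(lapply(tbl$info %||% list(), names)), ann_cols
  )))
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(qv_set_id)) paste0("##QV_SET_ID=", qv_set_id),
    if (include_command) {
      paste0("##qvtools_command=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    },
    vapply(info_keys, function(k) {
      sprintf(
        '##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
        k, if (info_key_is_flag(tbl, k)) "0" else "1",
        info_key_type(tbl, k), k
      )
    }, ""),
    vapply(fmt_keys, function(k) {
      type <- if (k == "GT") "String" else "Integer"
      sprintf('##FORMAT=<ID=%s,Number=1,Type=%s,Description="%s">', k, type, k)
    }, ""),
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      if (length(sample_ids)) c("FORMAT", sample_ids)
    ), collapse = "\t")
  )

  body <- vapply(seq_len(n), function(i) {
    extra <- lapply(ann_cols, function(k) tbl[[k]][i])
    names(extra) <- ann_cols
    info <- info_field_string(tbl$info[[i]] %||% list(), extra)
    fields <- c(
      tbl$chrom[i], tbl$pos[i],
      tbl$id[i] %|na|% ".", tbl$ref[i], tbl$alt[i],
      fmt_num(tbl$qual[i]), (tbl$filter[i] %|na|% "PASS"), info
    )
    if (length(sample_ids)) {
      s <- tbl$samples[[i]]
      cols <- vapply(seq_along(sample_ids), function(j) {
        vals <- vapply(fmt_keys, function(k) {
          v <- s[[k]][j]
          if (k == "GT") (v %|na|% "./.") else fmt_num(v)
        }, "")
        paste(vals, collapse = ":")
      }, "")
      fields <- c(fields, paste(fmt_keys, collapse = ":"), cols)
    }
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

info_key_is_flag <- function(tbl, k) {
  if (k %in% names(tbl)) {
    return(is.logical(tbl[[k]]))
  }
  vals <- lapply(tbl$info %||% list(), `[[`, k)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  length(vals) > 0 && all(vapply(vals, is.logical, logical(1)))
}

info_key_type <- function(tbl, k) {
  if (info_key_is_flag(tbl, k)) {
    return("Flag")
  }
  vals <- if (k %in% names(tbl)) {
    tbl[[k]]
  } else {
    unlist(lapply(tbl$info %||% list(), `[[`, k))
  }
  vals <- vals[!is.na(vals)]
  if (is.numeric(vals) && length(vals)) {
    if (all(vals == round(vals))) "Integer" else "Float"
  } else {
    "String"
  }
}

`%|na|%` <- function(a, b) {
  ifelse(is.na(a), b, a)
}

#' Genotype dosage matrix from a variant table
#'
#' Codes each biallelic genotype as the count of alternate alleles: 0
#' (hom-ref), 1 (het), 2 (hom-alt), `NA` for missing (any `.` allele or
#' missing GT). Variants are rows, samples are columns.
#'
#' @param variants A variant table with a `samples` list-column carrying `GT`.
#' @return Integer matrix with rownames `chrom:pos:ref:alt`.
#' @export
gt_matrix <- function(variants) {
  n <- nrow(variants)
  ids <- if (n) variants$samples[[1]]$sample else character()
  m <- matrix(NA_integer_,
    nrow = n, ncol = length(ids),
    dimnames = list(variant_key(variants), ids)
  )
  for (i in seq_len(n)) {
    m[i, ] <- gt_dosage(variants$samples[[i]]$GT)
  }
  m
}

gt_dosage <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) {
      return(NA_integer_)
    }
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) {
      return(NA_integer_)
    }
    a <- suppressWarnings(as.integer(alleles))
    if (any(is.na(a)) || any(a > 1)) {
      stop("gt_matrix requires biallelic genotypes, got ", dQuote(g), call. = FALSE)
    }
    sum(a)
  }, integer(1), USE.NAMES = FALSE)
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
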