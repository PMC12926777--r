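# BED-backed region indexes for OVERLAP() conditions.
# Coordinates: BED intervals are 0-based half-open; VCF positions are 1-based.
# A record's reference span is [pos, pos + nchar(ref) - 1], 1-based inclusive.

#' Build a region index from interval data
#'
#' @param intervals Data frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive). Extra columns (e.g. `name`) are kept.
#' @param label Source label (usually the BED path).
#' @return A `qv_regions` index backed by `GenomicRanges` for overlap queries.
#' @export
region_index <- function(intervals, label = "<memory>") {
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    bad <- which(intervals$start >= intervals$end)[1]
    stop("interval ", bad, ": start must be < end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(intervals$chrom),
    ranges = IRanges::IRanges(
      start = as.integer(intervals$start) + 1L,
      end = as.integer(intervals$end)
    )
  )
  structure(
    list(intervals = intervals, granges = gr, label = label),
    class = "qv_regions"
  )
}

#' @export
print.qv_regions <- function(x, ...) {
  cat("<qv_regions> ", nrow(x$intervals), " intervals from ", x$label, "\n", sep = "")
  invisible(x)
}

#' Load a BED file into a region index
#'
#' BED3+ (tab- or space-separated). Malformed lines (fewer than three fields,
#' non-integer coordinates, start >= end) raise an error naming the line.
#'
#' @param path BED file path.
#' @return A `qv_regions` index.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", bed)
#' idx <- load_bed(bed)
#' overlap_count(tibble::tibble(chrom = "chr1", pos = 150, ref = "A"), idx)
#' @export
load_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) {
    return(region_index(
      tibble::tibble(chrom = character(), start = integer(), end = integer()),
      label = path
    ))
  }
  parts <- strsplit(trimws(lines[rows]), "[\t ]+")
  parsed <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    line_no <- rows[i]
    if (length(p) < 3) {
      stop("BED line ", line_no, ": expected at least 3 fields", call. = FALSE)
    }
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end)) {
      stop("BED line ", line_no, ": non-integer coordinates", call. = FALSE)
    }
    if (start >= end) {
      stop("BED line ", line_no, ": start (", start, ") must be < end (", end, ")",
        call. = FALSE
      )
    }
    tibble::tibble(
      chrom = p[1], start = start, end = end,
      name = if (length(p) >= 4) p[4] else NA_character_
    )
  })
  region_index(dplyr::bind_rows(parsed), label = path)
}

#' Count intervals overlapping each variant's reference span
#'
#' The reference span of a record is `[pos, pos + nchar(ref) - 1]` (1-based,
#' inclusive); BED intervals are converted from 0-based half-open. A record is
#' counted against an interval when any base of the span intersects it.
#'
#' @param variants Data frame with columns `chrom`, `pos`, and (optionally)
#'   `ref`; a missing `ref` is treated as a single base.
#' @param index A `qv_regions` index.
#' @return Integer vector of overlap counts, one per record.
#' @export
overlap_count <- function(variants, index) {
  stopifnot(inherits(index, "qv_regions"))
  n <- nrow(variants)
  if (!n) {
    return(integer())
  }
  if (!nrow(index$intervals)) {
    return(integer(n))
  }
  ref_len <- if ("ref" %in% names(variants)) {
    pmax(1L, nchar(as.character(variants$ref)))
  } else {
    rep(1L, n)
  }
  query <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(
      start = as.integer(variants$pos),
      end = as.integer(variants$pos) + ref_len - 1L
    )
  )
  as.integer(suppressWarnings(GenomicRanges::countOverlaps(query, index$granges)))
}

#' Write intervals to a BED file
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optional
#'   `name` columns (0-based half-open, as in BED).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals) && !all(is.na(intervals$name))) {
    cols <- c(cols, "name")
  }
  lines <- do.call(paste, c(unname(as.list(intervals[cols])), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
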