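# Local QV release registry: append-only records binding (qv_set_id, version)
# to a SHA-256 digest, so a released criteria set is verifiable and immutable.

registry_cols <- c("qv_set_id", "version", "sha256", "released", "mode")

#' SHA-256 checksum of a QV document
#'
#' In `"canonical"` mode (default) the digest is taken over the canonical byte
#' form ([canonicalize_qv()]), so it is invariant under YAML/JSON
#' re-serialization and key reordering. In `"raw"` mode it is taken over the
#' file bytes as released.
#'
#' @param x A `qv_file`, a file path, a character scalar of document text, or
#'   a raw vector.
#' @param mode `"canonical"` or `"raw"`.
#' @return 64-character lowercase hex digest.
#' @export
qv_checksum <- function(x, mode = c("canonical", "raw")) {
  mode <- match.arg(mode)
  if (mode == "canonical") {
    doc <- if (inherits(x, "qv_file")) {
      x
    } else if (is.raw(x)) {
      parse_qv(x)
    } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
      read_qv(x)
    } else {
      parse_qv(x)
    }
    return(digest::digest(canonicalize_qv(doc), algo = "sha256", serialize = FALSE))
  }
  bytes <- if (is.raw(x)) {
    x
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    readBin(x, "raw", file.size(x))
  } else if (is.character(x)) {
    charToRaw(paste(x, collapse = "\n"))
  } else {
    stop("raw-bytes checksum needs a file path, text, or raw vector", call. = FALSE)
  }
  digest::digest(bytes, algo = "sha256", serialize = FALSE)
}

#' Read a QV registry file
#'
#' @param path Registry path (tab-separated, header line, append-only).
#' @return Tibble of registry records (empty when the file does not exist).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    return(tibble::as_tibble(stats::setNames(
      lapply(registry_cols, function(x) character()), registry_cols
    )))
  }
  tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
}

#' Register a QV release
#'
#' Records the digest of a released document under its (qv_set_id, version)
#' pair. Releases are immutable: re-registering the same pair with a different
#' digest is a conflict error; re-registering identical content is a no-op.
#'
#' @param x A `qv_file`, or a file path (required for `mode = "raw"`).
#' @param registry Registry file path (created if absent).
#' @param mode Digest mode, see [qv_checksum()].
#' @param released Release timestamp (ISO-8601); defaults to the current UTC
#'   time.
#' @return One-row tibble: the registry record.
#' @export
register_qv <- function(x, registry, mode = c("canonical", "raw"),
                        released = NULL) {
  mode <- match.arg(mode)
  doc <- if (inherits(x, "qv_file")) x else read_qv(x)
  if (mode == "raw" && inherits(x, "qv_file")) {
    stop("raw-bytes registration requires the released file, not an in-memory document",
      call. = FALSE
    )
  }
  id <- doc$meta$qv_set_id %||% stop("document has no qv_set_id", call. = FALSE)
  version <- as.character(doc$meta$version %||%
    stop("document has no version", call. = FALSE))
  digest <- qv_checksum(if (mode == "raw") x else doc, mode = mode)
  reg <- read_registry(registry)
  hit <- reg[reg$qv_set_id == id & reg$version == version & reg$mode == mode, ]
  if (nrow(hit)) {
    if (any(hit$sha256 != digest)) {
      stop(
        "conflict: ", id, " version ", version,
        " is already registered with a different digest (releases are immutable)",
        call. = FALSE
      )
    }
    return(tibble::as_tibble(hit[1, ]))
  }
  record <- tibble::tibble(
    qv_set_id = id, version = version, sha256 = digest,
    released = released %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    mode = mode
  )
  new_file <- !file.exists(registry)
  con <- file(registry, open = "a")
  on.exit(close(con))
  if (new_file) writeLines(paste(registry_cols, collapse = "\t"), con)
  writeLines(paste(unlist(record[1, registry_cols]), collapse = "\t"), con)
  record
}

#' Verify a QV document against the registry
#'
#' Recomputes the digest of `x` and compares it with the registered digest for
#' its (qv_set_id, version). In canonical mode, re-serialization (YAML to
#' JSON, key reordering) does not break verification; any change to a content
#' field does.
#'
#' @param x A `qv_file`, file path, document text, or raw bytes.
#' @param registry Registry file path.
#' @param mode Digest mode; defaults to the mode stored in the registry
#'   record.
#' @param qv_set_id,version Identify the record; defaults are taken from the
#'   document's meta.
#' @return A `qv_verification`: list with `verified`, `expected`, `actual`,
#'   and the registry `record`.
#' @export
verify_qv <- function(x, registry, mode = NULL, qv_set_id = NULL, version = NULL) {
  doc <- if (inherits(x, "qv_file")) {
    x
  } else if (is.raw(x)) {
    parse_qv(x)
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    read_qv(x)
  } else {
    parse_qv(x)
  }
  id <- qv_set_id %||% doc$meta$qv_set_id
  version <- as.character(version %||% doc$meta$version %||% NA_character_)
  reg <- read_registry(registry)
  hit <- reg[reg$qv_set_id %in% id & reg$version %in% version, ]
  if (!is.null(mode)) hit <- hit[hit$mode == mode, ]
  if (!nrow(hit)) {
    stop("no registry record for ", id %||% "<missing id>", " version ", version,
      call. = FALSE
    )
  }
  record <- hit[nrow(hit), ]
  mode <- record$mode
  actual <- qv_checksum(if (mode == "canonical") doc else x, mode = mode)
  structure(
    list(
      verified = identical(actual, record$sha256),
      expected = record$sha256, actual = actual,
      record = tibble::as_tibble(record)
    ),
    class = "qv_verification"
  )
}

#' @export
print.qv_verification <- function(x, ...) {
  cat(
    if (x$verified) "verified" else "MISMATCH", ": ",
    x$record$qv_set_id, " v", x$record$version, " (", x$record$mode, ")\n",
    sep = ""
  )
  if (!x$verified) {
    cat("  expected ", x$expected, "\n  actual   ", x$actual, "\n", sep = "")
  }
  invisible(x)
}
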