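# Reading, writing and building QV documents.

#' Parse a QV document from text
#'
#' Accepts YAML (default) or JSON. Group sentinels (`group: 'any_of: start'` /
#' `'any_of: end'`) are normalized into nested groups, typographic operator
#' artifacts (`'> ='`) are normalized, a top-level `descriptions` block is
#' folded into `meta`, and unknown top-level keys are preserved under the
#' document's extra slot. Schema problems do not raise conditions here: run
#' [validate_qv()] on the result.
#'
#' @param text Character scalar or raw vector of document text.
#' @param format `"auto"` (default; sniffs JSON by a leading `{`), `"yaml"`,
#'   or `"json"`.
#' @return A `qv_file`.
#' @examples
#' doc <- parse_qv("
#' meta:
#'   qv_set_id: qv_x_v1_20250101
#'   title: Minimal
#'   version: 1.0.0
#' filters:
#'   min_qual: {logic: keep_if, field: QUAL, operator: '>=', value: 30}
#' ")
#' doc$filters[[1]]$condition
#' @export
parse_qv <- function(text, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (is.raw(text)) text <- rawToChar(text)
  text <- paste(text, collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*\\{", text)) "json" else "yaml"
  }
  x <- if (format == "json") {
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(text)
  }
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("QV document must be a mapping at the top level", call. = FALSE)
  as_qv_file(x, source_format = format)
}

#' Read a QV document from a file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param format Serialization format; `"auto"` uses the file extension.
#' @return A `qv_file`.
#' @export
read_qv <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  parse_qv(readChar(path, file.size(path), useBytes = TRUE), format = format)
}

as_qv_file <- function(x, source_format = NA_character_) {
  known <- c("meta", "filters", "criteria", "notes", "descriptions")
  meta <- x$meta %||% list()
  if (!is.null(x$descriptions)) meta <- utils::modifyList(meta, x$descriptions)
  for (key in c("authors", "tags")) {
    if (!is.null(meta[[key]])) meta[[key]] <- as.character(unlist(meta[[key]]))
  }
  # fold whitespace in free-text scalars (YAML block scalars keep newlines)
  for (key in setdiff(names(meta), c("authors", "tags"))) {
    if (is.character(meta[[key]]) && length(meta[[key]]) == 1) {
      meta[[key]] <- squash_text(meta[[key]])
    }
  }
  filters <- parse_rule_block(x$filters, kind = "filter")
  criteria <- parse_rule_block(x$criteria, kind = "criterion")
  notes <- as.character(unlist(x$notes %||% character()))
  extra <- x[setdiff(names(x), known)]
  qv_file(
    meta = meta, filters = filters, criteria = criteria, notes = notes,
    extra = extra, source_format = source_format
  )
}

# Rule blocks come in two shapes: a mapping name -> body (the YAML-native
# form) or an array of bodies each carrying a `name` key (the canonical JSON
# form).
parse_rule_block <- function(block, kind) {
  if (is.null(block) || !length(block)) {
    return(list())
  }
  if (!is.list(block)) stop(kind, " block must be a mapping or list", call. = FALSE)
  nm <- names(block)
  entries <- if (!is.null(nm) && all(nzchar(nm))) {
    Map(function(name, body) c(list(name = name), body), nm, unname(block))
  } else {
    block
  }
  lapply(entries, function(body) {
    if (kind == "filter") parse_filter(body) else parse_criterion(body)
  })
}

parse_filter <- function(body) {
  if (!is.list(body)) {
    return(structure(list(name = NA_character_, raw = body), class = "list"))
  }
  cond <- NULL
  if (!is.null(body$field)) {
    cond <- qv_condition(body$field, body$operator %||% "", body$value)
  } else if (!is.null(body$condition)) {
    cond <- normalize_condition(body$condition)
  } else if (!is.null(body$any_of) || !is.null(body$all_of)) {
    mode <- if (!is.null(body$any_of)) "any_of" else "all_of"
    cond <- qv_group(mode, normalize_condition_list(body[[mode]]))
  } else if (!is.null(body$conditions)) {
    members <- normalize_condition_list(body$conditions)
    cond <- if (length(members) == 1) members[[1]] else qv_group("all_of", members)
  }
  qv_filter(
    name = body$name %||% NA_character_,
    logic = body$logic %||% NA_character_,
    condition = cond,
    description = squash_text(body$description),
    sample_aggregation = body$sample_aggregation
  )
}

parse_criterion <- function(body) {
  if (!is.list(body)) {
    return(structure(list(name = NA_character_, raw = body), class = "list"))
  }
  conds <- if (!is.null(body$conditions)) {
    normalize_condition_list(body$conditions)
  } else if (!is.null(body$field)) {
    list(qv_condition(body$field, body$operator %||% "", body$value))
  } else {
    list()
  }
  qv_criterion(
    name = body$name %||% NA_character_,
    logic = body$logic %||% "and",
    conditions = conds,
    description = squash_text(body$description)
  )
}

squash_text <- function(x) {
  if (is.null(x)) {
    return(NULL)
  }
  trimws(gsub("[[:space:]]+", " ", paste(as.character(x), collapse = " ")))
}

# A condition list may contain plain conditions, nested groups, and
# `group: 'any_of: start' ... 'any_of: end'` sentinel pairs, which are folded
# into nested groups with a stack.
normalize_condition_list <- function(lst) {
  if (is.null(lst)) {
    return(list())
  }
  if (!is.null(names(lst)) && any(names(lst) %in% c("field", "any_of", "all_of"))) {
    lst <- list(lst) # a single condition written without list markers
  }
  root <- list(members = list())
  stack <- list(root)
  push <- function(item) {
    top <- stack[[length(stack)]]
    top$members[[length(top$members) + 1]] <- item
    stack[[length(stack)]] <<- top
  }
  for (entry in lst) {
    sent <- sentinel_of(entry)
    if (!is.null(sent)) {
      if (sent$edge == "start") {
        stack[[length(stack) + 1]] <- list(mode = sent$mode, members = list())
      } else {
        if (length(stack) == 1) {
          stop("unmatched group sentinel '", sent$mode, ": end'", call. = FALSE)
        }
        closed <- stack[[length(stack)]]
        if (closed$mode != sent$mode) {
          stop(
            "mismatched group sentinels: '", closed$mode, ": start' closed by '",
            sent$mode, ": end'",
            call. = FALSE
          )
        }
        stack[[length(stack)]] <- NULL
        push(qv_group(closed$mode, closed$members))
      }
    } else {
      push(normalize_condition(entry))
    }
  }
  if (length(stack) > 1) {
    stop("unclosed group sentinel '", stack[[length(stack)]]$mode, ": start'",
      call. = FALSE
    )
  }
  stack[[1]]$members
}

sentinel_of <- function(entry) {
  g <- NULL
  if (is.character(entry) && length(entry) == 1) g <- entry
  if (is.list(entry) && length(entry) == 1 && identical(names(entry), "group")) {
    v <- entry$group
    if (is.character(v)) g <- v
    if (is.list(v) && length(v) == 1 && names(v) %in% c("any_of", "all_of")) {
      g <- paste0(names(v), ": ", v[[1]])
    }
  }
  if (is.null(g)) {
    return(NULL)
  }
  m <- regmatches(g, regexec("^\\s*(any_of|all_of)\\s*:\\s*(start|end)\\s*$", g))[[1]]
  if (!length(m)) {
    return(NULL)
  }
  list(mode = m[2], edge = m[3])
}

normalize_condition <- function(x) {
  if (inherits(x, "qv_condition") || inherits(x, "qv_group")) {
    return(x)
  }
  if (!is.list(x)) stop("condition must be a mapping, got ", class(x)[1], call. = FALSE)
  if (!is.null(x$field)) {
    val <- x$value
    if (is.list(val) && all(lengths(val) == 1)) val <- unlist(val)
    return(qv_condition(x$field, x$operator %||% "", val))
  }
  for (mode in c("any_of", "all_of")) {
    if (!is.null(x[[mode]])) {
      return(qv_group(mode, normalize_condition_list(x[[mode]])))
    }
  }
  if (!is.null(x$group) && is.list(x$group)) {
    return(normalize_condition(x$group))
  }
  stop("condition mapping has neither a field nor an any_of/all_of group", call. = FALSE)
}

# ---- serialization ---------------------------------------------------------

emit_condition <- function(x, flat_ok = FALSE) {
  if (inherits(x, "qv_group")) {
    out <- list()
    out[[x$mode]] <- lapply(x$members, emit_condition)
    return(out)
  }
  compact(list(field = x$field, operator = x$operator, value = canon_scalar(x$value)))
}

#' Serialize a QV document
#'
#' Emits a document that [parse_qv()] maps back to an equal `qv_file`
#' (equality up to canonical form, see [canonicalize_qv()]).
#'
#' @param doc A `qv_file`.
#' @param format `"yaml"` (default) or `"json"`.
#' @return Character scalar of serialized text.
#' @export
serialize_qv <- function(doc, format = c("yaml", "json")) {
  format <- match.arg(format)
  filters <- stats::setNames(
    lapply(doc$filters, function(f) {
      body <- compact(list(
        description = f$description,
        logic = f$logic,
        sample_aggregation = f$sample_aggregation
      ))
      if (inherits(f$condition, "qv_condition")) {
        c(body, emit_condition(f$condition))
      } else {
        c(body, list(condition = emit_condition(f$condition)))
      }
    }),
    vapply(doc$filters, `[[`, "", "name")
  )
  criteria <- stats::setNames(
    lapply(doc$criteria, function(cr) {
      compact(list(
        description = cr$description,
        logic = cr$logic,
        conditions = lapply(cr$conditions, emit_condition)
      ))
    }),
    vapply(doc$criteria, `[[`, "", "name")
  )
  top <- compact(list(
    meta = compact(doc$meta),
    filters = filters,
    criteria = criteria,
    notes = as.list(doc$notes)
  ))
  if (length(doc$extra)) top <- c(top, doc$extra)
  if (format == "yaml") {
    yaml::as.yaml(top, indent = 2)
  } else {
    paste0(as.character(jsonlite::toJSON(top,
      auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null"
    )), "\n")
  }
}

#' Write a QV document to a file
#'
#' @param doc A `qv_file`.
#' @param path Output path; extension picks the format unless given.
#' @param format `"auto"`, `"yaml"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_qv <- function(doc, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  writeLines(sub("\n$", "", serialize_qv(doc, format)), path, useBytes = TRUE)
  invisible(path)
}

# ---- statement builder -----------------------------------------------------

# Paths whose repeated statements append rather than override.
qv_list_paths <- c("notes", "meta.authors", "meta.tags")

#' Build a QV document from flat key=value statements
#'
#' The textual counterpart of a form-based QV builder: each statement is a
#' dotted path and a scalar value, e.g.
#' `filters.region_include.logic=keep_if`. Later statements on a path override
#' earlier ones; the list-valued paths `notes`, `meta.authors` and `meta.tags`
#' append instead; list elements elsewhere are addressed with numeric
#' segments (`criteria.pathogenic.conditions.1.field=CLASS`). Unquoted values
#' are typed integer, then float, then `true`/`false`, else string; quoting
#' forces string. Lines starting with `#` and blank lines are ignored.
#'
#' @param statements Character vector of `path=value` lines, or a data frame
#'   with columns `path` and `value`.
#' @return A `qv_file`.
#' @examples
#' build_from_statements(c(
#'   "meta.qv_set_id=qv_x_v1_20250101",
#'   "meta.version=1.0.0",
#'   "meta.title=T",
#'   "filters.f1.logic=keep_if",
#'   "filters.f1.field=QUAL",
#'   "filters.f1.operator=>=",
#'   "filters.f1.value=30"
#' ))
#' @export
build_from_statements <- function(statements) {
  if (is.data.frame(statements)) {
    stmts <- tibble::tibble(
      path = as.character(statements$path),
      value = as.character(statements$value)
    )
  } else {
    lines <- trimws(statements)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    eq <- regexpr("=", lines, fixed = TRUE)
    if (any(eq < 0)) {
      stop("statement without '=': ", dQuote(lines[eq < 0][1]), call. = FALSE)
    }
    stmts <- tibble::tibble(
      path = trimws(substr(lines, 1, eq - 1)),
      value = trimws(substr(lines, eq + 1, nchar(lines)))
    )
  }
  if (any(!nzchar(stmts$path))) stop("statement with empty path", call. = FALSE)
  doc <- list()
  for (i in seq_len(nrow(stmts))) {
    doc <- set_path(
      doc, strsplit(stmts$path[i], ".", fixed = TRUE)[[1]],
      typed_value(stmts$value[i]), stmts$path[i]
    )
  }
  as_qv_file(doc, source_format = NA_character_)
}

typed_value <- function(s) {
  if (grepl("^\".*\"$", s) || grepl("^'.*'$", s)) {
    return(substr(s, 2, nchar(s) - 1))
  }
  if (grepl("^[+-]?[0-9]+$", s)) {
    return(as.integer(s))
  }
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
    return(as.numeric(s))
  }
  if (s %in% c("true", "false")) {
    return(s == "true")
  }
  s
}

set_path <- function(doc, segs, value, full_path) {
  if (any(!nzchar(segs))) {
    stop("malformed statement path ", dQuote(full_path), call. = FALSE)
  }
  assign_in <- function(node, segs, prefix) {
    key <- segs[1]
    if (length(segs) == 1) {
      here <- paste(c(prefix, key), collapse = ".")
      existing <- node[[key]]
      if (!is.null(existing) && is.list(existing)) {
        stop("type conflict at ", dQuote(here),
          ": a mapping cannot be overwritten by a scalar",
          call. = FALSE
        )
      }
      if (here %in% qv_list_paths && !is.null(existing)) {
        node[[key]] <- c(existing, value)
      } else {
        node[[key]] <- value
      }
      return(node)
    }
    child <- node[[key]]
    if (is.null(child)) child <- list()
    if (!is.list(child)) {
      stop("type conflict at ", dQuote(paste(c(prefix, key), collapse = ".")),
        ": a scalar cannot be extended with nested keys",
        call. = FALSE
      )
    }
    node[[key]] <- assign_in(child, segs[-1], c(prefix, key))
    node
  }
  assign_in(doc, segs, character())
}
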