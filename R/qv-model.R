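# Domain types and structural rules for qualifying-variant (QV) criteria
# documents: meta, filters, criteria, notes, descriptions.

#' Closed operator set for QV conditions
#'
#' Comparison operators a QV condition may use. Anything else is a schema
#' violation reported by [validate_qv()].
#'
#' @format Character vector of operator tokens.
#' @export
qv_operators <- c("==", "!=", ">", ">=", "<", "<=", "in", "not_in")

qv_id_pattern <- "^[a-z0-9_]+_v[0-9]+(\\.[0-9]+)*_[0-9]{8}$"
qv_semver_pattern <- "^[0-9]+\\.[0-9]+\\.[0-9]+$"

#' Construct a single QV condition
#'
#' A condition is one field--operator--value test. Fields live in the
#' namespaces `QUAL`, `INFO/<key>`, `FORMAT/<key>` (per-sample), a bare
#' annotation column name (e.g. `CLASS`), or `OVERLAP(<bed path>)`.
#'
#' @param field Field expression string.
#' @param operator One of [qv_operators]. Typographic variants such as
#'   `"> ="` are normalized.
#' @param value Scalar, or vector for `in`/`not_in`.
#' @return A `qv_condition` object.
#' @examples
#' qv_condition("CLASS", "==", "P")
#' qv_condition("FORMAT/GQ", ">=", 20)
#' @export
qv_condition <- function(field, operator, value) {
  structure(
    list(
      field = as.character(field)[1],
      operator = normalize_operator(operator),
      value = value
    ),
    class = "qv_condition"
  )
}

#' Combine conditions into a compound logic block
#'
#' @param mode `"any_of"` (disjunction) or `"all_of"` (conjunction).
#' @param members List of `qv_condition` or nested `qv_group` objects.
#' @return A `qv_group` object.
#' @examples
#' qv_group("any_of", list(
#'   qv_condition("CLASS", "==", "P"),
#'   qv_condition("CLASS", "==", "LP")
#' ))
#' @export
qv_group <- function(mode, members) {
  structure(
    list(mode = as.character(mode)[1], members = members),
    class = "qv_group"
  )
}

#' Construct a QV filter rule
#'
#' Filters keep or drop whole variant records. When the condition touches any
#' `FORMAT/*` field the outcome is computed per sample and aggregated across
#' samples according to `sample_aggregation`.
#'
#' @param name Rule identifier.
#' @param logic `"keep_if"` or `"drop_if"`.
#' @param condition A `qv_condition` or `qv_group`.
#' @param description Optional free text.
#' @param sample_aggregation `"all_samples"` or `"any_sample"`; only meaningful
#'   for per-sample conditions. Defaults to `"all_samples"` at evaluation time.
#' @return A `qv_filter` object.
#' @export
qv_filter <- function(name, logic, condition, description = NULL,
                      sample_aggregation = NULL) {
  structure(
    list(
      name = as.character(name)[1],
      description = description,
      logic = as.character(logic)[1],
      condition = condition,
      sample_aggregation = sample_aggregation
    ),
    class = "qv_filter"
  )
}

#' Construct a QV criterion
#'
#' Criteria never remove records: they attach a boolean flag per variant (or
#' per variant--sample pair when any member condition is per-sample), e.g.
#' ACMG-style evidence codes.
#'
#' @param name Criterion identifier (e.g. `"ACMG_PS1"`).
#' @param logic `"and"` or `"or"` over `conditions`.
#' @param conditions List of `qv_condition` / `qv_group`.
#' @param description Optional free text.
#' @return A `qv_criterion` object.
#' @export
qv_criterion <- function(name, logic = "and", conditions, description = NULL) {
  structure(
    list(
      name = as.character(name)[1],
      description = description,
      logic = as.character(logic)[1],
      conditions = conditions
    ),
    class = "qv_criterion"
  )
}

#' Construct a QV document in memory
#'
#' The five logical components: meta (identification and optional
#' patient/PPIE descriptions), filters, criteria, notes, and free-text
#' descriptions carried inside meta.
#'
#' @param meta Named list; requires `qv_set_id`, `title`, `version`. Optional:
#'   `authors`, `date`, `tags`, `description_patient`, `description_ppie`.
#' @param filters List of `qv_filter`.
#' @param criteria List of `qv_criterion`.
#' @param notes Character vector of free-text notes.
#' @param extra Named list of unknown top-level keys, preserved on round trip
#'   and flagged as warnings by [validate_qv()].
#' @param source_format `"yaml"`, `"json"`, or `NA` when built in memory.
#' @return A `qv_file` object.
#' @examples
#' doc <- qv_file(
#'   meta = list(
#'     qv_set_id = "qv_example_v1_20250828",
#'     title = "Example", version = "1.0.0"
#'   ),
#'   filters = list(qv_filter("min_qual", "keep_if",
#'     qv_condition("QUAL", ">=", 30)
#'   ))
#' )
#' qv_is_valid(validate_qv(doc))
#' @export
qv_file <- function(meta, filters = list(), criteria = list(),
                    notes = character(), extra = list(),
                    source_format = NA_character_) {
  structure(
    list(
      meta = meta,
      filters = filters,
      criteria = criteria,
      notes = as.character(notes),
      extra = extra
    ),
    source_format = source_format,
    class = "qv_file"
  )
}

#' @export
print.qv_file <- function(x, ...) {
  cat("<qv_file> ", x$meta$qv_set_id %||% "<no id>",
    " (version ", x$meta$version %||% "?", ")\n",
    sep = ""
  )
  cat("  title:    ", x$meta$title %||% "", "\n", sep = "")
  cat("  filters:  ", length(x$filters),
    if (length(x$filters)) paste0(" [", paste(vapply(x$filters, `[[`, "", "name"),
      collapse = ", "
    ), "]") else "", "\n",
    sep = ""
  )
  cat("  criteria: ", length(x$criteria),
    if (length(x$criteria)) paste0(" [", paste(vapply(x$criteria, `[[`, "", "name"),
      collapse = ", "
    ), "]") else "", "\n",
    sep = ""
  )
  if (length(x$notes)) cat("  notes:    ", length(x$notes), "\n", sep = "")
  invisible(x)
}

# Normalize operator tokens: strip typographic primes/quotes and internal
# whitespace, so the printed forms like "'> ='" parse to ">=".
normalize_operator <- function(op) {
  op <- as.character(op)[1]
  op <- gsub("[′″‘’“”'\"`]", "", op)
  op <- gsub("[[:space:]]+", "", op)
  op
}

#' Compose a QV set identifier
#'
#' Identifiers follow `<name>_v<major>_<YYYYMMDD>`, e.g.
#' `qv_disease_panel_v1_20250828`.
#'
#' @param name Lowercase alphanumeric/underscore token.
#' @param major Major version integer (or dotted string like `"3.3"`).
#' @param date A `Date` or ISO-8601 date string.
#' @return Identifier string matching the QV identifier pattern.
#' @examples
#' make_qv_set_id("qv_disease_panel", 1, "2025-08-28")
#' @export
make_qv_set_id <- function(name, major, date) {
  name <- as.character(name)[1]
  if (!grepl("^[a-z0-9_]+$", name)) {
    stop("qv_set_id name must be lowercase alphanumeric/underscore, got ",
      dQuote(name),
      call. = FALSE
    )
  }
  major <- as.character(major)[1]
  if (!grepl("^[0-9]+(\\.[0-9]+)*$", major)) {
    stop("major version must be an integer or dotted integers, got ",
      dQuote(major),
      call. = FALSE
    )
  }
  date <- as.Date(date)
  if (is.na(date)) stop("date must be an ISO-8601 date", call. = FALSE)
  sprintf("%s_v%s_%s", name, major, format(date, "%Y%m%d"))
}

violation <- function(path, message, severity = "error") {
  tibble::tibble(path = path, severity = severity, message = message)
}

empty_report <- function() {
  tibble::tibble(
    path = character(), severity = character(), message = character()
  )
}

#' Structurally validate a QV document
#'
#' Validation is total: any parsed document yields a report, never an error.
#' Violations are rows, not exceptions; an empty report (no `error` rows and
#' no `warning` rows) means the document is fully clean, and [qv_is_valid()]
#' checks for the absence of `error` rows.
#'
#' @param doc A `qv_file`.
#' @return A tibble with columns `path`, `severity` (`error`/`warning`),
#'   `message`.
#' @examples
#' doc <- qv_file(meta = list(title = "no id"))
#' validate_qv(doc)
#' @export
validate_qv <- function(doc) {
  stopifnot(inherits(doc, "qv_file"))
  out <- list()
  add <- function(...) out[[length(out) + 1]] <<- violation(...)

  meta <- doc$meta
  if (is.null(meta) || !length(meta)) {
    add("meta", "mandatory meta component is missing")
  } else {
    id <- meta$qv_set_id
    if (is.null(id) || !nzchar(id %||% "")) {
      add("meta.qv_set_id", "mandatory field qv_set_id is missing or empty")
    } else if (!grepl(qv_id_pattern, id)) {
      add(
        "meta.qv_set_id",
        sprintf(
          "qv_set_id %s does not match the identifier pattern %s",
          dQuote(id), qv_id_pattern
        )
      )
    }
    ver <- meta$version
    if (is.null(ver) || !nzchar(as.character(ver)[1] %||% "")) {
      add("meta.version", "mandatory field version is missing")
    } else if (!grepl(qv_semver_pattern, as.character(ver)[1])) {
      add(
        "meta.version",
        sprintf(
          "version %s is not MAJOR.MINOR.PATCH",
          dQuote(as.character(ver)[1])
        )
      )
    }
    if (is.null(meta$title) || !nzchar(meta$title %||% "")) {
      add("meta.title", "mandatory field title is missing", "warning")
    }
    if (!is.null(meta$date) &&
      !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}", as.character(meta$date)[1])) {
      add("meta.date", "date is not ISO-8601 (YYYY-MM-DD)", "warning")
    }
  }

  if (!length(doc$filters) && !length(doc$criteria)) {
    add("filters", "document defines neither filters nor criteria", "warning")
  }

  for (i in seq_along(doc$filters)) {
    f <- doc$filters[[i]]
    path <- paste0("filters.", f$name %||% i)
    if (!inherits(f, "qv_filter")) {
      add(path, "filter entry is not a recognizable rule mapping")
      next
    }
    if (!(f$logic %||% "") %in% c("keep_if", "drop_if")) {
      add(
        paste0(path, ".logic"),
        sprintf(
          "logic must be keep_if or drop_if, got %s",
          dQuote(f$logic %||% "<missing>")
        )
      )
    }
    if (!is.null(f$sample_aggregation) &&
      !f$sample_aggregation %in% c("all_samples", "any_sample")) {
      add(
        paste0(path, ".sample_aggregation"),
        "sample_aggregation must be all_samples or any_sample"
      )
    }
    if (is.null(f$condition)) {
      add(paste0(path, ".condition"), "filter has no condition")
    } else {
      out <- c(out, list(validate_condition(f$condition, paste0(path, ".condition"))))
    }
  }

  for (i in seq_along(doc$criteria)) {
    cr <- doc$criteria[[i]]
    path <- paste0("criteria.", cr$name %||% i)
    if (!inherits(cr, "qv_criterion")) {
      add(path, "criterion entry is not a recognizable mapping")
      next
    }
    if (!(cr$logic %||% "") %in% c("and", "or")) {
      add(
        paste0(path, ".logic"),
        sprintf("logic must be and or or, got %s", dQuote(cr$logic %||% "<missing>"))
      )
    }
    if (!length(cr$conditions)) {
      add(paste0(path, ".conditions"), "criterion has no conditions")
    } else {
      for (j in seq_along(cr$conditions)) {
        out <- c(out, list(validate_condition(
          cr$conditions[[j]],
          paste0(path, ".conditions.", j)
        )))
      }
    }
  }

  for (key in names(doc$extra)) {
    add(key, sprintf("unknown top-level key %s preserved but ignored", dQuote(key)),
      severity = "warning"
    )
  }

  dplyr::bind_rows(empty_report(), out)
}

validate_condition <- function(x, path) {
  if (inherits(x, "qv_group")) {
    out <- list()
    if (!(x$mode %||% "") %in% c("any_of", "all_of")) {
      out[[length(out) + 1]] <- violation(
        paste0(path, ".mode"),
        sprintf("group mode must be any_of or all_of, got %s", dQuote(x$mode %||% "<missing>"))
      )
    }
    if (!length(x$members)) {
      out[[length(out) + 1]] <- violation(path, "group has no members")
    }
    for (j in seq_along(x$members)) {
      out[[length(out) + 1]] <- validate_condition(
        x$members[[j]],
        paste0(path, ".", j)
      )
    }
    return(dplyr::bind_rows(empty_report(), out))
  }
  if (!inherits(x, "qv_condition")) {
    return(violation(path, "condition is not a field/operator/value mapping or group"))
  }
  out <- list()
  if (is.null(x$field) || !nzchar(x$field %||% "")) {
    out[[length(out) + 1]] <- violation(paste0(path, ".field"), "field is missing or empty")
  } else if (!grepl(
    "^(QUAL|INFO/[A-Za-z_][A-Za-z0-9_.]*|FORMAT/[A-Za-z_][A-Za-z0-9_.]*|OVERLAP\\(.+\\)|[A-Za-z_][A-Za-z0-9_.]*)$",
    x$field
  )) {
    out[[length(out) + 1]] <- violation(
      paste0(path, ".field"),
      sprintf("field expression %s is not in a declared namespace (QUAL, INFO/*, FORMAT/*, annotation column, OVERLAP())", dQuote(x$field))
    )
  }
  if (!(x$operator %||% "") %in% qv_operators) {
    out[[length(out) + 1]] <- violation(
      paste0(path, ".operator"),
      sprintf(
        "operator %s is not in the closed set {%s}",
        dQuote(x$operator %||% "<missing>"), paste(qv_operators, collapse = ", ")
      )
    )
  }
  if (is.null(x$value) || (length(x$value) == 0)) {
    out[[length(out) + 1]] <- violation(paste0(path, ".value"), "value is missing")
  }
  dplyr::bind_rows(empty_report(), out)
}

#' Does a validation report contain no errors?
#'
#' @param report Tibble from [validate_qv()].
#' @return `TRUE` when no `error`-severity rows are present (warnings are
#'   allowed).
#' @export
qv_is_valid <- function(report) {
  !any(report$severity == "error")
}

# ---- canonical form --------------------------------------------------------

canon_scalar <- function(v) {
  if (is.numeric(v) && length(v) == 1 && !is.na(v) &&
    is.finite(v) && v == round(v) && abs(v) < .Machine$integer.max) {
    return(as.integer(v))
  }
  v
}

canon_condition <- function(x) {
  if (inherits(x, "qv_group")) {
    members <- lapply(x$members, canon_condition)
    out <- list()
    out[[x$mode]] <- members
    return(out)
  }
  val <- x$value
  val <- if (length(val) > 1) lapply(val, canon_scalar) else canon_scalar(val)
  list(field = x$field, operator = x$operator, value = val)
}

compact <- function(x) {
  x[!vapply(x, function(v) is.null(v) || (is.character(v) && !length(v)) ||
    (is.list(v) && !length(v)), logical(1))]
}

canon_document <- function(doc) {
  meta <- compact(doc$meta)
  meta <- lapply(meta, canon_scalar)
  meta <- meta[order(names(meta))]
  filters <- unname(lapply(doc$filters, function(f) {
    out <- compact(list(
      condition = canon_condition(f$condition),
      description = f$description,
      logic = f$logic,
      name = f$name,
      sample_aggregation = f$sample_aggregation
    ))
    out[order(names(out))]
  }))
  criteria <- unname(lapply(doc$criteria, function(cr) {
    out <- compact(list(
      conditions = lapply(cr$conditions, canon_condition),
      description = cr$description,
      logic = cr$logic,
      name = cr$name
    ))
    out[order(names(out))]
  }))
  top <- compact(list(
    criteria = criteria,
    filters = filters,
    meta = meta,
    notes = as.list(doc$notes)
  ))
  extra <- doc$extra
  if (length(extra)) top <- c(top, extra)
  top[order(names(top))]
}

# Mark scalars for auto_unbox-free deterministic JSON.
canon_jsonify <- function(x) {
  if (is.list(x)) {
    return(lapply(x, canon_jsonify))
  }
  if (length(x) == 1) {
    return(jsonlite::unbox(x))
  }
  as.list(x) |> lapply(canon_jsonify)
}

#' Canonical byte form of a QV document
#'
#' Deterministic serialization used for checksums: UTF-8 JSON with keys sorted
#' lexicographically at every level, normalized scalars (integer-valued
#' numbers as integers, group sentinels resolved, operators normalized),
#' empty/optional fields dropped, and a single trailing newline. The same
#' logical document parsed from YAML or JSON canonicalizes to identical bytes,
#' and canonicalization is a fixed point: parsing the canonical bytes and
#' canonicalizing again reproduces them.
#'
#' @param doc A `qv_file`.
#' @return Raw vector of canonical bytes.
#' @examples
#' doc <- qv_file(meta = list(
#'   qv_set_id = "qv_x_v1_20250101",
#'   title = "x", version = "1.0.0"
#' ))
#' rawToChar(canonicalize_qv(doc))
#' @export
canonicalize_qv <- function(doc) {
  stopifnot(inherits(doc, "qv_file"))
  top <- canon_document(doc)
  json <- jsonlite::toJSON(canon_jsonify(top),
    auto_unbox = FALSE, digits = NA, null = "null", na = "null"
  )
  charToRaw(paste0(as.character(json), "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
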