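# broom-style tidiers and ggplot2 autoplot methods for qvtools result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a QV apply result
#'
#' @param x A `qv_result` from [apply_qv()].
#' @param ... Unused.
#' @return The per-rule summary tibble (`rule`, `logic`, `evaluated`, `kept`,
#'   `dropped`, `dropped_missing`).
#' @method tidy qv_result
#' @export
tidy.qv_result <- function(x, ...) {
  x$summary
}

#' @rdname tidy.qv_result
#' @return For `glance()`: a one-row tibble with `qv_set_id`, `n_input`,
#'   `n_kept`, `n_rules`, `n_criteria`, `n_flagged`.
#' @method glance qv_result
#' @export
glance.qv_result <- function(x, ...) {
  tibble::tibble(
    qv_set_id = x$qv_set_id,
    n_input = x$n_input,
    n_kept = nrow(x$kept),
    n_rules = nrow(x$summary),
    n_criteria = length(unique(x$flags$criterion)),
    n_flagged = length(unique(variant_key(dplyr::filter(x$flags, .data$flag))))
  )
}

#' Tidy a GWAS QC result
#'
#' @param x A `qv_qc` from [apply_gwas_qc()].
#' @param ... Unused.
#' @return The per-step counts tibble.
#' @method tidy qv_qc
#' @export
tidy.qv_qc <- function(x, ...) {
  x$steps
}

#' @rdname tidy.qv_qc
#' @method glance qv_qc
#' @export
glance.qv_qc <- function(x, ...) {
  tibble::tibble(
    n_samples_kept = length(x$kept_samples),
    n_variants_kept = length(x$kept_variants),
    n_steps = nrow(x$steps),
    n_removed = sum(x$steps$n_removed)
  )
}

#' Flatten a QV document into a tibble of rules
#'
#' One row per condition, with the component (filter/criterion), rule name,
#' logic, group path, field, operator, and value rendered as text.
#'
#' @param x A `qv_file`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy qv_file
#' @export
tidy.qv_file <- function(x, ...) {
  rows <- list()
  walk <- function(node, component, name, logic, path) {
    if (inherits(node, "qv_group")) {
      for (i in seq_along(node$members)) {
        walk(
          node$members[[i]], component, name, logic,
          paste0(path, if (nzchar(path)) "." else "", node$mode, "[", i, "]")
        )
      }
    } else if (inherits(node, "qv_condition")) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        component = component, name = name, logic = logic, group = path,
        field = node$field, operator = node$operator,
        value = paste(as.character(node$value), collapse = ",")
      )
    }
  }
  for (f in x$filters) walk(f$condition, "filter", f$name, f$logic, "")
  for (cr in x$criteria) {
    for (i in seq_along(cr$conditions)) {
      walk(cr$conditions[[i]], "criterion", cr$name, cr$logic, "")
    }
  }
  dplyr::bind_rows(
    tibble::tibble(
      component = character(), name = character(), logic = character(),
      group = character(), field = character(), operator = character(),
      value = character()
    ),
    rows
  )
}

#' Plot per-rule record attrition for a QV apply result
#'
#' Stacked bars of kept versus dropped records per filter rule, in pipeline
#' order.
#'
#' @param object A `qv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qv_result
#' @export
autoplot.qv_result <- function(object, ...) {
  s <- object$summary
  if (!nrow(s)) stop("no filter rules to plot", call. = FALSE)
  long <- tidyr::pivot_longer(
    s[, c("rule", "kept", "dropped")],
    c("kept", "dropped"),
    names_to = "outcome", values_to = "records"
  )
  long$rule <- factor(long$rule, levels = s$rule)
  long$outcome <- factor(long$outcome, levels = c("dropped", "kept"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$rule, y = .data$records, fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(kept = "#2c7fb8", dropped = "#d95f0e")) +
    ggplot2::labs(
      x = "filter rule (pipeline order)", y = "records entering the rule",
      fill = NULL,
      title = object$qv_set_id %|na|% "QV filter pipeline"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-step removals for a GWAS QC result
#'
#' @param object A `qv_qc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qv_qc
#' @export
autoplot.qv_qc <- function(object, ...) {
  s <- object$steps
  s$step <- factor(s$step, levels = s$step)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$step, y = .data$n_removed, fill = .data$axis)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "QC step (applied order)", y = "removed",
      fill = "axis", title = "GWAS quality control"
    ) +
    ggplot2::theme_minimal()
}
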