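# broom-style and ggplot2 methods for the two result classes.

#' Tidy a call set
#'
#' @param x A `shortcall_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble of calls.
#' @export
tidy.shortcall_calls <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' One-row summary of a call set
#'
#' @param x A `shortcall_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble: call counts by type and source, PASS count,
#'   mean quality.
#' @export
glance.shortcall_calls <- function(x, ...) {
  d <- tibble::as_tibble(unclass_tbl(x))
  tibble::tibble(
    n_calls = nrow(d),
    n_snv = sum(d$kind == "SNV"),
    n_indel = sum(d$kind != "SNV"),
    n_pass = sum(d$filter == "PASS"),
    n_hc = sum(d$source == "HC"),
    n_lc = sum(d$source == "LC"),
    n_trc = sum(d$source == "TRC"),
    mean_qual = mean(d$qual)
  )
}

#' Plot a call set
#'
#' Quality histograms faceted by variant kind and coloured by the calling
#' path that produced each record.
#'
#' @param object A `shortcall_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shortcall_calls <- function(object, ...) {
  d <- tibble::as_tibble(unclass_tbl(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$qual, fill = .data$source)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind)) +
    ggplot2::labs(x = "genotype quality (Phred)", y = "calls",
                  fill = "path") +
    ggplot2::theme_minimal()
}

#' Tidy an evaluation result
#'
#' @param x A `shortcall_eval` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per variant type.
#' @export
tidy.shortcall_eval <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' One-row summary of an evaluation
#'
#' @param x A `shortcall_eval` tibble.
#' @param ... Unused.
#' @return A one-row tibble with per-type precision/recall/F1 spread wide.
#' @export
glance.shortcall_eval <- function(x, ...) {
  d <- tibble::as_tibble(unclass_tbl(x))
  d |>
    dplyr::select("type", "precision", "recall", "f1") |>
    tidyr::pivot_wider(names_from = "type",
                       values_from = c("precision", "recall", "f1"),
                       names_glue = "{tolower(type)}_{.value}")
}

#' Plot an evaluation result
#'
#' Precision, recall and F1 bars per variant type.
#'
#' @param object A `shortcall_eval` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shortcall_eval <- function(object, ...) {
  d <- tibble::as_tibble(unclass_tbl(object)) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

# rebuild as a plain tibble, dropping subclass and caller attributes
unclass_tbl <- function(x) {
  tibble::as_tibble(setNames(lapply(names(x), function(n) x[[n]]), names(x)))
}
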