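# ggplot2 views of the result types.

#' Plot an evaluation summary
#'
#' Sensitivity per test class with its Wilson interval, the standard way
#' engine benchmarks are displayed.
#'
#' @param object A `bronx_eval` tibble from [score_side()], or several
#'   row-bound together (an optional `engine` column is mapped to colour).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bronx_eval <- function(object, ...) {
  df <- tibble::as_tibble(object)
  aes_args <- if ("engine" %in% names(df)) {
    ggplot2::aes(x = .data$class, y = .data$sensitivity,
                 colour = .data$engine)
  } else {
    ggplot2::aes(x = .data$class, y = .data$sensitivity)
  }
  ggplot2::ggplot(df, aes_args) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$level)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "test class", y = "sensitivity (95% Wilson CI)")
}

#' Plot a query score table
#'
#' Terminal scores for one query at one level; the margin between the top
#' terminal and the runners-up is the visual evidence for (or against) an
#' unambiguous identification.
#'
#' @param object A `bronx_scores` tibble from [score_query()].
#' @param top Show at most this many terminals (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bronx_scores <- function(object, top = 20L, ...) {
  df <- head(tibble::as_tibble(object), top)
  df$terminal <- factor(df$terminal, levels = rev(df$terminal))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$terminal)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = sprintf("score (out of %d query windows)",
                  attr(object, "n_query_windows")),
      y = NULL,
      title = sprintf("%s-level scores", attr(object, "level"))
    )
}

#' Tidy identification results
#'
#' @param x A `bronx_id` tibble.
#' @param ... Unused.
#' @return A plain tibble with `winners` flattened to a semicolon-joined
#'   string.
#' @export
tidy.bronx_id <- function(x, ...) {
  flatten_identifications(x)
}

#' Summarise identification results
#'
#' @param x A `bronx_id` tibble.
#' @param ... Unused.
#' @return One row per level: query counts, how many were unambiguous,
#'   ambiguous and unidentified.
#' @export
glance.bronx_id <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$level),
    n_queries = dplyr::n(),
    n_unambiguous = sum(!.data$ambiguous & !.data$unidentified),
    n_ambiguous = sum(.data$ambiguous),
    n_unidentified = sum(.data$unidentified),
    .groups = "drop"
  )
}
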