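#' Paired CelTIL change plot
#'
#' Slope chart of scaled CelTIL from baseline to day 21, one line per
#' sample, coloured by direction of change (the classic paired-biopsy
#' display for window-of-opportunity trials).
#'
#' @param pairs Output of [celtil_pairs()].
#' @return A ggplot object.
#' @export
plot_celtil_change <- function(pairs) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(pairs, direction = ifelse(.data$delta >= 0, "increase", "decrease")),
    cols = c("celtil_baseline", "celtil_day21"),
    names_to = "timepoint", values_to = "celtil"
  ) |>
    dplyr::mutate(timepoint = ifelse(.data$timepoint == "celtil_baseline",
                                     "baseline", "day 21"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$celtil,
                                     group = .data$sample_id,
                                     colour = .data$direction)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(increase = "firebrick",
                                            decrease = "steelblue")) +
    ggplot2::labs(x = NULL, y = "CelTIL (scaled, 0-100)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Response rate by group
#'
#' Stacked proportion bars of responders vs non-responders per group
#' (tertile, HER2 IHC category, copy-number cluster, ...).
#'
#' @param data Data frame with one row per sample.
#' @param group Grouping column (tidy-eval).
#' @param responder Logical responder column (tidy-eval; default
#'   `responder`).
#' @return A ggplot object.
#' @export
plot_response_by_group <- function(data, group, responder = responder) {
  group <- rlang::enquo(group)
  responder <- rlang::enquo(responder)
  df <- dplyr::transmute(
    as_tibble(data),
    group = !!group,
    response = ifelse(!!responder, "responder", "non-responder")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, fill = .data$response)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_fill_manual(values = c(`responder` = "firebrick",
                                          `non-responder` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Proportion of samples", fill = NULL) +
    ggplot2::theme_minimal()
}
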