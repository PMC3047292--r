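#' Plot a recruitment funnel
#'
#' Horizontal bar chart of the funnel stages, labelled with counts and shares
#' of the identified net sample.
#'
#' @param object A `cta_funnel` from [funnel_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cta_funnel
#' @export
autoplot.cta_funnel <- function(object, ...) {
  d <- tidy.cta_funnel(object)
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0(.data$n, " (", .data$pct, "%)")),
      hjust = -0.05, size = 3
    ) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.25))) +
    ggplot2::labs(x = "records", y = NULL, title = "Recruitment funnel") +
    ggplot2::theme_minimal()
}

#' Plot stage demography
#'
#' Within-stage stratum shares side by side, making demographic selection
#' across recruitment stages visible (the enrolled bars drifting away from
#' the net-sample bars indicate selection bias).
#'
#' @param object A `cta_strata` tibble from [stage_demography()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cta_strata
#' @export
autoplot.cta_strata <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$stratum, y = .data$pct, fill = .data$stage)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "share within stage (%)",
      title = "Demography by recruitment stage"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-practice enrolment against practice size
#'
#' @param rows A [practice_table()] tibble.
#' @param poor_cutoff Reference line for poor recruitment (default 5%).
#' @return A ggplot object.
#' @export
plot_practice_enrolment <- function(rows, poor_cutoff = 5) {
  ggplot2::ggplot(
    rows,
    ggplot2::aes(x = .data$net_sample, y = .data$enrolment_pct,
                 colour = .data$size_class)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = poor_cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = "net sample (identified EPRs)", y = "enrolment (% of net sample)",
      colour = "practice size", title = "Enrolment by practice size"
    ) +
    ggplot2::theme_minimal()
}
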