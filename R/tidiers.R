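#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chi-square bias test
#'
#' @param x A `cta_bias_test` from [chi_square_bias_test()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p.value`, `method`.
#' @method tidy cta_bias_test
#' @export
tidy.cta_bias_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    method = paste0("Pearson chi-square (", x$mode, ")")
  )
}

#' @rdname tidy.cta_bias_test
#' @method glance cta_bias_test
#' @export
glance.cta_bias_test <- function(x, ...) {
  tidy.cta_bias_test(x)
}

#' Tidy a recruitment funnel into stage rows
#'
#' @param x A `cta_funnel` from [funnel_counts()].
#' @param ... Unused.
#' @return A tibble with one row per funnel stage (`stage`, `n`, `pct` of
#'   identified, half-up to one decimal).
#' @method tidy cta_funnel
#' @export
tidy.cta_funnel <- function(x, ...) {
  tibble::tibble(
    stage = c("identified", "open", "excluded", "contacted", "refused", "enrolled"),
    n = c(x$identified, x$open, x$excluded, x$contacted, x$refused, x$enrolled),
    pct = round_half_up(100 * .data$n / x$identified, 1)
  )
}
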