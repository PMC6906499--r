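#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a discrete probability mass function
#'
#' Column chart of a pmf tibble as returned by [causal_in_sample_pmf()],
#' [rediscovery_pmf()] or `tidy()` of a [druggable_yield()].
#'
#' @param object A `pmf_tbl` (first column the count, `prob` the mass).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pmf_tbl
#' @export
autoplot.pmf_tbl <- function(object, ...) {
  count_col <- names(object)[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[count_col]], y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = count_col, y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a two-stage model fit
#'
#' Bar chart of the declared success rate and discovery rates per stage.
#'
#' @param object A [two_stage()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot two_stage
#' @export
autoplot.two_stage <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::select("stage", "declared_success", "tdr", "fdr") |>
    tidyr::pivot_longer(-"stage", names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$value,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "rate") +
    ggplot2::theme_minimal()
}

#' Plot a back-calculation sweep over preclinical power
#'
#' Traces the inferred prior truth fraction and preclinical false-positive
#' rate against the assumed preclinical power, as returned by
#' [back_calculate_sweep()].
#'
#' @param sweep A tibble from [back_calculate_sweep()].
#' @return A ggplot object.
#' @export
plot_backcalc_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(sweep, c("gamma_pc", "alpha_pc"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power_pc, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "preclinical power (1 - beta_pc)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot overall success across development scenarios
#'
#' Dot plot of the overall declared success rate by scenario from a
#' [development_sweep()] table.
#'
#' @param sweep A tibble from [development_sweep()] carrying `approach`,
#'   `causal_per_disease`, `panel` and `s_o` columns.
#' @return A ggplot object.
#' @export
plot_development_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = factor(.data$causal_per_disease),
                               y = .data$s_o, colour = .data$approach,
                               shape = .data$panel)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "average causal genes per disease",
                  y = "overall declared success rate") +
    ggplot2::theme_minimal()
}
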