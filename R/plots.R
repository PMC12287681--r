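#' Plot the per-year carbon uptake period
#'
#' Horizontal bars from SOS to EOS per year, with the long-term mean SOS and
#' EOS as dashed lines. Years without a defined CUP are omitted.
#'
#' @param results Per-year phenology tibble ([extract_cup_all()]).
#' @return A ggplot.
#' @export
plot_cup <- function(results) {
  d <- dplyr::filter(results, !.data$no_cup)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$year)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$sos_doy, xend = .data$eos_doy,
                   yend = .data$year),
      linewidth = 2, colour = "#2c7fb8"
    ) +
    ggplot2::geom_vline(xintercept = mean(d$sos_doy), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = mean(d$eos_doy), linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Day of year", y = "Year",
                  title = "Net carbon uptake period (SOS to EOS)") +
    ggplot2::theme_minimal()
}

#' Plot per-day-of-year NEE trends by category
#'
#' Theil-Sen slope per day of year, filled when significant, coloured by the
#' six source/sink trend categories.
#'
#' @param doy_trends Output of [doy_trend_analysis()].
#' @return A ggplot.
#' @export
plot_doy_trends <- function(doy_trends) {
  ggplot2::ggplot(
    doy_trends,
    ggplot2::aes(x = .data$doy, y = .data$sen_slope,
                 colour = .data$category, alpha = .data$significant)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3)) +
    ggplot2::labs(x = "Day of year",
                  y = "NEE trend (g C m⁻² d⁻¹ yr⁻¹)",
                  colour = "Category", alpha = "p < alpha") +
    ggplot2::theme_minimal()
}

#' Stacked mean daily driver contributions over the year
#'
#' @param object An [compute_attributions()] result.
#' @param top_n Number of features to show, ranked by total absolute
#'   contribution (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nee_attribution <- function(object, top_n = 10, ...) {
  daily <- mean_daily_attribution(object)
  keep <- daily %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(imp = sum(abs(.data$mean_shap)), .groups = "drop") %>%
    dplyr::slice_max(.data$imp, n = top_n) %>%
    dplyr::pull(.data$feature)
  ggplot2::ggplot(
    dplyr::filter(daily, .data$feature %in% keep),
    ggplot2::aes(x = .data$doy, y = .data$mean_shap, fill = .data$feature)
  ) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::labs(x = "Day of year",
                  y = "Mean SHAP (g C m⁻² d⁻¹)",
                  fill = "Driver") +
    ggplot2::theme_minimal()
}
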