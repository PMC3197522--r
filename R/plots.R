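#' Threshold-sweep curves of path length and clustering
#'
#' Mean L and C per network as a function of the correlation threshold,
#' with standard-error ribbons — path length rises and clustering falls as
#' the threshold tightens.
#'
#' @param results An `rsn_results`.
#' @return A ggplot.
#' @export
plot_threshold_curves <- function(results) {
  stopifnot(inherits(results, "rsn_results"))
  df <- results$metrics_by_threshold |>
    tidyr::pivot_longer(c("L", "C"), names_to = "measure") |>
    dplyr::group_by(.data$network, .data$group, .data$threshold,
                    .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$mean,
                                   colour = .data$network,
                                   linetype = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem,
                                      fill = .data$network),
                         alpha = 0.15, colour = NA) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "correlation threshold T", y = NULL) +
    ggplot2::theme_minimal()
}

#' Group comparison of metrics at the analysis threshold
#'
#' @param results An `rsn_results`.
#' @param metrics Which columns to show.
#' @return A ggplot.
#' @export
plot_group_comparison <- function(results,
                                  metrics = c("C", "L", "sigma", "gamma",
                                              "lambda")) {
  stopifnot(inherits(results, "rsn_results"))
  df <- results$metrics_at_analysis_threshold |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$network, .data$value,
                                   fill = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "col") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), geom = "errorbar",
                          width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Mean relative power spectra per network
#'
#' @param spectra List of `rsn_spectrum` objects (any subjects/networks).
#' @return A ggplot of relative power against frequency.
#' @export
plot_spectra <- function(spectra) {
  df <- purrr::map_dfr(spectra, tidy) |>
    dplyr::group_by(.data$network, .data$freq) |>
    dplyr::summarise(relative_power = mean(.data$relative_power),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$relative_power,
                                   colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = 0.01, xmax = 0.08, ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::labs(x = "frequency (Hz)", y = "relative power") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_threshold_curves autoplot dispatch for results bundles.
#' @param object An `rsn_results`.
#' @param type One of `"threshold_curves"`, `"group"`.
#' @param ... Unused.
#' @export
autoplot.rsn_results <- function(object,
                                 type = c("threshold_curves", "group"),
                                 ...) {
  switch(match.arg(type),
         threshold_curves = plot_threshold_curves(object),
         group = plot_group_comparison(object))
}

#' Heatmap of the cross-network correlation matrix
#'
#' @param object An `rsn_xcor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rsn_xcor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$network_a, .data$network_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
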