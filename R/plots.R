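#' Map a sensitivity field
#'
#' Tile map of per-cell slopes with a diverging palette centered at zero
#' (warming sensitivities red, cooling blue); invalid cells are blank.
#'
#' @param map Sensitivity tibble (`lat`, `lon`, `slope`, `valid`).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_sensitivity_map <- function(map, title = NULL) {
  df <- dplyr::filter(as_tibble(map), .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$slope)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "K per full\ncover gain") +
    ggplot2::labs(x = "Longitude", y = "Latitude", title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sensitivity_map <- function(object, ...) {
  plot_sensitivity_map(object, ...)
}

#' Binned sensitivities against shortwave radiation
#'
#' Points with +/- 1 SE ribbons for the binned forest-minus-openland
#' anomalies of both temperature metrics, with the fitted WLS lines
#' overlaid when fits are supplied.
#'
#' @param bins Output of [bin_site_sensitivity()].
#' @param ta_fit,ts_fit Optional [wls_slope()] fits to draw.
#' @return A ggplot object.
#' @export
plot_binned_sensitivity <- function(bins, ta_fit = NULL, ts_fit = NULL) {
  long <- tidyr::pivot_longer(
    as_tibble(bins),
    cols = c("delta_ts_star", "delta_ta_star"),
    names_to = "metric", values_to = "delta"
  ) |>
    mutate(
      se = if_else(.data$metric == "delta_ts_star", .data$se_ts, .data$se_ta),
      metric = if_else(.data$metric == "delta_ts_star", "Ts", "Ta")
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sw_center,
                                          y = .data$delta,
                                          colour = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$delta - .data$se,
                                      ymax = .data$delta + .data$se,
                                      fill = .data$metric),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(SW[d] ~ (W ~ m^-2)),
                  y = expression(delta * T^"bph*" ~ (K)),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  add_fit <- function(p, fit) {
    if (is.null(fit)) return(p)
    lab <- if (fit$which == "ts") "Ts" else "Ta"
    p + ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                             linetype = 2,
                             colour = if (lab == "Ts") "#d95f02" else "#1b9e77")
  }
  add_fit(add_fit(p, ts_fit), ta_fit)
}

#' @export
autoplot.wls_fit <- function(object, ...) {
  fit_arg <- setNames(list(object), paste0(object$which, "_fit"))
  do.call(plot_binned_sensitivity, c(list(bins = object$bins), fit_arg))
}

#' Latitudinal band comparison of CO2-equivalent effects
#'
#' Grouped bars of the area-weighted band means of the biochemical and the
#' two biophysical CO2-absorption equivalents, with SE error bars.
#'
#' @param ratios Output of [bph_bchem_ratio()], or a tibble of band means
#'   with columns `band`, `bph_mean`, `bchem_mean`.
#' @return A ggplot object.
#' @export
plot_co2e_bands <- function(ratios) {
  long <- tidyr::pivot_longer(as_tibble(ratios),
                              cols = c("bph_mean", "bchem_mean"),
                              names_to = "effect", values_to = "co2e") |>
    mutate(effect = if_else(.data$effect == "bph_mean",
                            "biophysical", "biochemical"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$band, y = .data$co2e,
                                     fill = .data$effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Latitude band",
                  y = expression(delta * CO[2] * e ~ (t ~ ha^-1)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
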