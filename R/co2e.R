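#' Biomass carbon sensitivity to CO2 absorption equivalents
#'
#' Converts a carbon-stock sensitivity (tonnes of carbon per hectare for a
#' full tree cover gain, from the space-for-time estimator applied to a
#' biomass carbon density map) to tonnes of CO2 per hectare via the molar
#' mass ratio 44/12.
#'
#' @param delta_carbon Carbon sensitivity, tC ha-1 (vectorized).
#' @return CO2 absorption equivalent, t CO2 ha-1.
#' @export
carbon_to_co2e <- function(delta_carbon) {
  delta_carbon * 44 / 12
}

#' TCRE from a warming / concentration pair of series
#'
#' The transient climate response to cumulative emissions is the
#' zero-intercept OLS slope of the local warming on cumulative CO2
#' emissions. Concentration-driven experiments report ppm, converted to
#' emitted mass with 7.82 Gt CO2 per ppm and an airborne fraction of 43%
#' (cumulative emissions = delta-ppm x 7.82 / 0.43).
#'
#' @param delta_t Warming series relative to the start, K.
#' @param conc_ppm Atmospheric CO2 concentration series, ppm,
#'   non-decreasing and not constant.
#' @param gt_per_ppm,airborne_fraction Conversion constants.
#' @return TCRE in K per Gt CO2 (scalar).
#' @export
tcre_from_series <- function(delta_t, conc_ppm, gt_per_ppm = GT_PER_PPM,
                             airborne_fraction = AIRBORNE_FRACTION) {
  if (length(delta_t) != length(conc_ppm)) {
    abort("`delta_t` and `conc_ppm` must be aligned series.")
  }
  if (any(diff(conc_ppm) < 0)) abort("`conc_ppm` must be non-decreasing.")
  cum_e <- (conc_ppm - conc_ppm[1]) * gt_per_ppm / airborne_fraction
  if (all(cum_e == 0)) abort("Constant concentration: TCRE undefined.")
  sum(cum_e * delta_t) / sum(cum_e^2)
}

#' Temperature sensitivity as CO2 absorption equivalent
#'
#' Applies `deltaCO2e = deltaT / (TCRE x A_E)` per cell: the mass of CO2
#' whose emission would produce the same local temperature change, spread
#' over the Earth's surface area, expressed per hectare
#' (1 Gt km-2 = 1e7 t ha-1). The sign is then flipped to the absorption
#' convention, so a warming sensitivity becomes a negative absorption
#' equivalent (a climate cost) and a cooling sensitivity a positive one.
#'
#' @param sensitivity Sensitivity map tibble (columns `lat`, `lon`,
#'   `slope` in K, `valid`; e.g. from [estimate_sensitivity_map()] or
#'   [annual_mean_map()]), carrying metric `metric` attribute `"Ts"` or
#'   `"Ta"` if set.
#' @param tcre Tibble with columns `lat`, `lon`, `tcre` (K per Gt CO2) and
#'   optionally `metric`.
#' @param metric `"Ts"` or `"Ta"`; checked against `tcre$metric` when that
#'   column exists.
#' @param a_e Earth surface area, km2 (default 5.1e8).
#' @return Tibble `lat`, `lon`, `co2e` (t ha-1, absorption convention),
#'   `metric`. Cells with missing/zero TCRE where the sensitivity is valid
#'   become `NA` with a warning.
#' @export
temperature_to_co2e <- function(sensitivity, tcre, metric = c("Ts", "Ta"),
                                a_e = EARTH_SURFACE_KM2) {
  metric <- match.arg(metric)
  sensitivity <- as_tibble(sensitivity)
  tcre <- as_tibble(tcre)
  if ("metric" %in% names(tcre) &&
      !all(tcre$metric == metric, na.rm = TRUE)) {
    abort(sprintf("TCRE field is labelled for %s, not %s.",
                  unique(tcre$metric)[1], metric))
  }
  df <- sensitivity |>
    left_join(tcre[, c("lat", "lon", "tcre")], by = c("lat", "lon"))
  slope <- if_else(df$valid, df$slope, NA_real_)
  bad <- !is.na(slope) & (is.na(df$tcre) | df$tcre == 0)
  if (any(bad)) {
    warn(sprintf("%d valid cell(s) have missing or zero TCRE; set to NA.",
                 sum(bad)))
  }
  tcre_v <- if_else(bad, NA_real_, df$tcre)
  # Gt km-2 -> t ha-1 is exactly 1e7 (1 Gt = 1e9 t, 1 km2 = 100 ha)
  emission_equiv <- slope / (tcre_v * a_e) * 1e7
  tibble(lat = df$lat, lon = df$lon, co2e = -emission_equiv,
         metric = metric)
}

#' Ratio of biophysical to biochemical CO2 equivalents by latitude band
#'
#' Per latitude band (and optionally per month of the biophysical map),
#' the ratio of area-weighted mean biophysical CO2 equivalent to the
#' area-weighted mean biochemical CO2 equivalent, with a first-order
#' (delta-method) standard error propagated from the two means. The
#' biochemical map is annual (carbon stocks carry no monthly cycle); the
#' biophysical map may carry a `month` column.
#'
#' @param bph,bchem Tibbles with `lat`, `lon`, `co2e` (t ha-1); `bph` may
#'   also have `month`.
#' @param band_edges Ascending latitude edges (see [band_area_mean()]).
#' @return Tibble per band (x month): `band`, `lat_min`, `lat_max`,
#'   optional `month`, `bph_mean`, `bchem_mean`, `ratio`, `se`. A band
#'   with zero biochemical mean gets an `NA` ratio.
#' @export
bph_bchem_ratio <- function(bph, bchem, band_edges = c(-90, -20, 20, 50, 90)) {
  bph <- as_tibble(bph)
  bchem <- as_tibble(bchem)
  base <- band_area_mean(bchem, band_edges, value = .data$co2e)
  months <- if ("month" %in% names(bph)) unique(bph$month) else NA
  purrr::map_dfr(months, function(mo) {
    sub <- if (is.na(mo)) bph else bph[bph$month == mo, ]
    bm <- band_area_mean(sub, band_edges, value = .data$co2e)
    ratio <- bm$mean / base$mean
    ratio[!is.na(base$mean) & base$mean == 0] <- NA_real_
    se <- abs(ratio) * sqrt((bm$se / bm$mean)^2 + (base$se / base$mean)^2)
    out <- tibble(band = bm$band, lat_min = bm$lat_min, lat_max = bm$lat_max,
                  bph_mean = bm$mean, bchem_mean = base$mean,
                  ratio = ratio, se = se)
    if (!is.na(mo)) out <- mutate(out, month = mo, .before = 1)
    out
  })
}
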