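#' Surface temperature from longwave radiation
#'
#' Inverts the surface radiation balance,
#' `Ts = [(LW_u - (1 - e) LW_d) / (e sigma)]^(1/4)` with
#' `sigma = 5.67e-8 W m-2 K-4`, to recover the radiometric surface
#' temperature from tower-measured upward and downward longwave radiation.
#'
#' @param lw_up,lw_down Upward / downward longwave radiation, W m-2.
#' @param emissivity Surface emissivity in (0, 1].
#' @return Surface temperature, K (vectorized).
#' @export
ts_from_longwave <- function(lw_up, lw_down, emissivity) {
  if (any(emissivity <= 0 | emissivity > 1, na.rm = TRUE)) {
    abort("`emissivity` must lie in (0, 1].")
  }
  radicand <- (lw_up - (1 - emissivity) * lw_down) / (emissivity * SIGMA_SB)
  if (any(radicand <= 0, na.rm = TRUE)) {
    abort("Unphysical radiation pair: LW_u must exceed (1 - emissivity) * LW_d.")
  }
  radicand^0.25
}

#' Emissivity from albedo
#'
#' Default empirical relationship `e = 0.99 - 0.16 * albedo`, clipped to
#' (0, 1]. The linear coefficients are exposed so the relation can be
#' replaced.
#'
#' @param albedo Shortwave albedo in [0, 1].
#' @param intercept,slope Coefficients of the linear relation.
#' @return Emissivity (vectorized).
#' @export
emissivity_from_albedo <- function(albedo, intercept = 0.99, slope = -0.16) {
  if (any(albedo < 0 | albedo > 1, na.rm = TRUE)) {
    abort("`albedo` must lie in [0, 1].")
  }
  pmin(pmax(intercept + slope * albedo, .Machine$double.eps), 1)
}

#' Elevation (lapse-rate) correction of gridded temperature
#'
#' Estimates the local lapse rate as the OLS slope of gridded temperature
#' on gridded elevation over a window around the target cell (the paper
#' uses the 5 x 5 neighborhood), then shifts the cell temperature to the
#' site elevation. A degenerate window (fewer than two distinct
#' elevations) falls back to a zero lapse rate with a warning.
#'
#' @param window_t,window_elev Gridded temperatures (K) and elevations (m)
#'   of the window (vectors of equal length).
#' @param site_elev Site elevation, m.
#' @param cell_t Gridded temperature of the site's cell, K.
#' @param cell_elev Gridded elevation of the site's cell, m.
#' @return The elevation-corrected grid temperature, K.
#' @export
lapse_rate_correct <- function(window_t, window_elev, site_elev, cell_t,
                               cell_elev) {
  ok <- is.finite(window_t) & is.finite(window_elev)
  e <- window_elev[ok]; t <- window_t[ok]
  if (length(unique(e)) < 2) {
    warn("Degenerate elevation window; lapse rate set to 0.")
    lapse <- 0
  } else {
    lapse <- sum((e - mean(e)) * (t - mean(t))) / sum((e - mean(e))^2)
  }
  cell_t + lapse * (site_elev - cell_elev)
}

#' Forest-minus-openland temperature anomalies binned by shortwave radiation
#'
#' With forest and openland records that cannot be matched pairwise, the
#' temperature effect of forestation is recovered by binning both classes
#' on downward shortwave radiation (`[10k, 10k + 10)` W m-2 by default)
#' and differencing the class means of the macroclimate-corrected
#' anomalies: per bin,
#' `deltaT* = mean(T_site - T_grid)_forest - mean(T_site - T_grid)_openland`,
#' computed separately for surface (`ts_site`) and air (`ta_site`)
#' temperature. The standard error is propagated as
#' `sqrt(SE_f^2 + SE_o^2)`; bins with fewer than two records in either
#' class are dropped (their SE is undefined).
#'
#' @param records Tibble with columns `land_class` (`forest`/`openland`),
#'   `sw_down` (W m-2), `ts_site`, `ta_site`, `t_grid` (elevation-corrected
#'   grid temperature), all in K.
#' @param bin_width Bin width in W m-2 (default 10).
#' @return Tibble with one row per retained bin: `bin_lower`, `bin_upper`,
#'   `sw_center`, `delta_ts_star`, `se_ts`, `delta_ta_star`, `se_ta`,
#'   `n_forest`, `n_openland`. Errors when no bin holds both classes.
#' @export
bin_site_sensitivity <- function(records, bin_width = 10) {
  records <- as_tibble(records)
  need <- c("land_class", "sw_down", "ts_site", "ta_site", "t_grid")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(paste0("`records` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  df <- records |>
    mutate(
      bin = floor(.data$sw_down / bin_width),
      anom_ts = .data$ts_site - .data$t_grid,
      anom_ta = .data$ta_site - .data$t_grid
    )
  out <- df |>
    group_by(.data$bin) |>
    summarise(
      n_forest = sum(.data$land_class == "forest"),
      n_openland = sum(.data$land_class == "openland"),
      m_ts_f = mean(.data$anom_ts[.data$land_class == "forest"]),
      m_ts_o = mean(.data$anom_ts[.data$land_class == "openland"]),
      m_ta_f = mean(.data$anom_ta[.data$land_class == "forest"]),
      m_ta_o = mean(.data$anom_ta[.data$land_class == "openland"]),
      se_ts_f = sd(.data$anom_ts[.data$land_class == "forest"]) /
        sqrt(.data$n_forest),
      se_ts_o = sd(.data$anom_ts[.data$land_class == "openland"]) /
        sqrt(.data$n_openland),
      se_ta_f = sd(.data$anom_ta[.data$land_class == "forest"]) /
        sqrt(.data$n_forest),
      se_ta_o = sd(.data$anom_ta[.data$land_class == "openland"]) /
        sqrt(.data$n_openland),
      .groups = "drop"
    ) |>
    filter(.data$n_forest >= 2, .data$n_openland >= 2) |>
    mutate(
      bin_lower = .data$bin * bin_width,
      bin_upper = (.data$bin + 1) * bin_width,
      sw_center = .data$bin_lower + bin_width / 2,
      delta_ts_star = .data$m_ts_f - .data$m_ts_o,
      delta_ta_star = .data$m_ta_f - .data$m_ta_o,
      se_ts = sqrt(.data$se_ts_f^2 + .data$se_ts_o^2),
      se_ta = sqrt(.data$se_ta_f^2 + .data$se_ta_o^2)
    ) |>
    select("bin_lower", "bin_upper", "sw_center", "delta_ts_star", "se_ts",
           "delta_ta_star", "se_ta", "n_forest", "n_openland") |>
    arrange(.data$bin_lower)
  if (nrow(out) == 0) {
    abort("No shortwave bin holds >= 2 records of both forest and openland.")
  }
  out
}

#' Weighted least squares slope of binned sensitivity on shortwave radiation
#'
#' Regresses the binned forest-minus-openland anomalies on the bin-center
#' shortwave radiation with weights equal to the inverse of each bin's
#' standard error. The slope's standard error is propagated from the bin
#' SEs through the linear WLS estimator (not estimated from residuals):
#' the bins are few, but each bin mean's SE is well determined by its many
#' records. With equal SEs in every bin the fit reduces exactly to OLS. A
#' bin with SE = 0 has its weight capped at the largest finite weight
#' (with a warning).
#'
#' @param bins Output of [bin_site_sensitivity()] (>= 3 bins).
#' @param which `"ts"` or `"ta"`: which sensitivity to fit.
#' @return An object of class `wls_fit`: list with `slope` (K per W m-2),
#'   `slope_se`, `intercept`, `intercept_se`, `n_bins`, `which`,
#'   `weighting`, and the `bins` used. Supports [broom::tidy()],
#'   [broom::glance()] and [ggplot2::autoplot()].
#' @export
wls_slope <- function(bins, which = c("ta", "ts")) {
  which <- match.arg(which)
  bins <- as_tibble(bins)
  if (nrow(bins) < 3) abort("Need >= 3 bins for a reported WLS fit.")
  y <- bins[[paste0("delta_", which, "_star")]]
  se <- bins[[paste0("se_", which)]]
  x <- bins$sw_center
  w <- 1 / se
  if (any(!is.finite(w))) {
    finite_max <- max(w[is.finite(w)], na.rm = TRUE)
    if (!is.finite(finite_max)) finite_max <- 1
    warn("Bin(s) with zero standard error; weight capped at the maximum finite weight.")
    w[!is.finite(w)] <- finite_max
  }
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  A <- solve(XtWX, t(X * w))        # 2 x n linear estimator
  beta <- A %*% y
  var_beta <- (A^2) %*% (se^2)
  structure(
    list(
      slope = beta[2], slope_se = sqrt(var_beta[2]),
      intercept = beta[1], intercept_se = sqrt(var_beta[1]),
      n_bins = nrow(bins), which = which,
      weighting = "inverse standard error (1/SE)",
      bins = bins
    ),
    class = "wls_fit"
  )
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("<wls_fit> delta_%s* ~ SW_d over %d bins (weights %s)\n",
              x$which, x$n_bins, x$weighting))
  cat(sprintf("  slope     %.5g +/- %.3g K per W m-2\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %.5g +/- %.3g K\n", x$intercept, x$intercept_se))
  invisible(x)
}

#' Ratio of air- to surface-temperature sensitivity slopes
#'
#' The headline validation statistic: how much of the surface-temperature
#' response to tree cover gain survives in the air temperature, expressed
#' as the ratio of the two fitted slopes (with a first-order, delta-method
#' standard error when fits are supplied).
#'
#' @param ta_fit,ts_fit [wls_slope()] fits, or bare numeric slopes.
#' @return One-row tibble with `ratio` (fraction) and `se` (`NA` for bare
#'   numeric input).
#' @export
slope_ratio <- function(ta_fit, ts_fit) {
  get <- function(f) {
    if (inherits(f, "wls_fit")) c(f$slope, f$slope_se) else c(as.numeric(f), NA)
  }
  a <- get(ta_fit); s <- get(ts_fit)
  if (s[1] == 0) abort("Ts slope is zero; ratio undefined.")
  r <- a[1] / s[1]
  se <- if (any(is.na(c(a[2], s[2])))) NA_real_ else
    abs(r) * sqrt((a[2] / a[1])^2 + (s[2] / s[1])^2)
  tibble(ratio = r, se = se)
}
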