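#' Screen fine pixels before the space-for-time regression
#'
#' Applies the pixel-level screening rules: drop pixels with more than 1%
#' water cover, pixels with less than 10% tree cover (a documented toggle,
#' see Details), and pixels whose elevation differs from the coarse-cell
#' mean elevation by more than 100 m. Pixels with missing temperature or
#' tree cover are also dropped.
#'
#' @details The low-cover filter follows the FAO forest definition and is
#'   applied by default; because the regression nonetheless extrapolates to
#'   a 0-100% cover change, `low_cover_filter = FALSE` retains open pixels
#'   and lets users probe the sensitivity of results to this rule.
#'
#' @param pixels Tibble with columns `tree_cover` (fraction),
#'   `temperature` (K), `elevation` (m), `water_fraction` (fraction) and
#'   optionally `cell_id`.
#' @param cell_mean_elevation Mean elevation of the coarse cell, m. When
#'   `NULL` it is computed from `pixels` (per `cell_id` if present).
#' @param max_water,min_cover,max_elev_diff Screening thresholds.
#' @param low_cover_filter Apply the minimum tree-cover rule?
#' @return The retained rows of `pixels` (possibly empty).
#' @export
screen_pixels <- function(pixels, cell_mean_elevation = NULL,
                          max_water = 0.01, min_cover = 0.10,
                          max_elev_diff = 100, low_cover_filter = TRUE) {
  pixels <- as_tibble(pixels)
  if (nrow(pixels) == 0) abort("`pixels` is empty.")
  if (is.null(cell_mean_elevation)) {
    if ("cell_id" %in% names(pixels)) {
      pixels <- pixels |>
        group_by(.data$cell_id) |>
        mutate(.cell_elev = mean(.data$elevation, na.rm = TRUE)) |>
        ungroup()
    } else {
      pixels$.cell_elev <- mean(pixels$elevation, na.rm = TRUE)
    }
  } else {
    pixels$.cell_elev <- cell_mean_elevation
  }
  keep <- !is.na(pixels$temperature) & !is.na(pixels$tree_cover) &
    pixels$water_fraction <= max_water &
    abs(pixels$elevation - pixels$.cell_elev) <= max_elev_diff
  if (low_cover_filter) keep <- keep & pixels$tree_cover >= min_cover
  out <- pixels[which(keep), ]
  out$.cell_elev <- NULL
  out
}

#' Per-cell temperature sensitivity to full tree cover gain
#'
#' Ordinary least squares of pixel temperature on tree-cover fraction
#' within each coarse cell: the slope is the temperature change for a
#' 0 to 100% cover gain (K), the space-for-time estimate of the local
#' biophysical sensitivity. Quality control marks a cell valid only when
#' the sample size strictly exceeds `n_min` and the spread between the
#' highest and lowest tree cover strictly exceeds `cover_range_min`
#' percentage points.
#'
#' @param pixels Screened pixel tibble (see [screen_pixels()]); fitted per
#'   `cell_id` group when that column is present.
#' @param n_min QC threshold on sample size (strict `>`; default 90).
#' @param cover_range_min QC threshold on the tree-cover range in
#'   percentage points (strict `>`; default 40).
#' @return Tibble with one row per cell: `slope` (K per full cover gain),
#'   `intercept` (K), `n_pixels`, `cover_range` (percentage points),
#'   `valid`, `reason` (`"ok"`, `"too_few_pixels"`, `"cover_range"`, or
#'   `"zero_cover_variance"`).
#' @export
fit_cell_sensitivity <- function(pixels, n_min = 90, cover_range_min = 40) {
  pixels <- as_tibble(pixels)
  if (!"cell_id" %in% names(pixels)) pixels$cell_id <- 1L
  fit_one <- function(df, id) {
    tc <- df$tree_cover
    te <- df$temperature
    n <- length(tc)
    cover_range <- if (n > 0) 100 * (max(tc) - min(tc)) else 0
    slope <- NA_real_; intercept <- NA_real_
    reason <- "ok"
    if (n >= 2 && stats::var(tc) > 0) {
      mx <- mean(tc); my <- mean(te)
      slope <- sum((tc - mx) * (te - my)) / sum((tc - mx)^2)
      intercept <- my - slope * mx
    } else {
      reason <- "zero_cover_variance"
    }
    if (reason == "ok") {
      # strict thresholds; the range gets a tiny guard so that a spread
      # constructed to be exactly the threshold is not promoted by
      # floating-point round-off
      if (!(n > n_min)) reason <- "too_few_pixels"
      else if (!(cover_range > cover_range_min + 1e-9)) reason <- "cover_range"
    }
    valid <- reason == "ok"
    tibble(cell_id = id, slope = if (valid || reason %in% c("too_few_pixels", "cover_range")) slope else NA_real_,
           intercept = intercept, n_pixels = n, cover_range = cover_range,
           valid = valid, reason = reason)
  }
  if (nrow(pixels) == 0) {
    return(tibble(cell_id = pixels$cell_id, slope = numeric(0),
                  intercept = numeric(0), n_pixels = integer(0),
                  cover_range = numeric(0), valid = logical(0),
                  reason = character(0)))
  }
  split(pixels, pixels$cell_id, drop = TRUE) |>
    purrr::map_dfr(function(df) fit_one(df, df$cell_id[1]))
}

#' Trim the extreme 1% of a sensitivity map
#'
#' Invalidates cells whose slope falls below the 1st or above the 99th
#' percentile of the valid slopes (linear-interpolation percentiles,
#' computed per monthly map when a `month` column is present). The
#' percentile thresholds are recomputed on each call, so applying the trim
#' twice may invalidate further cells.
#'
#' @param map Sensitivity tibble (columns `slope`, `valid`; optional
#'   `month`).
#' @param lower,upper Trim probabilities (defaults 0.01 and 0.99).
#' @return `map` with trimmed cells set `valid = FALSE`,
#'   `reason = "trimmed"` and `slope = NA`.
#' @export
trim_sensitivity_map <- function(map, lower = 0.01, upper = 0.99) {
  map <- as_tibble(map)
  if (!any(map$valid)) abort("Map has no valid cells to trim.")
  grp <- if ("month" %in% names(map)) as.character(map$month) else
    rep("1", nrow(map))
  grp[is.na(grp)] <- "none"
  for (g in unique(grp)) {
    sel <- grp == g & map$valid
    if (!any(sel)) next
    q <- quantile(map$slope[sel], c(lower, upper), names = FALSE, type = 7)
    cut <- sel & (map$slope < q[1] | map$slope > q[2])
    map$valid[cut] <- FALSE
    map$reason[cut] <- "trimmed"
    map$slope[cut] <- NA_real_
  }
  map
}

#' Annual mean sensitivity from twelve monthly maps
#'
#' Per-cell unweighted mean of the monthly slopes over the months where the
#' cell is valid. A cell enters the annual map only when it is valid in at
#' least `min_months` months.
#'
#' @param monthly Tibble of monthly sensitivity maps stacked with a
#'   `month` column (12 distinct months on one grid).
#' @param min_months Minimum number of valid months (default 6).
#' @return Annual sensitivity tibble (one row per cell) with `n_months`.
#' @export
annual_mean_map <- function(monthly, min_months = 6) {
  monthly <- as_tibble(monthly)
  if (!"month" %in% names(monthly)) abort("`monthly` needs a `month` column.")
  months <- unique(monthly$month)
  if (length(months) != 12) {
    abort(sprintf("Expected 12 monthly maps, found %d.", length(months)))
  }
  key_cols <- intersect(c("cell_id", "lat", "lon"), names(monthly))
  if (length(key_cols) == 0) abort("Maps need `cell_id` or `lat`/`lon` keys.")
  counts <- monthly |>
    group_by(across(dplyr::all_of(key_cols))) |>
    summarise(.n_map = dplyr::n(), .groups = "drop")
  if (any(counts$.n_map != 12)) {
    abort("Monthly maps are not on a common grid (cells missing in some months).")
  }
  monthly |>
    group_by(across(dplyr::all_of(key_cols))) |>
    summarise(
      n_months = sum(.data$valid),
      slope = if (sum(.data$valid) >= min_months)
        mean(.data$slope[.data$valid]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(valid = !is.na(.data$slope))
}

#' Space-for-time sensitivity map from co-registered rasters
#'
#' Tiles co-registered fine-resolution rasters into coarse cells of
#' `cell_size` degrees, screens the pixels of each cell, fits the
#' per-cell temperature-on-tree-cover regression and applies quality
#' control. Deterministic given its inputs. The same estimator applies
#' unchanged to mean/max/min temperature inputs and to biomass carbon
#' density (then the "temperature" raster carries tC ha-1 and the slope is
#' a carbon-stock sensitivity).
#'
#' @param tc,temperature,elevation,water [raster_grid()]s on one fine
#'   grid: tree-cover fraction, temperature (K), elevation (m), water
#'   fraction.
#' @param cell_size Coarse cell size in degrees (default 0.25).
#' @param month Optional month index attached to the output.
#' @param ... Passed to [screen_pixels()] and [fit_cell_sensitivity()]
#'   (`low_cover_filter`, `n_min`, `cover_range_min`, ...).
#' @return A sensitivity tibble (class `sensitivity_map`): one row per
#'   coarse cell with `cell_id`, cell-center `lat`/`lon`, `slope`,
#'   `intercept`, `n_pixels`, `cover_range`, `valid`, `reason` and
#'   `month`.
#' @export
estimate_sensitivity_map <- function(tc, temperature, elevation, water,
                                     cell_size = 0.25, month = NA_integer_,
                                     ...) {
  grids <- list(tc = tc, temperature = temperature,
                elevation = elevation, water = water)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$lat, ref$lat)) ||
        !isTRUE(all.equal(g$lon, ref$lon))) {
      abort("Input rasters are not co-registered (lat/lon mismatch).")
    }
  }
  dots <- list(...)
  screen_args <- dots[intersect(names(dots),
                                c("max_water", "min_cover", "max_elev_diff",
                                  "low_cover_filter"))]
  fit_args <- dots[intersect(names(dots), c("n_min", "cover_range_min"))]

  lat0 <- min(ref$lat) - ref$cellsize / 2
  lon0 <- min(ref$lon) - ref$cellsize / 2
  px <- tibble(
    lat = rep(ref$lat, times = length(ref$lon)),
    lon = rep(ref$lon, each = length(ref$lat)),
    tree_cover = as.vector(tc$values),
    temperature = as.vector(temperature$values),
    elevation = as.vector(elevation$values),
    water_fraction = as.vector(water$values)
  )
  row_i <- floor((px$lat - lat0) / cell_size + 1e-9)
  col_i <- floor((px$lon - lon0) / cell_size + 1e-9)
  px$cell_lat <- lat0 + (row_i + 0.5) * cell_size
  px$cell_lon <- lon0 + (col_i + 0.5) * cell_size
  px$cell_id <- paste0(row_i, "_", col_i)

  centers <- px |>
    dplyr::distinct(.data$cell_id, .data$cell_lat, .data$cell_lon)

  screened <- px |>
    group_by(.data$cell_id) |>
    mutate(.cell_elev = mean(.data$elevation, na.rm = TRUE)) |>
    ungroup()
  screened <- do.call(screen_pixels, c(
    list(pixels = screened, cell_mean_elevation = screened$.cell_elev),
    screen_args))

  fitted <- do.call(fit_cell_sensitivity, c(list(pixels = screened), fit_args))
  # cells fully emptied by screening still appear, as nodata
  out <- centers |>
    left_join(fitted, by = "cell_id") |>
    mutate(
      n_pixels = dplyr::coalesce(.data$n_pixels, 0L),
      cover_range = dplyr::coalesce(.data$cover_range, 0),
      valid = dplyr::coalesce(.data$valid, FALSE),
      reason = dplyr::coalesce(.data$reason, "all_pixels_screened"),
      month = month
    ) |>
    dplyr::rename(lat = "cell_lat", lon = "cell_lon") |>
    arrange(.data$lat, .data$lon)
  class(out) <- c("sensitivity_map", class(out))
  out
}
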