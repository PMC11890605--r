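#' Forward-simulate a gridded scene with known sensitivity truth
#'
#' Builds co-registered fine-resolution rasters (tree cover, surface and
#' air temperature, elevation, water fraction) in which pixel temperature
#' is exactly linear in tree cover plus Gaussian noise, so the
#' space-for-time estimator has a known per-cell ground truth. Coarse
#' cells are stacked in a single column of latitudes starting at
#' `lat_start`, which lets a latitude-dependent sensitivity rule (e.g. a
#' sign flip at 50 deg N) span the scene. A configurable fraction of
#' pixels violates each screening rule (water cover > 1%, tree cover
#' < 10%, elevation offset > 100 m); violators also receive a temperature
#' bias so that skipping the screening is detectable. Violating pixels
#' overwrite a recorded subset of the cell's pixels (the rasters keep a
#' fixed shape); their indices are returned.
#'
#' @param n_cells Number of coarse cells (one 0.25-deg column).
#' @param pixels_per_cell Fine pixels per coarse cell; must be a perfect
#'   square (default 900 = 30 x 30).
#' @param truth_dts,truth_dta Functions latitude -> true sensitivity
#'   (K per full cover gain) for surface and air temperature. Defaults
#'   follow the observed sign structure: warming north of 50 deg N,
#'   cooling south of it, with the air response a quarter of the surface
#'   response.
#' @param noise_sd Pixel temperature noise, K (default 0.3).
#' @param cell_size Coarse cell size, degrees.
#' @param lat_start,lon_start South-west corner of the scene, degrees.
#' @param cover_range Tree-cover support `(min, max)`; two pixels per cell
#'   are pinned near the ends (at 0.12 and the maximum) so the QC cover
#'   range is guaranteed even for small cells.
#' @param intercept_ts,intercept_ta Regression intercepts at `lat_start`,
#'   K; both decrease by `lat_gradient` K per degree of latitude.
#' @param lat_gradient Macroclimate lapse of the intercepts, K per degree.
#' @param frac_violators Named fractions of pixels per cell violating each
#'   rule: `water`, `low_cover`, `elevation`.
#' @param violator_bias Temperature bias added to violating pixels, K.
#' @param seed Integer seed; identical arguments and seed give
#'   bit-identical output.
#' @return List with `rasters` (named [raster_grid()]s: `tree_cover`,
#'   `ts`, `ta`, `elevation`, `water`), `truth` (per-cell tibble:
#'   `cell_id`, `lat`, `lon`, `true_dts`, `true_dta`, `b_s`, `b_a`,
#'   `noise_sd`, `n_pixels`, violator counts), `violators` (tibble of
#'   violating pixel indices and types) and `cell_size`.
#' @export
make_scene <- function(n_cells, pixels_per_cell = 900,
                       truth_dts = function(lat) ifelse(lat >= 50, 0.8, -1.2),
                       truth_dta = function(lat) ifelse(lat >= 50, 0.2, -0.3),
                       noise_sd = 0.3, cell_size = 0.25,
                       lat_start = 35, lon_start = 10,
                       cover_range = c(0.05, 0.95),
                       intercept_ts = 288, intercept_ta = 287.2,
                       lat_gradient = 0.5,
                       frac_violators = c(water = 0.02, low_cover = 0.02,
                                          elevation = 0.02),
                       violator_bias = 3, seed) {
  q <- sqrt(pixels_per_cell)
  if (q != round(q) || pixels_per_cell < 4) {
    abort("`pixels_per_cell` must be a perfect square >= 4.")
  }
  q <- as.integer(q)
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (!is.function(truth_dts) || !is.function(truth_dta)) {
    abort("`truth_dts` and `truth_dta` must be functions of latitude.")
  }
  fv <- c(water = 0, low_cover = 0, elevation = 0)
  fv[names(frac_violators)] <- frac_violators
  if (any(fv < 0) || sum(fv) > 0.5) {
    abort("Violator fractions must be non-negative and sum to <= 0.5.")
  }
  cell_lat <- lat_start + (seq_len(n_cells) - 0.5) * cell_size
  dts <- truth_dts(cell_lat)
  dta <- truth_dta(cell_lat)
  if (length(dts) != n_cells || length(dta) != n_cells ||
      any(!is.finite(dts)) || any(!is.finite(dta))) {
    abort("Sensitivity rule must return one finite value per cell latitude.")
  }
  b_s <- intercept_ts - lat_gradient * (cell_lat - lat_start)
  b_a <- intercept_ta - lat_gradient * (cell_lat - lat_start)
  ppc <- pixels_per_cell
  n_viol <- setNames(pmax(0L, as.integer(round(fv * ppc))), names(fv))

  fine_cs <- cell_size / q
  fine_lat <- lat_start + (seq_len(n_cells * q) - 0.5) * fine_cs
  fine_lon <- lon_start + (seq_len(q) - 0.5) * fine_cs
  dims <- c(n_cells * q, q)
  m_tc <- m_ts <- m_ta <- m_el <- m_wa <- matrix(NA_real_, dims[1], dims[2])

  viol_list <- vector("list", n_cells)
  withr::with_seed(seed, {
    for (i in seq_len(n_cells)) {
      tc <- runif(ppc, cover_range[1], cover_range[2])
      tc[1] <- 0.12
      tc[2] <- cover_range[2]
      water <- runif(ppc, 0, 0.01)
      elev_base <- runif(1, 100, 800)
      elev <- elev_base + rnorm(ppc, 0, 20)
      # violators overwrite pixels beyond the two pinned ones
      pool <- if (sum(n_viol) > 0)
        sample(3:ppc, sum(n_viol), replace = FALSE) else integer(0)
      idx_w <- pool[seq_len(n_viol[["water"]])]
      idx_c <- pool[n_viol[["water"]] + seq_len(n_viol[["low_cover"]])]
      idx_e <- pool[n_viol[["water"]] + n_viol[["low_cover"]] +
                      seq_len(n_viol[["elevation"]])]
      if (length(idx_w)) water[idx_w] <- runif(length(idx_w), 0.02, 0.8)
      if (length(idx_c)) tc[idx_c] <- runif(length(idx_c), 0, 0.09)
      if (length(idx_e)) {
        elev[idx_e] <- elev_base +
          sample(c(-1, 1), length(idx_e), TRUE) * runif(length(idx_e), 150, 400)
      }
      bias <- numeric(ppc)
      bias[c(idx_w, idx_c, idx_e)] <- violator_bias
      ts <- b_s[i] + dts[i] * tc + rnorm(ppc, 0, noise_sd) + bias
      ta <- b_a[i] + dta[i] * tc + rnorm(ppc, 0, noise_sd) + bias
      rows <- (i - 1L) * q + seq_len(q)
      m_tc[rows, ] <- matrix(tc, q, q)
      m_ts[rows, ] <- matrix(ts, q, q)
      m_ta[rows, ] <- matrix(ta, q, q)
      m_el[rows, ] <- matrix(elev, q, q)
      m_wa[rows, ] <- matrix(water, q, q)
      viol_list[[i]] <- tibble(
        cell_id = i,
        pixel = c(idx_w, idx_c, idx_e),
        type = rep(c("water", "low_cover", "elevation"),
                   times = c(length(idx_w), length(idx_c), length(idx_e)))
      )
    }
  })
  rasters <- list(
    tree_cover = raster_grid(m_tc, fine_lat, fine_lon, units = "fraction"),
    ts = raster_grid(m_ts, fine_lat, fine_lon, units = "K"),
    ta = raster_grid(m_ta, fine_lat, fine_lon, units = "K"),
    elevation = raster_grid(m_el, fine_lat, fine_lon, units = "m"),
    water = raster_grid(m_wa, fine_lat, fine_lon, units = "fraction")
  )
  truth <- tibble(
    cell_id = seq_len(n_cells), lat = cell_lat,
    lon = lon_start + cell_size / 2,
    true_dts = dts, true_dta = dta, b_s = b_s, b_a = b_a,
    noise_sd = noise_sd, n_pixels = ppc,
    n_water_viol = n_viol[["water"]],
    n_low_cover_viol = n_viol[["low_cover"]],
    n_elev_viol = n_viol[["elevation"]]
  )
  list(rasters = rasters, truth = truth,
       violators = bind_rows(viol_list), cell_size = cell_size)
}

#' Write a synthetic scene to disk
#'
#' One ASCII grid per variable plus a `truth.json` sidecar, the layout
#' [load_raster()] reads back.
#'
#' @param scene Output of [make_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(scene$rasters)) {
    write_ascii_grid(scene$rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  jsonlite::write_json(scene$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Ground truth for a paired forest/openland tower simulation
#'
#' Draws per-record series of sensible heat flux, friction velocity and
#' surface temperature for a forest member and an openland member sharing
#' one macroclimate, then solves each record's Monin-Obukhov state
#' (Obukhov length, stability, aerodynamic resistance, air temperature at
#' the measurement height) to self-consistency. In `"stable"` conditions
#' (cold-season) the heat flux is downward (negative) and the surface is
#' colder than the air (temperature inversion); in `"unstable"` conditions
#' (warm-season) the flux is upward and the surface is warmer.
#'
#' @param n_records Records per member.
#' @param seed Integer seed.
#' @param stability `"stable"` or `"unstable"`.
#' @param forest,openland Member parameters: `z_oh` (m), `h` (vegetation
#'   height, m; `d = 0.67 h` exactly), `z_m` (measurement height, m),
#'   `albedo`, `u_star` range (m s-1), `h_flux` magnitude range (W m-2),
#'   `ts_offset` (K, surface offset from macroclimate).
#' @param macro_mean,macro_sd Shared macroclimate series, K.
#' @param lw_down Downward longwave radiation, W m-2.
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1.
#' @return A `site_pair_truth` list: per member the fixed geometry and the
#'   solved series (`h_flux`, `u_star`, `ts`, `macro`, `L`, `zeta`, `r_a`,
#'   `ta`), plus `rho_cp`, `stability` and `n_records`.
#' @export
site_pair_truth <- function(n_records = 120, seed,
                            stability = c("stable", "unstable"),
                            forest = list(z_oh = 0.8, h = 20, z_m = 28,
                                          albedo = 0.12, u_star = c(0.3, 0.8),
                                          h_flux = c(25, 80), ts_offset = 0.5),
                            openland = list(z_oh = 0.02, h = 0.5, z_m = 3,
                                            albedo = 0.22,
                                            u_star = c(0.2, 0.5),
                                            h_flux = c(25, 80),
                                            ts_offset = -0.5),
                            macro_mean = 272, macro_sd = 2, lw_down = 300,
                            rho_cp = RHO_CP_DEFAULT) {
  stability <- match.arg(stability)
  sgn <- if (stability == "stable") -1 else 1
  members <- list(forest = forest, openland = openland)
  out <- withr::with_seed(seed, {
    macro <- macro_mean + rnorm(n_records, 0, macro_sd)
    purrr::map(members, function(p) {
      d <- 0.67 * p$h
      if (p$z_m - d <= p$z_oh) {
        abort("Unphysical profile: need z_m - d > Z_oh for every member.")
      }
      h_flux <- sgn * runif(n_records, p$h_flux[1], p$h_flux[2])
      u_star <- runif(n_records, p$u_star[1], p$u_star[2])
      ts <- macro + p$ts_offset + rnorm(n_records, 0, 0.5)
      st <- solve_profile(ts, h_flux, u_star, p$z_m, d, p$z_oh, rho_cp)
      list(z_oh = p$z_oh, h = p$h, d = d, z_m = p$z_m, albedo = p$albedo,
           series = tibble(h_flux = h_flux, u_star = u_star, ts = ts,
                           macro = macro, L = st$L, zeta = st$zeta,
                           r_a = st$r_a, ta = st$ta))
    })
  })
  structure(c(out, list(rho_cp = rho_cp, stability = stability,
                        n_records = n_records, lw_down = lw_down)),
            class = "site_pair_truth")
}

#' Generate paired forest/openland tower records from a known truth
#'
#' Emits flux-tower style records whose measured air temperature is the
#' forward Monin-Obukhov solution of the truth state and whose upward
#' longwave radiation encodes the true surface temperature through the
#' emissivity model, so every downstream estimator (surface temperature
#' retrieval, roughness-length inversion, height normalization,
#' decomposition) has an exact target. Optional measurement noise is added
#' to the measured air temperature only, and recorded.
#'
#' @param truth A [site_pair_truth()].
#' @param n_records Number of records per member (<= `truth$n_records`).
#' @param noise_sd Measurement noise on `ta_meas_K`, K (default 0: exact).
#' @param seed Seed for the measurement noise (required if `noise_sd > 0`).
#' @return List with `records` (tibble in the [read_site_table()] layout
#'   plus `land_class`, `site`) and `noise_sd`.
#' @export
make_site_pair <- function(truth, n_records = truth$n_records, noise_sd = 0,
                           seed = NULL) {
  stopifnot(inherits(truth, "site_pair_truth"))
  if (n_records > truth$n_records) {
    abort("`n_records` exceeds the length of the truth series.")
  }
  if (noise_sd > 0 && is.null(seed)) {
    abort("`seed` is required when measurement noise is on.")
  }
  one <- function(member, cls, igbp, site_name) {
    s <- member$series[seq_len(n_records), ]
    emis <- emissivity_from_albedo(member$albedo)
    tibble(
      timestamp = seq_len(n_records),
      site = site_name,
      igbp_class = igbp,
      ta_meas_K = s$ta,
      z_m = member$z_m,
      lw_up = emis * SIGMA_SB * s$ts^4 + (1 - emis) * truth$lw_down,
      lw_down = truth$lw_down,
      sw_down = pmax(0, if (truth$stability == "stable")
        runif(n_records, 5, 120) else runif(n_records, 150, 400)),
      h_flux = s$h_flux,
      u_star = s$u_star,
      albedo = member$albedo,
      veg_height_m = member$h,
      site_elev_m = 300,
      grid_t_K = s$macro,
      grid_elev_m = 300,
      land_class = factor(cls, levels = c("forest", "openland"))
    )
  }
  records <- withr::with_seed(seed %||% 1L, {
    rec <- bind_rows(
      one(truth$forest, "forest", "ENF", "forest_site"),
      one(truth$openland, "openland", "GRA", "openland_site")
    )
    if (noise_sd > 0) {
      rec$ta_meas_K <- rec$ta_meas_K + rnorm(nrow(rec), 0, noise_sd)
    }
    rec
  })
  list(records = records, noise_sd = noise_sd)
}

#' Draw random valid Monin-Obukhov states
#'
#' Samples surface-layer states (surface temperature, flux, friction
#' velocity, geometry, roughness) across both stability regimes, solves
#' each to self-consistency, and keeps only states satisfying all four
#' roughness-inversion validity conditions (flux/gradient sign agreement,
#' `|H| > 20 W m-2`, `u* > 0.01 m s-1`, `-2 < zeta < 1`). Used for the
#' inversion round-trip property.
#'
#' @param n Number of valid states to return.
#' @param seed Integer seed.
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1.
#' @return Tibble of states: `ts`, `h_flux`, `u_star`, `h`, `d`, `z_m`,
#'   `z_oh`, and the solved `ta`, `L`, `zeta`, `r_a`.
#' @export
sample_profile_states <- function(n, seed, rho_cp = RHO_CP_DEFAULT) {
  withr::with_seed(seed, {
    out <- list()
    got <- 0L
    while (got < n) {
      m <- ceiling((n - got) * 1.6) + 20L
      h_veg <- runif(m, 0.3, 30)
      d <- 0.67 * h_veg
      z_m <- h_veg + runif(m, 2, 12)
      z_oh <- exp(runif(m, log(0.005), log(1.5)))
      z_oh <- pmin(z_oh, 0.3 * (z_m - d))
      u_star <- runif(m, 0.15, 0.9)
      h_flux <- sample(c(-1, 1), m, TRUE) * runif(m, 25, 250)
      ts <- runif(m, 260, 310)
      st <- solve_profile(ts, h_flux, u_star, z_m, d, z_oh, rho_cp)
      ok <- is.finite(st$ta) & st$zeta > -2 & st$zeta < 1 &
        abs(h_flux) > 20 & u_star > 0.01 &
        sign(h_flux) == sign(ts - st$ta) & st$r_a > 0
      keep <- tibble(ts = ts, h_flux = h_flux, u_star = u_star, h = h_veg,
                     d = d, z_m = z_m, z_oh = z_oh, ta = st$ta, L = st$L,
                     zeta = st$zeta, r_a = st$r_a)[ok, ]
      out[[length(out) + 1]] <- keep
      got <- got + nrow(keep)
    }
    bind_rows(out)[seq_len(n), ]
  })
}

#' Generate site records with a linear sensitivity-radiation law
#'
#' Synthesizes forest and openland records whose macroclimate-corrected
#' anomaly difference follows `deltaT*(SW_d) = a + b SW_d` exactly in
#' expectation: forest anomalies are `a + b SW_d` plus noise, openland
#' anomalies are pure noise. Used to test the binned-sensitivity / WLS
#' stage end to end with known slope truth.
#'
#' @param n_bins Number of 10 W m-2 shortwave bins spanned.
#' @param records_per_bin Records per class per bin.
#' @param slope_ts,slope_ta True slopes `b`, K per W m-2.
#' @param intercept_ts,intercept_ta True intercepts `a`, K.
#' @param noise_sd Per-record anomaly noise, K.
#' @param bin_width Bin width, W m-2.
#' @param seed Integer seed.
#' @return Tibble with `land_class`, `sw_down`, `ts_site`, `ta_site`,
#'   `t_grid` ready for [bin_site_sensitivity()].
#' @export
make_validation_sites <- function(n_bins = 25, records_per_bin = 120,
                                  slope_ts = -0.012, slope_ta = -0.003,
                                  intercept_ts = 0.8, intercept_ta = 0.3,
                                  noise_sd = 0.8, bin_width = 10, seed) {
  withr::with_seed(seed, {
    one_class <- function(cls) {
      bin <- rep(seq_len(n_bins) - 1, each = records_per_bin)
      n <- length(bin)
      sw <- bin * bin_width + runif(n, 0, bin_width)
      grid_t <- 280 + rnorm(n, 0, 4)
      if (cls == "forest") {
        ts <- grid_t + intercept_ts + slope_ts * sw + rnorm(n, 0, noise_sd)
        ta <- grid_t + intercept_ta + slope_ta * sw + rnorm(n, 0, noise_sd)
      } else {
        ts <- grid_t + rnorm(n, 0, noise_sd)
        ta <- grid_t + rnorm(n, 0, noise_sd)
      }
      tibble(land_class = factor(cls, levels = c("forest", "openland")),
             sw_down = sw, ts_site = ts, ta_site = ta, t_grid = grid_t)
    }
    bind_rows(one_class("forest"), one_class("openland"))
  })
}
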