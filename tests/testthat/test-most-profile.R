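test_that("stability correction matches both branches and is continuous at neutral", {
  expect_identical(psi_h(0), 0)
  expect_equal(psi_h(0.2), -1.0, tolerance = 1e-12)
  x2 <- sqrt(17)
  expect_equal(psi_h(-1), 2 * log((1 + x2) / 2), tolerance = 1e-12)
  expect_equal(psi_h(-1), 1.8812, tolerance = 1e-4)
  expect_lt(abs(psi_h(1e-10) - psi_h(-1e-10)), 1e-8)
})

test_that("Obukhov length follows its closed form and sign convention", {
  expect_equal(obukhov_length(0.3, 150, 300, 1205),
               -(1205 * 0.027 * 300) / (0.4 * 9.81 * 150), tolerance = 1e-12)
  expect_equal(obukhov_length(0.3, 150, 300, 1205), -16.58, tolerance = 1e-3)
  expect_equal(obukhov_length(0.3, -150, 300, 1205), 16.58, tolerance = 1e-3)
  expect_identical(obukhov_length(0.3, 0, 300), Inf)
  expect_error(obukhov_length(0, 100, 300), "positive")
})

test_that("aerodynamic resistance matches closed forms and is monotone", {
  expect_equal(aerodynamic_resistance(10, 0, 0.1, 0.5, Inf),
               log(100) / 0.2, tolerance = 1e-12)
  # stable zeta = 0.2: psi_h = -1, r_a = (ln(100) + 1) / 0.2
  L <- 10 / 0.2
  expect_equal(aerodynamic_resistance(10, 0, 0.1, 0.5, L),
               (log(100) + 1) / 0.2, tolerance = 1e-12)
  expect_equal(aerodynamic_resistance(10, 0, 0.1, 0.5, L), 28.026,
               tolerance = 1e-3)
  expect_error(aerodynamic_resistance(10, 0, 10, 0.5, Inf), "z - d > Z_oh")

  # strict decrease in u* and in Z_oh under neutral conditions
  u <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(aerodynamic_resistance(10, 0, 0.1, u, Inf)) < 0))
  zoh <- seq(0.01, 1, by = 0.05)
  expect_true(all(diff(aerodynamic_resistance(10, 0, zoh, 0.5, Inf)) < 0))
})

test_that("roughness inversion round-trips random valid states and flags violations", {
  st <- sample_profile_states(1500, seed = 17)
  inv <- infer_zoh(tibble::tibble(
    ts = st$ts, ta_meas_K = st$ta, z_m = st$z_m, veg_height_m = st$h,
    h_flux = st$h_flux, u_star = st$u_star))
  expect_true(all(inv$zoh_valid))
  expect_lt(max(abs(inv$zoh - st$z_oh) / st$z_oh), 1e-8)

  base <- tibble::tibble(ts = st$ts[1], ta_meas_K = st$ta[1], z_m = st$z_m[1],
                         veg_height_m = st$h[1], h_flux = st$h_flux[1],
                         u_star = st$u_star[1])
  flip <- base; flip$h_flux <- -base$h_flux
  expect_identical(infer_zoh(flip)$zoh_reason, "sign_mismatch")
  weak <- base; weak$h_flux <- sign(base$h_flux) * 15
  weak$ta_meas_K <- base$ts - sign(base$h_flux) * 0.1
  expect_identical(infer_zoh(weak)$zoh_reason, "h_too_small")
  calm <- base; calm$u_star <- 0.005
  expect_identical(infer_zoh(calm)$zoh_reason, "u_star_too_small")
  # tiny u*, large |H| -> |L| small -> zeta out of range, but u* trips first
  expect_identical(infer_zoh(calm)$zoh_valid, FALSE)
  strong <- base
  strong$u_star <- 0.05; strong$h_flux <- 400
  strong$ta_meas_K <- base$ts - 5
  expect_identical(infer_zoh(strong)$zoh_reason, "zeta_out_of_range")
})

test_that("gap-filling regenerates an exact log-linear roughness law", {
  withr::with_seed(23, {
    u <- runif(40, 0.1, 0.8)
  })
  zoh <- exp(-2 + 0.5 * u)
  rec <- tibble::tibble(u_star = u, zoh = zoh,
                        zoh_valid = rep(c(TRUE, FALSE), 20))
  rec$zoh[!rec$zoh_valid] <- NA
  filled <- gapfill_zoh(rec)
  expect_equal(filled$zoh, zoh, tolerance = 1e-10)
  expect_true(all(filled$zoh_filled == !rec$zoh_valid))

  # nothing to fill: output identical
  all_valid <- tibble::tibble(u_star = u, zoh = zoh, zoh_valid = TRUE)
  expect_equal(gapfill_zoh(all_valid)$zoh, zoh)

  one <- tibble::tibble(u_star = c(0.3, 0.4), zoh = c(0.1, NA),
                        zoh_valid = c(TRUE, FALSE))
  expect_error(gapfill_zoh(one), ">= 2")
})

test_that("height normalization reproduces the analytic profile", {
  rec <- tibble::tibble(ts = 290, h_flux = 100, u_star = 0.4,
                        veg_height_m = 20, zoh = 0.5, L = Inf,
                        ta_meas_K = NA, z_m = 28)
  out <- normalize_ta(rec)
  r_a <- log(8.6 / 0.5) / (0.4 * 0.4)
  expect_equal(out$r_a_norm, r_a, tolerance = 1e-12)
  expect_equal(out$ta_norm, 290 - 100 * r_a / 1205, tolerance = 1e-12)
  expect_equal(out$ta_norm, 288.525, tolerance = 1e-3)

  none <- rec; none$h_flux <- 0
  expect_equal(normalize_ta(none)$ta_norm, 290)

  # a record measured exactly at h + 2 normalizes to its own measurement
  tr <- site_pair_truth(
    n_records = 15, seed = 6,
    forest = list(z_oh = 0.5, h = 20, z_m = 22, albedo = 0.12,
                  u_star = c(0.3, 0.8), h_flux = c(25, 80), ts_offset = 0.5))
  rec2 <- with_surface_temperature(make_site_pair(tr)$records)
  rec2 <- rec2[rec2$land_class == "forest", ]
  out2 <- normalize_ta(infer_zoh(rec2))
  expect_lt(max(abs(out2$ta_norm - out2$ta_meas_K)), 1e-8)
})

test_that("midpoint decomposition is exact for the bilinear flux-resistance term", {
  # printed winter means: H -3.4 vs -13.6 W m-2, r_a 30.7 vs 178.1 s m-1
  dec <- decompose_sensitivity(list(h_flux = -3.4, r_a = 30.7),
                               list(h_flux = -13.6, r_a = 178.1),
                               delta_ts_star = 1.63)
  expect_equal(dec$delta_t_h, -104.4 * 10.2 / 1205, tolerance = 1e-12)
  expect_equal(dec$delta_t_h, -0.884, tolerance = 1e-3)
  expect_equal(dec$delta_t_ra, 8.5 * (-147.4) / 1205, tolerance = 1e-12)
  expect_equal(dec$delta_t_ra, -1.040, tolerance = 1e-3)
  expect_gt(abs(dec$delta_t_ra), abs(dec$delta_t_h))
  expect_equal(dec$share_ra, 0.5406, tolerance = 1e-3)

  # closure against the forward oracle on random pairs
  withr::with_seed(41, {
    for (i in 1:20) {
      h_f <- runif(1, -80, 200); h_o <- runif(1, -80, 200)
      r_f <- runif(1, 10, 60); r_o <- runif(1, 40, 200)
      ts_f <- 285 + rnorm(1); ts_o <- 285 + rnorm(1)
      ta_f <- ts_f - h_f * r_f / 1205
      ta_o <- ts_o - h_o * r_o / 1205
      dec <- decompose_sensitivity(list(h_flux = h_f, r_a = r_f),
                                   list(h_flux = h_o, r_a = r_o),
                                   delta_ts_star = ts_f - ts_o)
      expect_lt(abs(dec$delta_ta_star - (ta_f - ta_o)), 1e-10)
    }
  })

  # shares do not depend on the air heat capacity
  a <- decompose_sensitivity(list(h_flux = -3.4, r_a = 30.7),
                             list(h_flux = -13.6, r_a = 178.1), 1.63,
                             rho_cp = 1205)
  b <- decompose_sensitivity(list(h_flux = -3.4, r_a = 30.7),
                             list(h_flux = -13.6, r_a = 178.1), 1.63,
                             rho_cp = 1100)
  expect_equal(a$share_ra, b$share_ra, tolerance = 1e-12)
})
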