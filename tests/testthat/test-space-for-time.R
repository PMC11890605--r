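make_test_pixels <- function() {
  tibble::tibble(
    tree_cover = c(0.5, 0.6, 0.05, 0.7, 0.4),
    temperature = c(284, 283.8, 284.5, 283.6, 284.2),
    elevation = c(400, 410, 395, 550, 405),
    water_fraction = c(0.005, 0.02, 0.0, 0.0, 0.01)
  )
}

test_that("screening applies the water, low-cover and elevation rules", {
  px <- make_test_pixels()
  out <- screen_pixels(px, cell_mean_elevation = 400)
  # pixel 2: water 0.02 > 1%; pixel 3: cover 5% < 10%; pixel 4: 150 m above
  expect_identical(out$tree_cover, c(0.5, 0.4))
  # low-cover rule is a toggle
  out2 <- screen_pixels(px, cell_mean_elevation = 400, low_cover_filter = FALSE)
  expect_identical(out2$tree_cover, c(0.5, 0.05, 0.4))
  # boundary values are retained (rules are strict "more than"/"less than")
  edge <- tibble::tibble(tree_cover = 0.10, temperature = 280,
                         elevation = 500, water_fraction = 0.01)
  expect_identical(nrow(screen_pixels(edge, cell_mean_elevation = 400)), 1L)
})

test_that("per-cell fit matches the two-point line and the normal-equations oracle", {
  two <- tibble::tibble(tree_cover = c(0.2, 0.8), temperature = c(285, 284.1),
                        elevation = 0, water_fraction = 0)
  f <- fit_cell_sensitivity(two, n_min = 1, cover_range_min = 1)
  expect_equal(f$slope, (284.1 - 285) / 0.6, tolerance = 1e-12)

  for (seed in 1:5) {
    px <- random_pixel_table(40, seed)
    f <- fit_cell_sensitivity(px, n_min = 10, cover_range_min = 10)
    oracle <- ols_oracle(px$tree_cover, px$temperature)
    expect_equal(f$slope, oracle[2], tolerance = 1e-10)
    expect_equal(f$intercept, oracle[1], tolerance = 1e-10)
  }

  flat <- tibble::tibble(tree_cover = rep(0.5, 100), temperature = rnorm(100),
                         elevation = 0, water_fraction = 0)
  f0 <- fit_cell_sensitivity(flat)
  expect_false(f0$valid)
  expect_identical(f0$reason, "zero_cover_variance")
})

test_that("QC thresholds are strict inequalities at n = 90 and range = 40", {
  make_cell <- function(n, range_pp) {
    tc <- seq(0.2, 0.2 + range_pp / 100, length.out = n)
    tibble::tibble(tree_cover = tc, temperature = 285 - 1.2 * tc,
                   elevation = 0, water_fraction = 0)
  }
  expect_false(fit_cell_sensitivity(make_cell(90, 45))$valid)
  expect_identical(fit_cell_sensitivity(make_cell(90, 45))$reason,
                   "too_few_pixels")
  expect_true(fit_cell_sensitivity(make_cell(91, 45))$valid)
  expect_false(fit_cell_sensitivity(make_cell(120, 40))$valid)
  expect_identical(fit_cell_sensitivity(make_cell(120, 40))$reason,
                   "cover_range")
  expect_true(fit_cell_sensitivity(make_cell(120, 40.1))$valid)
})

test_that("the 1% tail trim removes the documented number of cells and recomputes", {
  map <- tibble::tibble(cell_id = 1:200, slope = as.numeric(1:200),
                        valid = TRUE, reason = "ok")
  trimmed <- trim_sensitivity_map(map)
  expect_identical(sum(!trimmed$valid), 4L)           # 2 per tail
  expect_true(all(!trimmed$valid[c(1, 2, 199, 200)]))
  expect_true(all(trimmed$reason[!trimmed$valid] == "trimmed"))

  # degenerate distribution: nothing removed
  const <- tibble::tibble(cell_id = 1:50, slope = rep(1.5, 50),
                          valid = TRUE, reason = "ok")
  expect_identical(sum(!trim_sensitivity_map(const)$valid), 0L)

  # thresholds are recomputed, so a second pass may remove more
  again <- trim_sensitivity_map(trimmed)
  expect_gte(sum(!again$valid), sum(!trimmed$valid))

  # removal count bounded by ceiling(0.01 * m) per tail
  withr::with_seed(3, {
    m <- tibble::tibble(cell_id = 1:137, slope = rnorm(137),
                        valid = TRUE, reason = "ok")
  })
  t2 <- trim_sensitivity_map(m)
  expect_lte(sum(!t2$valid), 2 * ceiling(0.01 * 137))
})

test_that("annual synthesis averages valid months and enforces the month minimum", {
  grid <- tibble::tibble(cell_id = rep(1:3, each = 12),
                         month = rep(1:12, times = 3))
  monthly <- grid |>
    dplyr::mutate(
      valid = dplyr::case_when(
        cell_id == 1 ~ TRUE,
        cell_id == 2 ~ month <= 7,
        cell_id == 3 ~ month <= 3
      ),
      slope = dplyr::case_when(
        cell_id == 1 ~ 2.5,
        cell_id == 2 ~ as.numeric(month),
        TRUE ~ 1.0
      ),
      slope = ifelse(valid, slope, NA_real_),
      reason = ifelse(valid, "ok", "invalid")
    )
  ann <- annual_mean_map(monthly)
  ann <- dplyr::arrange(ann, cell_id)
  expect_equal(ann$slope, c(2.5, 4.0, NA))
  expect_identical(ann$valid, c(TRUE, TRUE, FALSE))
  expect_error(annual_mean_map(monthly[monthly$month <= 11, ]), "12")
  expect_error(annual_mean_map(monthly[-1, ]), "common grid")
})

test_that("rule-violating pixels never change a fit and QC is monotone under pixel removal", {
  px <- random_pixel_table(120, seed = 77)
  base <- fit_cell_sensitivity(screen_pixels(px, cell_mean_elevation = 400),
                               n_min = 50, cover_range_min = 40)
  violators <- tibble::tibble(
    tree_cover = c(0.5, 0.05, 0.6),
    temperature = c(295, 296, 297),          # wildly biased
    elevation = c(400, 400, 900),
    water_fraction = c(0.5, 0.0, 0.0)
  )
  with_viol <- fit_cell_sensitivity(
    screen_pixels(dplyr::bind_rows(px, violators), cell_mean_elevation = 400),
    n_min = 50, cover_range_min = 40)
  expect_identical(with_viol$slope, base$slope)
  expect_identical(with_viol$n_pixels, base$n_pixels)

  # removing valid pixels can only decrease n and never validates an invalid cell
  for (seed in 1:10) {
    px <- random_pixel_table(100, seed)
    full <- fit_cell_sensitivity(px, n_min = 95, cover_range_min = 40)
    sub <- fit_cell_sensitivity(px[-sample(100, 10), ],
                                n_min = 95, cover_range_min = 40)
    expect_lt(sub$n_pixels, full$n_pixels)
    if (!full$valid) expect_false(sub$valid)
  }
})

test_that("the raster estimator screens whole-cell water and recovers noisy truth", {
  sc <- make_scene(n_cells = 6, pixels_per_cell = 400, noise_sd = 0.2,
                   truth_dts = function(lat) rep(-0.9, length(lat)),
                   seed = 13)
  # drown one cell completely
  q <- sqrt(400)
  sc$rasters$water$values[(2 * q + 1):(3 * q), ] <- 1
  m <- estimate_sensitivity_map(sc$rasters$tree_cover, sc$rasters$ts,
                                sc$rasters$elevation, sc$rasters$water,
                                cell_size = sc$cell_size,
                                n_min = 50, cover_range_min = 40)
  m <- dplyr::arrange(m, lat)
  expect_false(m$valid[3])
  expect_identical(m$n_pixels[3], 0L)
  expect_true(all(m$valid[-3]))
  expect_lt(max(abs(m$slope[-3] + 0.9)), 0.1)

  shuffled <- sc$rasters$ts
  shuffled$lat <- shuffled$lat + 1
  expect_error(
    estimate_sensitivity_map(sc$rasters$tree_cover, shuffled,
                             sc$rasters$elevation, sc$rasters$water),
    "co-registered")
})
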