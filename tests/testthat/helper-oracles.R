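# Independent brute-force oracles used across test files.

# Closed-form normal-equations OLS, independent of the package's fitting code.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(crossprod(X), crossprod(X, y)))  # (intercept, slope)
}

# Closed-form weighted normal equations.
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  as.numeric(solve(crossprod(X, w * X), crossprod(X, w * y)))
}

# A small random pixel table for property tests.
random_pixel_table <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      tree_cover = stats::runif(n, 0.1, 0.95),
      temperature = 285 - 1.1 * stats::runif(n) + stats::rnorm(n, 0, 0.4),
      elevation = 400 + stats::rnorm(n, 0, 15),
      water_fraction = stats::runif(n, 0, 0.01)
    )
  })
}

# Shallow list update, for perturbing forward-model states.
within_list <- function(l, ...) {
  mods <- list(...)
  l[names(mods)] <- mods
  l
}

# Build a site-record tibble with derived surface temperature ready for the
# profile stages.
with_surface_temperature <- function(records) {
  records$ts <- ts_from_longwave(records$lw_up, records$lw_down,
                                 emissivity_from_albedo(records$albedo))
  records
}
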