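#' Tidy a WLS slope fit
#'
#' @param x A [wls_slope()] fit.
#' @param ... Unused.
#' @return Tibble with one row per term (`(Intercept)`, `sw_center`):
#'   `term`, `estimate`, `std.error`.
#' @export
tidy.wls_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "sw_center"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' Glance at a WLS slope fit
#'
#' @inheritParams tidy.wls_fit
#' @return One-row tibble: `n_bins`, `which`, `weighting`, `slope`,
#'   `slope_se`.
#' @export
glance.wls_fit <- function(x, ...) {
  tibble(n_bins = x$n_bins, which = x$which, weighting = x$weighting,
         slope = x$slope, slope_se = x$slope_se)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance
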