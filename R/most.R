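#' Stability correction for heat
#'
#' Integrated Monin-Obukhov stability correction for heat as a function of
#' the stability parameter `zeta = (z - d) / L`. The default form is
#' Businger-Dyer on the unstable side, `2 ln[(1 + x^2)/2]` with
#' `x = (1 - 16 zeta)^(1/4)`, and the linear `-5 zeta` on the stable side;
#' the two branches meet continuously at `zeta = 0` (neutral, where the
#' correction vanishes).
#'
#' @param zeta Stability parameter, dimensionless (vectorized).
#' @return Dimensionless correction; positive when unstable, negative when
#'   stable.
#' @export
psi_h <- function(zeta) {
  out <- numeric(length(zeta))
  stable <- !is.na(zeta) & zeta >= 0
  out[stable] <- -5 * zeta[stable]
  un <- !is.na(zeta) & zeta < 0
  x2 <- sqrt(1 - 16 * zeta[un])
  out[un] <- 2 * log((1 + x2) / 2)
  out[is.na(zeta)] <- NA_real_
  out
}

#' Obukhov length
#'
#' `L = -rho Cp u*^3 T / (kappa g H)` with `kappa = 0.4` and
#' `g = 9.81 m s-2`. `H = 0` yields `+Inf` (neutral); the sign of `L` is
#' opposite to the sign of `H` (unstable surface layers, upward flux, have
#' negative `L`).
#'
#' @param u_star Friction velocity, m s-1, positive.
#' @param h_flux Sensible heat flux, W m-2, positive upward.
#' @param t_air Air temperature, K.
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1.
#' @return Obukhov length in m.
#' @export
obukhov_length <- function(u_star, h_flux, t_air, rho_cp = RHO_CP_DEFAULT) {
  if (any(u_star <= 0, na.rm = TRUE)) abort("`u_star` must be positive.")
  L <- -rho_cp * u_star^3 * t_air / (VON_KARMAN * GRAVITY * h_flux)
  L[!is.na(h_flux) & h_flux == 0] <- Inf
  L
}

#' Aerodynamic resistance to heat transfer
#'
#' `r_a(z) = [ln((z - d)/Z_oh) - psi_h((z - d)/L)] / (0.4 u*)`. In the
#' neutral limit (`L = Inf`) the stability correction is zero. A resistance
#' driven non-positive by the unstable correction is flagged `NA` with a
#' warning rather than returned.
#'
#' @param z Height above ground, m.
#' @param d Zero-plane displacement, m.
#' @param z_oh Heat roughness length, m, positive; `z - d > z_oh` required.
#' @param u_star Friction velocity, m s-1, positive.
#' @param L Obukhov length, m (`Inf` for neutral).
#' @return Resistance in s m-1 (vectorized).
#' @export
aerodynamic_resistance <- function(z, d, z_oh, u_star, L = Inf) {
  dz <- z - d
  if (any(dz <= z_oh, na.rm = TRUE)) {
    abort("Require z - d > Z_oh > 0 for a defined profile.")
  }
  if (any(z_oh <= 0, na.rm = TRUE)) abort("`z_oh` must be positive.")
  if (any(u_star <= 0, na.rm = TRUE)) abort("`u_star` must be positive.")
  zeta <- dz / L
  zeta[is.infinite(L)] <- 0
  r <- (log(dz / z_oh) - psi_h(zeta)) / (VON_KARMAN * u_star)
  bad <- !is.na(r) & r <= 0
  if (any(bad)) {
    warn(sprintf("%d aerodynamic resistance value(s) non-positive after stability correction; set to NA.",
                 sum(bad)))
    r[bad] <- NA_real_
  }
  r
}

# Solve the surface-layer state to self-consistency: the Obukhov length
# depends on the air temperature the profile itself produces, so iterate
# Ta -> L -> r_a -> Ta to a fixed point. Convergence is fast because the
# stability feedback on Ta is weak. All arguments vectorized.
solve_profile <- function(ts, h_flux, u_star, z, d, z_oh,
                          rho_cp = RHO_CP_DEFAULT,
                          tol = 1e-13, max_iter = 200) {
  ta <- ts
  for (i in seq_len(max_iter)) {
    L <- obukhov_length(u_star, h_flux, ta, rho_cp)
    zeta <- (z - d) / L
    zeta[is.infinite(L)] <- 0
    r_a <- (log((z - d) / z_oh) - psi_h(zeta)) / (VON_KARMAN * u_star)
    ta_new <- ts - h_flux * r_a / rho_cp
    if (max(abs(ta_new - ta), na.rm = TRUE) < tol) {
      ta <- ta_new
      break
    }
    ta <- ta_new
  }
  L <- obukhov_length(u_star, h_flux, ta, rho_cp)
  zeta <- (z - d) / L
  zeta[is.infinite(L)] <- 0
  r_a <- (log((z - d) / z_oh) - psi_h(zeta)) / (VON_KARMAN * u_star)
  list(ta = ta, L = L, zeta = zeta, r_a = r_a)
}

#' Forward Monin-Obukhov air temperature
#'
#' Evaluates `Ta(z) = Ts - H r_a(z) / (rho Cp)`, the theoretical air
#' temperature at height `z` implied by a surface-layer state. This is the
#' forward model used to generate synthetic tower records and the
#' brute-force oracle against which the roughness-length inversion is
#' tested.
#'
#' @param state A list with elements `ts` (K), `h_flux` (W m-2), `u_star`
#'   (m s-1), `z_oh` (m), and either `d` or vegetation height `h`
#'   (`d = 0.67 h`). An optional `L` fixes the Obukhov length; when absent
#'   the state is solved self-consistently (L computed from the generated
#'   Ta). Optional `rho_cp` overrides the default 1205 J m-3 K-1.
#' @param z Height above ground, m; `z - d > z_oh` required.
#' @return Air temperature at `z`, K.
#' @export
forward_air_temperature <- function(state, z) {
  d <- state$d %||% (0.67 * state$h)
  rho_cp <- state$rho_cp %||% RHO_CP_DEFAULT
  if (any(z - d <= state$z_oh)) abort("Require z - d > Z_oh.")
  if (any(state$u_star <= 0)) abort("`u_star` must be positive.")
  if (!is.null(state$L)) {
    r_a <- aerodynamic_resistance(z, d, state$z_oh, state$u_star, state$L)
    return(state$ts - state$h_flux * r_a / rho_cp)
  }
  solve_profile(state$ts, state$h_flux, state$u_star, z, d, state$z_oh,
                rho_cp)$ta
}

#' Infer the heat roughness length from one-level observations
#'
#' With surface temperature from longwave radiation and air temperature
#' measured at a single height, the heat roughness length is the only
#' unknown of the Monin-Obukhov profile and can be solved record by record:
#' the observed resistance is `r_a = rho Cp (Ts - Ta) / H`, and
#' `ln Z_oh = ln(z - d) - 0.4 u* r_a - psi_h(zeta)`. The inversion is
#' accepted only when, in order: (1) `H` has the same sign as `Ts - Ta`;
#' (2) `|H| > 20 W m-2`; (3) `u* > 0.01 m s-1`; and (4) the stability
#' parameter `zeta = (z - d)/L` lies in `(-2, 1)`. Records failing a
#' condition are flagged with the first violated condition as the reason.
#'
#' @param records Tibble with columns `ts` (surface temperature, K; see
#'   [ts_from_longwave()]), `ta_meas_K`, `z_m`, `veg_height_m`, `h_flux`,
#'   `u_star`.
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1.
#' @return The input tibble with columns `L`, `zeta`, `r_a_obs`, `zoh`,
#'   `zoh_valid`, `zoh_reason` (`"ok"` or the first violated condition:
#'   `"sign_mismatch"`, `"h_too_small"`, `"u_star_too_small"`,
#'   `"zeta_out_of_range"`).
#' @export
infer_zoh <- function(records, rho_cp = RHO_CP_DEFAULT) {
  records <- as_tibble(records)
  d <- 0.67 * records$veg_height_m
  dz <- records$z_m - d
  if (any(dz <= 0, na.rm = TRUE)) {
    abort("Measurement height must exceed the zero-plane displacement.")
  }
  ts <- records$ts
  ta <- records$ta_meas_K
  H <- records$h_flux
  u <- records$u_star
  L <- -rho_cp * u^3 * ta / (VON_KARMAN * GRAVITY * H)
  L[!is.na(H) & H == 0] <- Inf
  zeta <- dz / L
  zeta[is.infinite(L)] <- 0
  reason <- rep("ok", nrow(records))
  reason[zeta <= -2 | zeta >= 1] <- "zeta_out_of_range"
  reason[u <= 0.01] <- "u_star_too_small"
  reason[abs(H) <= 20] <- "h_too_small"
  reason[sign(H) != sign(ts - ta)] <- "sign_mismatch"
  r_a_obs <- rho_cp * (ts - ta) / H
  ln_zoh <- log(dz) - VON_KARMAN * u * r_a_obs - psi_h(zeta)
  zoh <- exp(ln_zoh)
  ok <- reason == "ok"
  zoh[!ok] <- NA_real_
  records$L <- L
  records$zeta <- zeta
  records$r_a_obs <- if_else(ok, r_a_obs, NA_real_)
  records$zoh <- zoh
  records$zoh_valid <- ok
  records$zoh_reason <- reason
  records
}

#' Fill invalid roughness lengths from the Z_oh - u* relationship
#'
#' Regresses `ln(Z_oh)` of the valid records on friction velocity (per
#' site when a `site` column is present) and fills invalid records with
#' `exp` of the prediction. Valid records are untouched.
#'
#' @param records Output of [infer_zoh()] (columns `zoh`, `zoh_valid`,
#'   `u_star`, optional `site`).
#' @return `records` with `zoh` filled and a logical `zoh_filled` column.
#' @export
gapfill_zoh <- function(records) {
  records <- as_tibble(records)
  grp <- if ("site" %in% names(records)) records$site else rep("all", nrow(records))
  records$zoh_filled <- FALSE
  for (g in unique(grp)) {
    sel <- grp == g
    valid <- sel & records$zoh_valid
    if (sum(valid) < 2) {
      abort(sprintf("Site '%s' has %d valid roughness estimates; need >= 2 to gap-fill.",
                    g, sum(valid)))
    }
    fill <- sel & !records$zoh_valid
    if (!any(fill)) next
    fit <- lm(log(zoh) ~ u_star, data = records[valid, ])
    records$zoh[fill] <- exp(predict(fit, records[fill, ]))
    records$zoh_filled[fill] <- TRUE
  }
  records
}

#' Normalize measured air temperature to 2 m above the canopy
#'
#' Re-evaluates the Monin-Obukhov profile at the reference height
#' `z = veg_height + 2 m`, removing the influence of heterogeneous
#' measurement heights: `Ta(h + 2) = Ts - H r_a(h + 2) / (rho Cp)` with the
#' record's own Obukhov length (a property of the surface layer, not of
#' the height).
#'
#' @param records Output of [infer_zoh()] (after [gapfill_zoh()] if
#'   needed): columns `ts`, `h_flux`, `u_star`, `veg_height_m`, `zoh`, `L`.
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1.
#' @return `records` with columns `ta_norm` (K at `h + 2` m) and
#'   `r_a_norm` (s m-1 at the reference height).
#' @export
normalize_ta <- function(records, rho_cp = RHO_CP_DEFAULT) {
  records <- as_tibble(records)
  d <- 0.67 * records$veg_height_m
  z <- records$veg_height_m + 2
  if (any(z - d <= records$zoh, na.rm = TRUE)) {
    abort("Reference height h + 2 must satisfy z - d > Z_oh.")
  }
  zeta <- (z - d) / records$L
  zeta[is.infinite(records$L)] <- 0
  r_a <- (log((z - d) / records$zoh) - psi_h(zeta)) /
    (VON_KARMAN * records$u_star)
  records$r_a_norm <- r_a
  records$ta_norm <- records$ts - records$h_flux * r_a / rho_cp
  records
}

#' Decompose the Ts-Ta sensitivity gap into H and r_a pathways
#'
#' First-order expansion of `Ta = Ts - H r_a / (rho Cp)` around the
#' midpoint of the forest and openland states. With
#' `delta = forest - openland` and overbars the forest/openland midpoints,
#' the sensible-heat pathway is `deltaT^H = -rbar_a deltaH / (rho Cp)` and
#' the aerodynamic pathway is `deltaT^ra = -Hbar delta r_a / (rho Cp)`.
#' Because `H r_a` is bilinear, the midpoint rule is exact: the
#' reconstructed air temperature sensitivity
#' `deltaTa* = deltaTs* + deltaT^H + deltaT^ra` equals the true difference
#' of the two profiles with no linearization remainder.
#'
#' @param forest,openland Lists or one-row data frames with elements
#'   `h_flux` (W m-2) and `r_a` (s m-1) at the common reference height.
#' @param delta_ts_star Surface-temperature sensitivity (forest minus
#'   openland), K.
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1 (must be the
#'   one used for both states).
#' @return One-row tibble: `delta_ts_star`, `delta_t_h`, `delta_t_ra`,
#'   `delta_ta_star`, and the fractional shares `share_h`, `share_ra`
#'   (shares of the two pathway terms in their sum; invariant to
#'   `rho_cp`).
#' @export
decompose_sensitivity <- function(forest, openland, delta_ts_star,
                                  rho_cp = RHO_CP_DEFAULT) {
  get <- function(s, f) {
    v <- s[[f]]
    if (is.null(v)) abort(paste0("State is missing element '", f, "'."))
    as.numeric(v)
  }
  h_f <- get(forest, "h_flux"); h_o <- get(openland, "h_flux")
  r_f <- get(forest, "r_a"); r_o <- get(openland, "r_a")
  h_bar <- (h_f + h_o) / 2
  r_bar <- (r_f + r_o) / 2
  d_h <- h_f - h_o
  d_r <- r_f - r_o
  delta_t_h <- -r_bar * d_h / rho_cp
  delta_t_ra <- -h_bar * d_r / rho_cp
  tot <- delta_t_h + delta_t_ra
  share_h <- if (tot != 0) delta_t_h / tot else NA_real_
  share_ra <- if (tot != 0) delta_t_ra / tot else NA_real_
  tibble(
    delta_ts_star = delta_ts_star,
    delta_t_h = delta_t_h,
    delta_t_ra = delta_t_ra,
    delta_ta_star = delta_ts_star + delta_t_h + delta_t_ra,
    share_h = share_h,
    share_ra = share_ra
  )
}
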