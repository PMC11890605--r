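---
title: "Surface versus air temperature effects of tree cover gain: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface versus air temperature effects of tree cover gain: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(canopyclim)
library(dplyr)
```

## The problem

Forests change the local climate through two distinct channels. The
*biochemical* channel is carbon uptake: more biomass, less atmospheric
CO2. The *biophysical* channel is the change in surface properties —
albedo, evapotranspiration, aerodynamic roughness — which warms or cools
the air locally without touching the carbon budget. Most satellite
assessments of the biophysical channel are built on land surface
temperature (Ts), the radiometric temperature of the canopy top, while
climate policy is framed in near-surface air temperature (Ta, 2 m above
the interface). The two respond very differently to tree cover change:
forests couple the surface to the air far more efficiently than smooth
openlands, so Ts anomalies are strongly attenuated before they reach Ta.
`canopyclim` implements a complete, testable pipeline for quantifying
that attenuation and its consequences:

1. **Space-for-time sensitivity mapping** — per-cell regression of
   fine-pixel temperature on tree cover fraction.
2. **Site-based validation** — flux-tower style records, binned by
   shortwave radiation, compared through weighted least squares slopes.
3. **Monin–Obukhov profile decomposition** — attribution of the Ts–Ta
   gap to sensible heat flux and aerodynamic resistance.
4. **CO2-equivalent comparison** — biophysical temperature effects and
   biochemical carbon effects on one per-hectare CO2 scale via TCRE.

Every stage runs on synthetic data with known ground truth, generated by
the package itself, so the statistical machinery is verifiable end to
end without any external downloads.

## Space-for-time sensitivity mapping

Within a coarse grid cell (0.25° by default) all fine pixels share one
macroclimate, so the spatial covariation of temperature with tree cover
isolates the land-surface contribution. For each cell we fit

$$T = \delta T^{\mathrm{bph}} \cdot \mathrm{TC} + b$$

by ordinary least squares over the cell's fine pixels, where TC is the
tree-cover fraction; the slope is the expected local temperature change
for a full (0 → 100%) cover gain, in K.

Pixels are screened first: more than 1% water cover, less than 10% tree
cover (the FAO forest threshold), or an elevation more than 100 m from
the cell mean disqualify a pixel. The low-cover rule is a documented
toggle (`low_cover_filter`): the regression extrapolates to zero cover
even though low-cover pixels are excluded by default, and users can
retain them to probe that choice. A cell is valid only when the sample
size strictly exceeds 90 and the cover spread strictly exceeds 40
percentage points — both thresholds strict, as printed in the source
method. Each monthly map is then trimmed: slopes below the 1st or above
the 99th percentile (linear-interpolation percentiles over valid cells)
are invalidated. Trimming happens after QC, on valid cells only, and the
thresholds are recomputed on every call — a second pass can remove more.
Annual maps average the valid months of each cell and require at least
`min_months = 6` valid months (the source is silent on partially valid
years; six months balances coverage against seasonal bias).

Slope units are fixed as K per full cover gain with the regressor on the
0–1 fraction scale; spatial means are always cos(latitude)-weighted (the
source does not state its weighting; area weighting is the defensible
default on a regular lat/lon grid). Latitude bands are half-open so no
cell is double-counted.

```{r}
scene <- make_scene(n_cells = 20, pixels_per_cell = 400,
                    truth_dts = function(lat) rep(-1.2, length(lat)),
                    noise_sd = 0.3, seed = 42)
map <- estimate_sensitivity_map(scene$rasters$tree_cover, scene$rasters$ts,
                                scene$rasters$elevation, scene$rasters$water,
                                n_min = 50)
mean(map$slope[map$valid])   # truth: -1.2 K
```

## What the synthetic scenes emulate — and what they do not

`make_scene()` generates exactly the data-generating process the
estimator assumes: pixel temperature linear in tree cover plus Gaussian
noise, a latitude-dependent sensitivity rule (by default a sign flip at
50° N — warming north, cooling south, with the air response a quarter of
the surface response, consistent with the 15–30% attenuation the method
was built to measure), and a configurable fraction of pixels violating
each screening rule with a deliberate temperature bias so that skipping
a screen is detectable. Two pixels per cell are pinned near the ends of
the cover support so the QC spread requirement is satisfiable by
construction; the default cover support is 0.05–0.95.

Real scenes are not linear in tree cover, have spatially correlated
noise, and confound cover with topography and moisture. Passing the
recovery tests therefore shows that the estimator is correct *under its
own assumptions* — unbiasedness, screening behavior, QC boundary
placement — not that the space-for-time analogy holds in nature.

## Site validation

Tower surface temperature comes from the longwave balance,
$T_s = [(LW_u - (1-\varepsilon)LW_d)/(\varepsilon\sigma)]^{1/4}$, with
emissivity from the default empirical relation
$\varepsilon = 0.99 - 0.16\,\alpha$ (the source cites an external
relationship without printing it; the linear coefficients are
arguments). Macroclimate is removed by subtracting a gridded temperature
corrected to the site elevation with a locally estimated lapse rate (the
OLS slope of gridded temperature on elevation over a 5 × 5 window; a
flat window falls back to zero lapse with a warning).

Because forest and openland towers cannot be matched pairwise, records
are binned by downward shortwave radiation (10 W m⁻² bins); per bin, the
forest-minus-openland difference of mean anomalies is the temperature
effect of forestation under that radiation load. Bins need at least two
records of each class (otherwise their SE is undefined) and bin centers
are the regressor (centers vs edges is not stated in the source; centers
are unbiased for uniform within-bin radiation). The sensitivity–radiation
slope is fitted by weighted least squares with weights 1/SE, as printed.

The slope's standard error is propagated from the per-bin SEs through
the linear WLS estimator, $\mathrm{Var} = \sum a_i^2 SE_i^2$, rather
than estimated from regression residuals: there are few bins but each
bin mean's SE is well determined by its many records. Over 1500
synthetic replicates the empirical slope SD (2.89e-4) matches the mean
fitted SE (2.86e-4) and the 2-SE interval covers the true slope 95.6% of
the time, so the estimator is calibrated; note that any 2-SE criterion
evaluated on a *finite* replicate set is intrinsically knife-edge, since
the asymptotic coverage of a two-sigma interval is only 95.45%.

```{r}
recs <- make_validation_sites(seed = 7)       # truth: -0.012 / -0.003 K per W m-2
bins <- bin_site_sensitivity(recs)
fit_ts <- wls_slope(bins, "ts")
fit_ta <- wls_slope(bins, "ta")
slope_ratio(fit_ta, fit_ts)
```

## Monin–Obukhov profile decomposition

The vertical structure between the surface and the measurement height is
modeled with similarity theory:

$$T_a(z) = T_s - \frac{H\,r_a(z)}{\rho C_p}, \qquad
  r_a(z) = \frac{1}{0.4\,u_*}\left[\ln\frac{z-d}{Z_{oh}}
  - \Psi_h\!\left(\frac{z-d}{L}\right)\right]$$

with displacement height $d = 0.67h$, heat roughness length $Z_{oh}$,
and Obukhov length $L = -\rho C_p u_*^3 T / (0.4\,g\,H)$. The stability
correction $\Psi_h$ is not printed in the source; the package uses the
standard Businger–Dyer form on the unstable side and $-5\zeta$ on the
stable side, both replaceable in principle and continuous at neutral.
Air density handling is likewise unstated; the default is
$\rho C_p = 1205\ \mathrm{J\,m^{-3}K^{-1}}$ (1.2 kg m⁻³ × 1004
J kg⁻¹ K⁻¹), an argument everywhere it enters. The temperature in $L$ is
the measured air temperature.

$Z_{oh}$ is the only unknown and is inverted record by record, but only
when four conditions hold (checked in this order, and reported as the
first violated reason): the flux and the Ts–Ta gradient agree in sign;
|H| > 20 W m⁻²; u* > 0.01 m s⁻¹; and −2 < ζ < 1. Rejected records are
gap-filled from the site's regression of ln Z_oh on u*. Air temperatures
are then re-evaluated at the common reference height h + 2 m.

A numerical subtlety: the forward generator solves the state to
self-consistency (L depends on the Ta that the profile itself produces;
the fixed point is iterated to 1e-13), which is what makes the inversion
round-trip exact to ~1e-13 relative error on valid states — the same L
is recovered from the measured Ta on the way back.

The Ts–Ta divergence is decomposed by a first-order expansion of
$H r_a$ about the *midpoint* of the forest and openland states:
$\delta T^{H} = -\bar r_a\,\delta H/\rho C_p$ and
$\delta T^{r_a} = -\bar H\,\delta r_a/\rho C_p$ with
$\delta = $ forest − openland. The source does not state its expansion
reference; the midpoint is chosen because the product is bilinear, so
the midpoint rule is *exact* — the reconstructed
$\delta T_a^* = \delta T_s^* + \delta T^H + \delta T^{r_a}$ equals the
true profile difference with no remainder, and the pathway shares are
independent of $\rho C_p$. (Single-state references would leave a
remainder term; aggregated means and per-record decompositions do not
commute, which is why published aggregate examples are reproduced as
worked examples rather than targets.)

```{r}
decompose_sensitivity(forest = list(h_flux = -3.4, r_a = 30.7),
                      openland = list(h_flux = -13.6, r_a = 178.1),
                      delta_ts_star = 1.63)
```

On these winter mean states the resistance pathway carries ~54% of the
attenuation, slightly ahead of the flux pathway — the openland's far
larger aerodynamic resistance sustains a strong temperature inversion
that the well-coupled forest canopy cannot.

## CO2-equivalent comparison

Biomass carbon sensitivity (from the same space-for-time estimator run
on a carbon-density map, tC ha⁻¹) converts to CO2 by the molar ratio
44/12. Temperature sensitivities convert through the transient climate
response to cumulative emissions:
$\delta CO_2e = \delta T / (\mathrm{TCRE} \times A_E)$ with
$A_E = 5.1 \times 10^8\ \mathrm{km^2}$, then
1 Gt km⁻² = 1e7 t ha⁻¹ exactly, then a sign flip to the absorption
convention (warming → negative equivalent, a climate cost). TCRE itself
is the zero-intercept OLS slope of warming on cumulative emissions —
zero intercept because zero cumulative emission means zero response by
construction — with concentration converted at 7.82 Gt CO2 per ppm and a
43% airborne fraction. Monthly biophysical maps are compared against a
single annual biochemical map, since carbon stocks carry no monthly
cycle. Ratio uncertainties use first-order (delta-method) propagation of
the standard errors of the two area-weighted means; the source does not
define its uncertainty estimator.

The per-hectare normalization divides by the whole Earth surface area
for the emission spread while the benefit is counted per hectare of
restored land; this is implemented literally as printed, and users
comparing against per-area accounting schemes should be aware of it.

## Numerical choices and degenerate inputs

* QC thresholds are strict inequalities; the cover-range comparison
  carries a 1e-9 guard so a spread constructed to be exactly the
  threshold is not promoted by floating-point round-off.
* Zero cover variance in a cell yields an invalid cell with a reason
  code, not an exception; a fully screened cell is nodata.
* A bin SE of zero caps that bin's weight at the largest finite weight.
* An aerodynamic resistance driven non-positive by the unstable
  correction is flagged `NA`, with a warning.
* Empty latitude bands yield `NA`, never an error.
* Generators take explicit seeds and touch no global random state
  (`withr::with_seed`); identical arguments give bit-identical output.
* Rasters are stored as plain-text ESRI ASCII grids with full double
  precision, so write→read round trips are bit-exact; units ride in a
  JSON sidecar.

## Problem sizes

The shipped tests exercise: 100-cell scenes at 900 pixels per cell
(recovery to within ±0.03 K of truth at 0.3 K pixel noise), 10,000
random surface-layer states for the inversion round trip, 200 replicates
of the binned WLS stage, and 20-replicate closure checks of the
decomposition. These sizes give comfortable statistical resolution for
every assertion while keeping the full suite fast.

## Known limitations

* The synthetic scenes prescribe the sign structure; nothing radiative
  or snow-related is emergent.
* No spatial autocorrelation correction in the per-cell OLS, and no
  regression beyond OLS — the method is plain linear regression.
* No reprojection: all rasters must share one regular lat/lon grid.
* No surface energy-balance closure correction of tower fluxes, and no
  momentum roughness modeling beyond the heat roughness length.
* Nonlocal (advective/teleconnected) effects of forestation are out of
  scope; results are local sensitivities only.
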