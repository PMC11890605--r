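Package: canopyclim
Title: Surface and Air Temperature Effects of Tree Cover Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the local biophysical sensitivity of land surface
    temperature (Ts) and near-surface air temperature (Ta) to full tree
    cover restoration from the spatial covariation of fine-resolution tree
    cover and temperature (space-for-time substitution), validates the
    sensitivities against flux-tower style site records binned by shortwave
    radiation, attributes the Ts-Ta divergence to sensible heat flux and
    aerodynamic resistance through a Monin-Obukhov profile decomposition,
    and converts biophysical and biochemical (carbon stock) effects to a
    common CO2-absorption-equivalent metric via the transient climate
    response to cumulative emissions (TCRE). Ships a synthetic-data module
    that forward-simulates gridded scenes and paired forest/openland tower
    records with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
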