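#' @keywords internal
IGBP_FOREST <- c("ENF", "EBF", "DBF", "MF")

#' @keywords internal
IGBP_OPENLAND <- c("DNF", "CSH", "OSH", "WSA", "SAV", "GRA", "WET", "CRO",
                   "CVM", "BSV")

#' Read a site record table
#'
#' Reads flux-tower style records from CSV. Each row is one observation
#' interval with the measured air temperature and its measurement height,
#' the four radiation/turbulence terms needed to derive surface temperature
#' and invert the profile, and the co-located gridded macroclimate anchors.
#' The land class is derived from the IGBP code: the four forest classes
#' (evergreen needleleaf, evergreen broadleaf, deciduous broadleaf, mixed)
#' map to `"forest"`; the remaining vegetated classes map to `"openland"`.
#'
#' Required columns: `timestamp`, `igbp_class`, `ta_meas_K`, `z_m`, `lw_up`,
#' `lw_down`, `sw_down`, `h_flux`, `u_star`, `albedo`, `veg_height_m`,
#' `site_elev_m`, `grid_t_K`, `grid_elev_m`. An optional `site` column tags
#' records from the same tower (used by [gapfill_zoh()]).
#'
#' @param path CSV path.
#' @return A tibble with the input columns plus a `land_class` factor.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Site table not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("timestamp", "igbp_class", "ta_meas_K", "z_m", "lw_up",
                "lw_down", "sw_down", "h_flux", "u_star", "albedo",
                "veg_height_m", "site_elev_m", "grid_t_K", "grid_elev_m")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Site table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  numeric_cols <- setdiff(required, c("timestamp", "igbp_class"))
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column '%s' at row %d: '%s'",
                    col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- parsed
  }
  df$land_class <- classify_igbp(df$igbp_class)
  bad_phys <- which(df$u_star < 0 | df$albedo < 0 | df$albedo > 1 |
                      df$sw_down < 0)
  if (length(bad_phys) > 0) {
    abort(sprintf(
      "Row %d violates a physical bound (u_star >= 0, albedo in [0,1], sw_down >= 0).",
      bad_phys[1]))
  }
  as_tibble(df)
}

#' Classify IGBP land-cover codes into forest vs openland
#'
#' @param igbp Character vector of IGBP codes (e.g. `"ENF"`, `"CRO"`).
#' @return Factor with levels `forest`, `openland`.
#' @export
classify_igbp <- function(igbp) {
  igbp <- toupper(trimws(igbp))
  unknown <- setdiff(unique(igbp), c(IGBP_FOREST, IGBP_OPENLAND))
  if (length(unknown) > 0) {
    abort(paste0("Unknown IGBP land-class token(s): ",
                 paste(unknown, collapse = ", ")))
  }
  factor(if_else(igbp %in% IGBP_FOREST, "forest", "openland"),
         levels = c("forest", "openland"))
}

#' Write a site record table
#'
#' Inverse of [read_site_table()]; drops the derived `land_class` column.
#'
#' @param records Tibble of site records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(records, path) {
  out <- records[setdiff(names(records), "land_class")]
  readr::write_csv(out, path)
  invisible(path)
}
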