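#' Construct a regular latitude-longitude raster grid
#'
#' A `raster_grid` holds one gridded variable on a regular lat/lon grid:
#' a numeric matrix (rows = latitudes, columns = longitudes, both cell
#' centers in ascending order), the coordinate vectors, the cell size in
#' degrees, and a units label. Missing cells are `NA`.
#'
#' @param values Numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat,lon Cell-center coordinates in degrees, ascending, evenly
#'   spaced.
#' @param units Units label carried through I/O (e.g. `"K"`).
#' @param cellsize Cell size in degrees; inferred from the coordinate
#'   spacing when either vector has length > 1.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, 2, 3), lat = c(10, 11), lon = c(0, 1, 2),
#'                  units = "K")
#' @export
raster_grid <- function(values, lat, lon, units = "", cellsize = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    abort("`values` must be a length(lat) x length(lon) matrix.")
  }
  step <- function(x) if (length(x) > 1) diff(x)[1] else NULL
  cs <- cellsize %||% step(lat) %||% step(lon)
  if (is.null(cs)) abort("`cellsize` is required for a 1 x 1 grid.")
  if (cs <= 0) abort("Cell size must be positive (coordinates ascending).")
  for (x in list(lat, lon)) {
    if (length(x) > 1 && max(abs(diff(x) - cs)) > 1e-6 * cs) {
      abort("Coordinates must be evenly spaced with a common cell size.")
    }
  }
  structure(
    list(values = unname(values), lat = as.numeric(lat),
         lon = as.numeric(lon), cellsize = as.numeric(cs),
         units = units),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells, %.6g deg, lat [%.4g, %.4g], lon [%.4g, %.4g]%s\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    min(x$lat), max(x$lat), min(x$lon), max(x$lon),
    if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  cat(sprintf("  %d missing of %d cells\n",
              sum(is.na(x$values)), length(x$values)))
  invisible(x)
}

#' @export
as_tibble.raster_grid <- function(x, ...) {
  tibble(
    lat = rep(x$lat, times = length(x$lon)),
    lon = rep(x$lon, each = length(x$lat)),
    value = as.vector(x$values)
  )
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' Values are written row-wise from north to south with full double
#' precision, so a write/read round trip is bit-exact. Units are stored in
#' a small JSON sidecar (`<path>.json`) when non-empty.
#'
#' @param grid A [raster_grid()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  cs <- grid$cellsize
  nodata <- -9999
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", min(grid$lon) - cs / 2),
    sprintf("yllcorner %.10f", min(grid$lat) - cs / 2),
    sprintf("cellsize %.10f", cs),
    sprintf("NODATA_value %d", nodata)
  )
  rows <- vapply(rev(seq_len(nrow(v))), function(i) {
    paste(sprintf("%.17g", v[i, ]), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  if (nzchar(grid$units)) {
    jsonlite::write_json(list(units = grid$units), paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Honors the header's `NODATA_value` (masked cells become `NA`) and picks
#' up a units label from a `<path>.json` sidecar when one exists.
#'
#' @param path Path to an `.asc` file.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(paste0("Raster file not found: ", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(paste0("Malformed ASCII grid header in ", path))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    abort(sprintf("Expected %d values in %s, found %d.",
                  nr * nc, path, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # stored north->south
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  units <- ""
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    units <- jsonlite::read_json(sidecar)$units %||% ""
  }
  cs <- hdr$cellsize
  raster_grid(
    m,
    lat = hdr$yllcorner + cs * (seq_len(nr) - 0.5),
    lon = hdr$xllcorner + cs * (seq_len(nc) - 0.5),
    units = units, cellsize = cs
  )
}

#' Load a named raster variable
#'
#' `path` may be a single `.asc` file (then `variable` is ignored) or a
#' directory holding one `.asc` file per variable, the layout written by
#' [write_scene()]. Requesting a variable absent from a directory raises an
#' error listing the variables that are available.
#'
#' @param path File or directory path.
#' @param variable Variable name (file stem) when `path` is a directory.
#' @return A [raster_grid()].
#' @export
load_raster <- function(path, variable = NULL) {
  if (!file.exists(path)) abort(paste0("Raster path not found: ", path))
  if (dir.exists(path)) {
    if (is.null(variable)) abort("`variable` is required for a raster directory.")
    f <- file.path(path, paste0(variable, ".asc"))
    if (!file.exists(f)) {
      have <- sub("\\.asc$", "", list.files(path, pattern = "\\.asc$"))
      abort(sprintf("Variable '%s' not found in %s. Available: %s",
                    variable, path, paste(have, collapse = ", ")))
    }
    return(read_ascii_grid(f))
  }
  read_ascii_grid(path)
}

#' Monthly mean temperature from monthly maximum and minimum
#'
#' The monthly mean is the arithmetic average of the monthly maximum and
#' minimum values, the convention used to build mean air temperature from
#' daily max/min retrievals.
#'
#' @param t_max,t_min Temperatures in K (vectorized); `t_max >= t_min`.
#' @return `(t_max + t_min) / 2` in K.
#' @export
monthly_mean_temperature <- function(t_max, t_min) {
  if (any(t_max < t_min, na.rm = TRUE)) {
    abort("`t_max` must be >= `t_min` everywhere.")
  }
  (t_max + t_min) / 2
}

#' Area-weighted latitudinal band means
#'
#' Averages a per-cell quantity within latitude bands, weighting each cell
#' by `cos(latitude)` so means approximate true area averages on a regular
#' lat/lon grid. Bands are half-open intervals `[lower, upper)` built from
#' ascending `band_edges` (the topmost band is closed at its upper edge), so
#' no cell falls in two bands. A band with no unmasked cells yields `NA`,
#' not an error.
#'
#' @param x A [raster_grid()] or a data frame with a `lat` column.
#' @param band_edges Ascending latitude edges in degrees. The default gives
#'   the four bands southern mid-latitudes (< 20 deg S), tropics
#'   (20 deg S - 20 deg N), northern mid-latitudes (20 - 50 deg N) and
#'   northern high latitudes (> 50 deg N).
#' @param value For a data-frame `x`, the column to average (tidy-eval;
#'   default `value`).
#' @return A tibble with one row per band: `lat_min`, `lat_max`, `band`
#'   label, area-weighted `mean`, its standard error `se`, and `n` cells.
#' @export
band_area_mean <- function(x, band_edges = c(-90, -20, 20, 50, 90),
                           value = NULL) {
  band_edges <- sort(band_edges)
  if (length(band_edges) < 2) abort("Need at least two band edges.")
  if (inherits(x, "raster_grid")) {
    df <- as_tibble(x)
    val <- df$value
  } else {
    df <- as_tibble(x)
    if (!"lat" %in% names(df)) abort("`x` must have a `lat` column.")
    q <- enquo(value)
    val <- if (rlang::quo_is_null(q)) df$value else rlang::eval_tidy(q, df)
  }
  idx <- findInterval(df$lat, band_edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(band_edges) - 1
  nb <- length(band_edges) - 1
  out <- purrr::map_dfr(seq_len(nb), function(b) {
    sel <- keep & idx == b & !is.na(val)
    w <- cos(df$lat[sel] * pi / 180)
    v <- val[sel]
    if (length(v) == 0 || sum(w) == 0) {
      m <- NA_real_; se <- NA_real_
    } else {
      m <- sum(w * v) / sum(w)
      se <- sqrt(sum(w^2 * (v - m)^2)) / sum(w)
    }
    tibble(
      lat_min = band_edges[b], lat_max = band_edges[b + 1],
      band = sprintf("[%g,%g)", band_edges[b], band_edges[b + 1]),
      mean = m, se = se, n = length(v)
    )
  })
  out
}
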