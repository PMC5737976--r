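# Station-level explanatory variables: fetch-based wave exposure, mean
# current speed (consumed as a precomputed scalar), human population
# change in a 1-degree-diameter buffer, and AR(1)-corrected rainfall
# trend.

#' Directional wind climate over 32 sectors
#'
#' @param frequency Fraction of time the wind blows from each of the 32
#'   sectors (11.25 degrees each); must sum to 1 within 1e-6.
#' @param speed Mean wind speed per sector, m/s.
#' @return List of class `wind_rose`.
#' @export
wind_rose <- function(frequency, speed) {
  if (length(frequency) != 32 || length(speed) != 32)
    stop("wind rose needs exactly 32 sectors")
  if (abs(sum(frequency) - 1) > 1e-6)
    stop("sector frequencies must sum to 1 (got ", sum(frequency), ")")
  if (any(frequency < 0)) stop("frequencies must be non-negative")
  if (any(speed < 0)) stop("wind speeds must be non-negative")
  structure(list(frequency = as.numeric(frequency),
                 speed = as.numeric(speed)), class = "wind_rose")
}

#' Directional fetch lengths over 32 sectors
#'
#' @param lengths_km Open-water distance per sector, km; values above
#'   `cap_km` are truncated (open-ocean wave growth saturates).
#' @param cap_km Fetch cap, km (default 500).
#' @return List of class `fetch_vector`.
#' @export
fetch_vector <- function(lengths_km, cap_km = 500) {
  if (length(lengths_km) != 32) stop("fetch needs exactly 32 sectors")
  if (any(lengths_km < 0)) stop("fetch lengths must be non-negative")
  structure(list(lengths_km = pmin(as.numeric(lengths_km), cap_km),
                 cap_km = cap_km), class = "fetch_vector")
}

#' Fetch-limited significant wave height
#'
#' Deep-water fetch-limited growth law: the dimensionless wave height
#' `g H / U^2` grows as `1.6e-3 * sqrt(g F / U^2)`, i.e.
#' `H = 1.6e-3 * U * sqrt(F / g)` with wind speed `U` (m/s) and fetch
#' `F` (m). Exposed as its own function so alternative growth relations
#' can be plugged into [wave_exposure_index()].
#'
#' @param speed Wind speed, m/s.
#' @param fetch_m Fetch, m.
#' @param g Gravitational acceleration, m/s^2.
#' @return Significant wave height, m.
#' @export
fetch_limited_height <- function(speed, fetch_m, g = 9.81) {
  1.6e-3 * speed * sqrt(fetch_m / g)
}

#' Wave exposure index from wind rose and fetch
#'
#' Per sector, the fetch-limited significant wave height is converted to
#' wave energy density `E = rho g H^2 / 16` (J/m^2) and weighted by the
#' sector's wind frequency; the exposure is the frequency-weighted sum
#' over the 32 sectors. The result is deterministic given its inputs and
#' linear in the sector frequencies.
#'
#' @param rose A [wind_rose()].
#' @param fetch A [fetch_vector()] (already capped).
#' @param height_fun Wave growth relation `f(speed, fetch_m)` returning a
#'   height in m; defaults to [fetch_limited_height()].
#' @param rho Sea-water density, kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @return Non-negative exposure in J/m^2 (relative energy units).
#' @export
wave_exposure_index <- function(rose, fetch,
                                height_fun = fetch_limited_height,
                                rho = 1025, g = 9.81) {
  stopifnot(inherits(rose, "wind_rose"), inherits(fetch, "fetch_vector"))
  if (all(rose$frequency == 0)) stop("all sector frequencies are zero")
  H <- height_fun(rose$speed, fetch$lengths_km * 1000)
  E <- rho * g * H^2 / 16
  sum(rose$frequency * E)
}

#' Simple georeferenced density grid
#'
#' A plain ASCII grid: `values` is an `nrows x ncols` matrix whose first
#' row is the northernmost; `xll`/`yll` give the lower-left corner of the
#' lattice in decimal degrees and `cellsize` the (square) cell side.
#'
#' @param values Numeric matrix of cell densities (persons/km^2).
#' @param xll,yll Lower-left corner, decimal degrees.
#' @param cellsize Cell side, degrees.
#' @return List of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize,
                 nrows = nrow(values), ncols = ncol(values)),
            class = "ascii_grid")
}

#' Read / write the package's ASCII grid format
#'
#' Header lines `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`
#' followed by `nrows` whitespace-separated data rows, north first.
#'
#' @param path File path.
#' @param grid An [ascii_grid()].
#' @return An `ascii_grid` (reader); `path` invisibly (writer).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[1:5]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- do.call(rbind, lapply(lines[-(1:5)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!identical(dim(vals), c(as.integer(h["nrows"]),
                              as.integer(h["ncols"]))))
    stop("grid data does not match header dimensions")
  ascii_grid(vals, h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]])
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  hdr <- c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
           paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
           paste("cellsize", grid$cellsize))
  rows <- apply(grid$values, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# cell-center coordinates of an ascii_grid, row-major
.grid_centers <- function(grid) {
  cx <- grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  cy <- grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  list(x = matrix(cx, grid$nrows, grid$ncols, byrow = TRUE),
       y = matrix(cy, grid$nrows, grid$ncols))
}

# persons in a circular buffer: density (persons/km^2) times cell area,
# summed over cells whose centers fall inside the buffer; cell areas use
# an equirectangular cos(latitude) correction
.buffer_persons <- function(grid, lat, lon, radius_deg, km_per_deg = 111.32) {
  ctr <- .grid_centers(grid)
  inside <- (ctr$x - lon)^2 + (ctr$y - lat)^2 <= radius_deg^2
  area <- (km_per_deg * grid$cellsize)^2 * cos(ctr$y * pi / 180)
  sum(grid$values[inside] * area[inside])
}

#' Population change within a buffer around a station
#'
#' Sums persons (density times cos-latitude-corrected cell area) over the
#' cells whose centers fall within a circular buffer of the stated
#' diameter (planar degrees) centered on the station, for each census
#' grid, and returns the year-2000 total minus the year-1990 total.
#'
#' @param grid_1990,grid_2000 [ascii_grid()] objects on a common lattice
#'   (persons/km^2).
#' @param station One-row data.frame (or list) with `latitude` and
#'   `longitude`.
#' @param buffer_diameter_deg Buffer diameter in degrees (default 1).
#' @return Change in persons (year 2000 minus 1990).
#' @export
population_change <- function(grid_1990, grid_2000, station,
                              buffer_diameter_deg = 1) {
  stopifnot(inherits(grid_1990, "ascii_grid"),
            inherits(grid_2000, "ascii_grid"))
  same <- identical(dim(grid_1990$values), dim(grid_2000$values)) &&
    isTRUE(all.equal(c(grid_1990$xll, grid_1990$yll, grid_1990$cellsize),
                     c(grid_2000$xll, grid_2000$yll, grid_2000$cellsize)))
  if (!same) stop("census grids must share a common lattice")
  lat <- station$latitude[1]; lon <- station$longitude[1]
  r <- buffer_diameter_deg / 2
  g <- grid_1990
  xmax <- g$xll + g$ncols * g$cellsize
  ymax <- g$yll + g$nrows * g$cellsize
  if (lon - r < g$xll || lon + r > xmax || lat - r < g$yll || lat + r > ymax)
    stop(sprintf(paste0("buffer [%.3f, %.3f] x [%.3f, %.3f] extends ",
                        "beyond grid [%.3f, %.3f] x [%.3f, %.3f]"),
                 lon - r, lon + r, lat - r, lat + r,
                 g$xll, xmax, g$yll, ymax))
  .buffer_persons(grid_2000, lat, lon, r) -
    .buffer_persons(grid_1990, lat, lon, r)
}

#' Rainfall trend with AR(1) correction
#'
#' Fits the trend-plus-AR(1) model (no seasonal harmonics) to a monthly
#' precipitation series and returns the trend, its p-value and category.
#'
#' @param series Monthly series (data.frame with `t`, `value`) of
#'   precipitation in mm/month; at least 30 records.
#' @param alpha Significance level for the category.
#' @return List with `trend` (mm/month per year), `p_value`, `category`
#'   and the full `fit`.
#' @export
rainfall_trend <- function(series, alpha = 0.05) {
  if (nrow(series) < 30)
    stop("rainfall trend needs at least 30 monthly records")
  fit <- fit_ar1_gls(series[, c("t", "value")], n_harmonics = 0,
                     alpha = alpha)
  list(trend = fit$omega, p_value = fit$p_omega,
       category = fit$category, fit = fit)
}

#' Assemble the station covariate table
#'
#' Joins the four per-station covariates into one row per station.
#' Stations missing any covariate are dropped and listed in the
#' `excluded` attribute. Optional standardization (mean 0, SD 1) records
#' the centers and scales in attributes so coefficients can be
#' back-transformed.
#'
#' @param wave_exposure,current_speed,delta_population,rainfall_trend
#'   Named numeric vectors (names = station ids).
#' @param standardize Standardize the four columns?
#' @return data.frame with `station_id` and the four covariates;
#'   attributes `excluded`, and when standardized, `center` and `scale`.
#' @export
assemble_covariates <- function(wave_exposure, current_speed,
                                delta_population, rainfall_trend,
                                standardize = FALSE) {
  parts <- list(wave_exposure = wave_exposure,
                current_speed = current_speed,
                delta_population = delta_population,
                rainfall_trend = rainfall_trend)
  for (nm in names(parts))
    if (anyDuplicated(names(parts[[nm]])))
      stop("duplicate station_id in ", nm)
  ids <- Reduce(intersect, lapply(parts, names))
  all_ids <- Reduce(union, lapply(parts, names))
  excluded <- setdiff(all_ids, ids)
  if (length(excluded))
    message("excluding station(s) with incomplete covariates: ",
            paste(sort(excluded), collapse = ", "))
  out <- data.frame(station_id = ids,
                    wave_exposure = unname(parts$wave_exposure[ids]),
                    current_speed = unname(parts$current_speed[ids]),
                    delta_population = unname(parts$delta_population[ids]),
                    rainfall_trend = unname(parts$rainfall_trend[ids]),
                    stringsAsFactors = FALSE)
  if (standardize) {
    num <- names(out)[-1]
    ctr <- vapply(out[num], mean, numeric(1))
    scl <- vapply(out[num], stats::sd, numeric(1))
    out[num] <- Map(function(x, c, s) (x - c) / s, out[num], ctr, scl)
    attr(out, "center") <- ctr
    attr(out, "scale") <- scl
  }
  attr(out, "excluded") <- excluded
  out
}
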