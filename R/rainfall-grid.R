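#' Construct a monthly rainfall grid
#'
#' A `rainfall_grid` holds monthly precipitation totals (mm) on a regular
#' latitude/longitude grid with a time axis starting in January of
#' `start_year`. It is the package's stand-in for a gridded precipitation
#' reanalysis cube.
#'
#' @param lat_axis Ascending vector of cell-centre latitudes (degrees).
#' @param lon_axis Ascending vector of cell-centre longitudes (degrees).
#' @param start_year First calendar year covered; the time axis starts in
#'   January of that year.
#' @param values Numeric array of non-negative monthly totals (mm) with
#'   dimensions `(month_index, lat, lon)`; the time extent must be a whole
#'   number of years.
#' @return An object of class `rainfall_grid`.
#' @seealso [generate_rainfall_grid()] to simulate one,
#'   [extract_cluster_series()] for nearest-cell lookup.
#' @export
rainfall_grid <- function(lat_axis, lon_axis, start_year, values) {
  stopifnot(is.numeric(lat_axis), is.numeric(lon_axis), length(lat_axis) >= 1,
            length(lon_axis) >= 1)
  if (is.unsorted(lat_axis, strictly = TRUE) ||
      is.unsorted(lon_axis, strictly = TRUE)) {
    stop("lat_axis and lon_axis must be strictly ascending")
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-d array (month, lat, lon)")
  }
  d <- dim(values)
  if (d[2] != length(lat_axis) || d[3] != length(lon_axis)) {
    stop("values dimensions do not match the coordinate axes")
  }
  if (d[1] %% 12L != 0L) stop("time axis length must be a multiple of 12")
  if (anyNA(values) || any(values < 0)) {
    stop("rainfall values must be non-negative and non-missing")
  }
  structure(
    list(lat_axis = as.numeric(lat_axis), lon_axis = as.numeric(lon_axis),
         start_year = as.integer(start_year), values = values,
         units = "mm/month"),
    class = "rainfall_grid")
}

#' @export
print.rainfall_grid <- function(x, ...) {
  ny <- dim(x$values)[1] / 12
  cat(sprintf(
    "rainfall_grid: %d x %d cells, %d years from %d (%s)\n",
    length(x$lat_axis), length(x$lon_axis), ny, x$start_year, x$units))
  invisible(x)
}

n_years <- function(grid) dim(grid$values)[1] %/% 12L

# Half a grid cell in each direction; used for the "never extrapolate beyond
# half a cell" containment rule.
grid_resolution <- function(grid) {
  res_lat <- if (length(grid$lat_axis) > 1) min(diff(grid$lat_axis)) else 1
  res_lon <- if (length(grid$lon_axis) > 1) min(diff(grid$lon_axis)) else 1
  c(lat = res_lat, lon = res_lon)
}

#' Simulate a monthly rainfall grid with interannual variability
#'
#' Monthly totals are gamma distributed around a cell/year mean. The mean for
#' cell c in year y is `mean_monthly_mm * m_cy`, where the annual multiplier
#' `m_cy` is lognormal with unit mean and coefficient of variation
#' `annual_cv`, and its log is drawn as a smooth Gaussian random field across
#' cells (exponential covariance, range `annual_range_km`) so that drought
#' years are spatially coherent rather than cell-wise independent. Setting
#' `annual_cv = 0` and `monthly_shape = Inf` gives a deterministic constant
#' grid.
#'
#' @param lat_range,lon_range Length-2 extents in degrees (min, max).
#' @param res_deg Cell size in degrees.
#' @param start_year First calendar year.
#' @param n_years Number of years; at least 2 (at least ~20 recommended so
#'   baseline percentiles are meaningful).
#' @param mean_monthly_mm Long-run mean monthly total, mm.
#' @param monthly_shape Gamma shape of monthly totals (monthly CV is
#'   `1/sqrt(monthly_shape)`); `Inf` for no within-year noise.
#' @param annual_cv Coefficient of variation of the annual multiplier.
#' @param annual_range_km Correlation range of the annual multiplier field.
#' @param seed Integer seed; the grid is reproducible given the seed.
#' @return A [rainfall_grid()].
#' @export
generate_rainfall_grid <- function(lat_range = c(0, 10), lon_range = c(0, 10),
                                   res_deg = 1, start_year = 1981L,
                                   n_years = 30L, mean_monthly_mm = 80,
                                   monthly_shape = 4, annual_cv = 0.3,
                                   annual_range_km = 300, seed = NULL) {
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0) {
    stop("grid extent is degenerate")
  }
  if (n_years < 2) stop("need at least 2 years to form a baseline distribution")
  if (annual_cv < 0) stop("annual_cv must be >= 0")
  nlat <- max(1L, round(diff(lat_range) / res_deg))
  nlon <- max(1L, round(diff(lon_range) / res_deg))
  lat_axis <- lat_range[1] + res_deg * (seq_len(nlat) - 0.5)
  lon_axis <- lon_range[1] + res_deg * (seq_len(nlon) - 0.5)
  ncell <- nlat * nlon
  cells <- expand.grid(lat = lat_axis, lon = lon_axis,
                       KEEP.OUT.ATTRS = FALSE)  # lat varies fastest

  with_seed(seed, {
    if (annual_cv > 0) {
      sdlog <- sqrt(log1p(annual_cv^2))
      f <- sample_spatial_field(cells$lat, cells$lon, sd = sdlog,
                                range_km = annual_range_km, n_draws = n_years)
      mult <- exp(f - sdlog^2 / 2)              # ncell x n_years, mean 1
    } else {
      mult <- matrix(1, ncell, n_years)
    }
    n_month <- 12L * n_years
    # mean for (month, cell): recycle each year's multiplier over 12 months
    year_of_month <- rep(seq_len(n_years), each = 12L)
    mean_tc <- mean_monthly_mm * t(mult)[year_of_month, , drop = FALSE]
    if (is.infinite(monthly_shape)) {
      vals <- mean_tc
    } else {
      if (monthly_shape <= 0) stop("monthly_shape must be positive")
      vals <- matrix(
        rgamma(n_month * ncell, shape = monthly_shape,
               rate = monthly_shape / as.vector(mean_tc)),
        n_month, ncell)
    }
    arr <- array(vals, dim = c(n_month, nlat, nlon))
    rainfall_grid(lat_axis, lon_axis, start_year, arr)
  })
}

#' Write / read a rainfall grid as long-format CSV
#'
#' Plain-text serialization of the cube: columns `year, month, lat, lon, mm`,
#' one row per (month, cell), preceded by comment lines carrying the units
#' attribute. This is the package's portable text stand-in for a NetCDF cube.
#'
#' @param grid A [rainfall_grid()].
#' @param path Output file path.
#' @return `write_rainfall_csv` returns `path` invisibly;
#'   `read_rainfall_csv` returns a [rainfall_grid()].
#' @export
write_rainfall_csv <- function(grid, path) {
  stopifnot(inherits(grid, "rainfall_grid"))
  d <- dim(grid$values)
  idx <- expand.grid(t = seq_len(d[1]), i = seq_len(d[2]), j = seq_len(d[3]),
                     KEEP.OUT.ATTRS = FALSE)
  dt <- data.table::data.table(
    year = grid$start_year + (idx$t - 1L) %/% 12L,
    month = 1L + (idx$t - 1L) %% 12L,
    lat = grid$lat_axis[idx$i],
    lon = grid$lon_axis[idx$j],
    mm = as.vector(grid$values))
  con <- file(path, "w")
  writeLines(c("# rainfall grid, units: mm/month",
               sprintf("# start_year: %d", grid$start_year)), con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_rainfall_csv
#' @export
read_rainfall_csv <- function(path) {
  dt <- data.table::fread(path, skip = "year,month")
  lat_axis <- sort(unique(dt$lat))
  lon_axis <- sort(unique(dt$lon))
  start_year <- min(dt$year)
  t_idx <- (dt$year - start_year) * 12L + dt$month
  arr <- array(NA_real_,
               dim = c(max(t_idx), length(lat_axis), length(lon_axis)))
  arr[cbind(t_idx, match(dt$lat, lat_axis), match(dt$lon, lon_axis))] <- dt$mm
  rainfall_grid(lat_axis, lon_axis, start_year, arr)
}
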