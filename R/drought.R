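# Drought exposure: trailing 12-month rainfall ranked against the site's
# baseline distribution of same-calendar-window totals, then cut into the
# ordinal categories used in the drought/IPV literature.

DROUGHT_LEVELS <- c("none", "moderate", "severe", "extreme")

#' Extract the monthly series of the nearest grid cell
#'
#' Nearest-cell lookup by great-circle distance; ties are broken toward the
#' lower cell index (latitude index varying fastest). The coordinate must lie
#' within the grid extent padded by half a cell — lookups never extrapolate.
#'
#' @param grid A [rainfall_grid()].
#' @param lat,lon Query coordinate in degrees.
#' @return Numeric vector of monthly totals (mm), January of
#'   `grid$start_year` first.
#' @export
extract_cluster_series <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "rainfall_grid"), length(lat) == 1,
            length(lon) == 1)
  res <- grid_resolution(grid)
  if (lat < min(grid$lat_axis) - res["lat"] / 2 ||
      lat > max(grid$lat_axis) + res["lat"] / 2 ||
      lon < min(grid$lon_axis) - res["lon"] / 2 ||
      lon > max(grid$lon_axis) + res["lon"] / 2) {
    stop("coordinate lies outside the rainfall grid (padded by half a cell)")
  }
  idx <- nearest_cell_index(grid, lat, lon)
  grid$values[, idx[1], idx[2]]
}

# (lat_index, lon_index) of the nearest cell centre; ties -> lower index in
# column-major (lat-fastest) order.
nearest_cell_index <- function(grid, lat, lon) {
  cells <- expand.grid(lat = grid$lat_axis, lon = grid$lon_axis,
                       KEEP.OUT.ATTRS = FALSE)
  d <- gc_dist_km(lat, lon, cells$lat, cells$lon)
  k <- which.min(d)  # which.min returns the first (lowest) index on ties
  nlat <- length(grid$lat_axis)
  c((k - 1L) %% nlat + 1L, (k - 1L) %/% nlat + 1L)
}

# Index of the month (1-based from series start) for a calendar year/month.
month_index <- function(start_year, year, month) {
  (year - start_year) * 12L + month
}

#' Trailing 12-month rainfall total before an interview
#'
#' Sum of the 12 calendar months strictly preceding (and excluding) the
#' interview month — the recall window of the survey outcomes.
#'
#' @param series Monthly series from [extract_cluster_series()].
#' @param start_year Calendar year of `series[1]` (January).
#' @param interview_year,interview_month Interview date.
#' @return Total rainfall in mm.
#' @export
trailing_annual_rainfall <- function(series, start_year, interview_year,
                                     interview_month) {
  end <- month_index(start_year, interview_year, interview_month) - 1L
  start <- end - 11L
  if (start < 1L || end > length(series)) {
    stop("series does not cover the 12 months before the interview")
  }
  sum(series[start:end])
}

#' Baseline distribution of same-window annual totals
#'
#' For an interview date, returns the trailing 12-month totals ending in the
#' same calendar month of every earlier year of the series (the target year's
#' own window is excluded, avoiding self-ranking bias).
#'
#' @inheritParams trailing_annual_rainfall
#' @return Numeric vector of baseline totals (earliest first).
#' @export
baseline_totals <- function(series, start_year, interview_year,
                            interview_month) {
  end <- month_index(start_year, interview_year, interview_month) - 1L
  ends <- seq(end - 12L, by = -12L, length.out = max(0L, (end - 12L) %/% 12L))
  ends <- sort(ends[ends - 11L >= 1L])
  if (length(ends) < 2L) {
    stop("fewer than 2 complete baseline windows before the target window")
  }
  vapply(ends, function(e) sum(series[(e - 11L):e]), numeric(1))
}

#' Mid-rank empirical percentile of a rainfall total
#'
#' `(#\{baseline < target\} + 0.5 * #\{baseline = target\}) / n`: symmetric in
#' ties and exact in expectation for exchangeable annual totals.
#'
#' @param target_total Trailing 12-month total, mm.
#' @param baseline Baseline totals from [baseline_totals()].
#' @return Fraction in `[0, 1]`.
#' @export
rainfall_percentile <- function(target_total, baseline) {
  if (length(baseline) == 0) stop("baseline distribution is empty")
  (sum(baseline < target_total) + 0.5 * sum(baseline == target_total)) /
    length(baseline)
}

#' Ordinal drought category from a rainfall percentile
#'
#' Cutoffs follow the published convention: extreme below the 2.5th
#' percentile, severe in \[2.5%, 10%), moderate in \[10%, 30%), none at or
#' above 30%. Intervals are lower-inclusive half-open, so an exact 0.30 is
#' classified `none` (consistent with the binary definition of drought as
#' "< 30% of normal").
#'
#' @param percentile Fraction(s) in `[0, 1]`.
#' @return Factor with levels `none < moderate < severe < extreme`.
#' @export
classify_drought <- function(percentile) {
  if (anyNA(percentile) || any(percentile < 0 | percentile > 1)) {
    stop("percentile must lie in [0, 1]")
  }
  out <- ifelse(percentile < 0.025, "extreme",
         ifelse(percentile < 0.10, "severe",
         ifelse(percentile < 0.30, "moderate", "none")))
  factor(out, levels = DROUGHT_LEVELS)
}

#' Binary drought indicator from a rainfall percentile
#'
#' `drought` iff the percentile is below 0.30; the boundary belongs to
#' `normal`.
#'
#' @inheritParams classify_drought
#' @return Factor with levels `normal`, `drought`.
#' @export
binarize_drought <- function(percentile) {
  if (anyNA(percentile) || any(percentile < 0 | percentile > 1)) {
    stop("percentile must lie in [0, 1]")
  }
  factor(ifelse(percentile < 0.30, "drought", "normal"),
         levels = c("normal", "drought"))
}

#' Classify drought exposure for a respondent table
#'
#' Computes, for every distinct (cluster, interview date) in `records`, the
#' trailing 12-month total at the nearest rainfall cell, its mid-rank
#' percentile against the site baseline, the ordinal category and the binary
#' indicator, and appends/overwrites the columns `drought_total_mm`,
#' `drought_percentile`, `drought_category`, `drought_binary`.
#'
#' @param records Respondent table with columns `cluster_id`, `latitude`,
#'   `longitude`, `interview_year`, `interview_month`.
#' @param grid A [rainfall_grid()] covering all cluster coordinates.
#' @return `records` with exposure columns appended.
#' @export
classify_exposure <- function(records, grid) {
  stopifnot(inherits(grid, "rainfall_grid"))
  need <- c("cluster_id", "latitude", "longitude", "interview_year",
            "interview_month")
  if (!all(need %in% names(records))) {
    stop("records must contain: ", paste(need, collapse = ", "))
  }
  key <- paste(records$cluster_id, records$interview_year,
               records$interview_month)
  first <- !duplicated(key)
  uk <- key[first]
  lat <- records$latitude[first]; lon <- records$longitude[first]
  yy <- records$interview_year[first]; mm <- records$interview_month[first]
  tot <- pct <- numeric(length(uk))
  for (i in seq_along(uk)) {
    s <- extract_cluster_series(grid, lat[i], lon[i])
    tot[i] <- trailing_annual_rainfall(s, grid$start_year, yy[i], mm[i])
    base <- baseline_totals(s, grid$start_year, yy[i], mm[i])
    pct[i] <- rainfall_percentile(tot[i], base)
  }
  m <- match(key, uk)
  records$drought_total_mm <- tot[m]
  records$drought_percentile <- pct[m]
  records$drought_category <- classify_drought(pct[m])
  records$drought_binary <- binarize_drought(pct[m])
  records
}
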