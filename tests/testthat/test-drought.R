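# drought module: nearest-cell lookup, trailing windows, baseline
# percentiles and the published category cutoffs.

test_that("nearest-cell lookup matches a brute-force oracle and tie rule", {
  g <- fixture_constant_grid()
  # stamp each cell with a unique constant so series identify cells
  nlat <- length(g$lat_axis); nlon <- length(g$lon_axis)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    g$values[, i, j] <- (i - 1) * nlon + j
  }
  # exact cell centre
  s <- extract_cluster_series(g, g$lat_axis[2], g$lon_axis[3])
  expect_equal(unique(s), (2 - 1) * nlon + 3)
  # equidistant between two centres in latitude -> lower index cell
  mid <- (g$lat_axis[1] + g$lat_axis[2]) / 2
  s_tie <- extract_cluster_series(g, mid, g$lon_axis[1])
  expect_equal(unique(s_tie), 1)
  # randomized coordinates vs exhaustive argmin
  set.seed(2)
  for (r in 1:25) {
    lat <- runif(1, 0, 4); lon <- runif(1, 30, 34)
    cells <- expand.grid(lat = g$lat_axis, lon = g$lon_axis)
    d <- hav_km(lat, lon, cells$lat, cells$lon)
    k <- which.min(d)
    want <- g$values[1, (k - 1) %% nlat + 1, (k - 1) %/% nlat + 1]
    expect_equal(extract_cluster_series(g, lat, lon)[1], want)
  }
  expect_error(extract_cluster_series(g, 10, 30), "outside")
})

test_that("trailing window sums the 12 months before the interview", {
  expect_equal(trailing_annual_rainfall(rep(10, 120), 2000, 2005, 7), 120)
  # interview June 2010 on a month-indexed series: June 2009 .. May 2010
  series <- seq_len(40 * 12)  # value = month index, start 1981
  got <- trailing_annual_rainfall(series, 1981, 2010, 6)
  want <- sum(series[(month_index <- (2009 - 1981) * 12 + 6):(month_index + 11)])
  expect_equal(got, want)
  # random series vs loop oracle
  set.seed(9)
  s <- rgamma(30 * 12, 3, 0.1)
  tot <- 0
  end <- (2005 - 1990) * 12 + 3 - 1
  for (t in (end - 11):end) tot <- tot + s[t]
  expect_equal(trailing_annual_rainfall(s, 1990, 2005, 3), tot)
  expect_error(trailing_annual_rainfall(rep(1, 12), 2000, 2000, 6),
               "does not cover")
})

test_that("baseline windows cover prior years and exclude the target", {
  s <- rep(10, 30 * 12)
  b <- baseline_totals(s, 1981, 2010, 6)
  expect_equal(length(b), 28)
  expect_true(all(b == 120))
  # one anomalous year -> exactly one baseline total differs
  s2 <- s
  s2[((1990 - 1981) * 12 + 1):((1990 - 1981) * 12 + 12)] <- 20
  b2 <- baseline_totals(s2, 1981, 2010, 1)  # windows are calendar years
  expect_equal(sum(b2 != 120), 1)
  # loop oracle on a random series
  set.seed(4)
  sr <- rgamma(30 * 12, 2, 0.05)
  br <- baseline_totals(sr, 1981, 2009, 4)
  ends <- seq((2008 - 1981) * 12 + 3, 12, by = -12)
  want <- rev(vapply(ends, function(e) sum(sr[(e - 11):e]), numeric(1)))
  expect_equal(br, want)
  expect_error(baseline_totals(rep(1, 24), 1981, 1982, 6), "fewer than 2")
})

test_that("mid-rank percentile handles ties and extremes", {
  expect_equal(rainfall_percentile(250, c(100, 200, 300, 400)), 0.5)
  expect_equal(rainfall_percentile(50, c(100, 200, 300, 400)), 0)
  expect_equal(rainfall_percentile(100, 100), 0.5)
  expect_equal(rainfall_percentile(500, c(100, 200)), 1)
  expect_error(rainfall_percentile(1, numeric(0)), "empty")
})

test_that("drought categories follow the published cutoffs", {
  expect_equal(as.character(classify_drought(0.20)), "moderate")
  expect_equal(as.character(classify_drought(0.05)), "severe")
  expect_equal(as.character(classify_drought(0.01)), "extreme")
  expect_equal(as.character(classify_drought(0.50)), "none")
  # lower-inclusive half-open boundaries
  expect_equal(as.character(classify_drought(c(0.025, 0.10, 0.30))),
               c("severe", "moderate", "none"))
  expect_error(classify_drought(1.2), "0, 1")
  expect_equal(as.character(binarize_drought(c(0.29, 0.30, 0.95))),
               c("drought", "normal", "normal"))
  expect_error(binarize_drought(-0.1), "0, 1")
})

test_that("category severity is monotone in the percentile", {
  p <- seq(0, 1, by = 0.001)
  sev <- as.integer(classify_drought(p))  # none=1 < moderate < severe < extreme
  rank_sev <- c(4, 3, 2, 1)[sev]          # increasing with percentile
  expect_true(all(diff(rank_sev) >= 0))
  expect_identical(binarize_drought(p) == "drought",
                   classify_drought(p) != "none")
})

test_that("long-run category frequencies match the interval widths", {
  # iid annual totals, each year ranked against all other years
  set.seed(77)
  n_yr <- 400
  s <- rgamma(n_yr * 12, shape = 3, rate = 1 / 30)
  cats <- vapply(4:n_yr, function(yr) {
    as.character(classify_drought(rainfall_percentile(
      trailing_annual_rainfall(s, 1, yr, 1),
      baseline_totals(s, 1, yr, 1))))
  }, character(1))
  props <- table(factor(cats, levels = c("none", "moderate", "severe",
                                         "extreme")))
  props <- props / sum(props)
  expect_lt(abs(props[["moderate"]] - 0.20), 0.05)
  expect_lt(abs(props[["severe"]] - 0.075), 0.035)
  expect_lt(abs(props[["extreme"]] - 0.025), 0.025)
})

test_that("classify_exposure appends consistent columns", {
  rec <- fixture_records(seed = 5, n_clusters = 8, n_women = 3)
  g <- fixture_grid(seed = 6)
  out <- classify_exposure(rec[setdiff(names(rec),
                                       grep("^drought", names(rec),
                                            value = TRUE))], g)
  expect_true(all(out$drought_percentile >= 0 & out$drought_percentile <= 1))
  expect_identical(out$drought_category, classify_drought(out$drought_percentile))
  expect_identical(out$drought_binary == "drought",
                   out$drought_category != "none")
})
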