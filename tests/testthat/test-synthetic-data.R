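# synthetic_data module: rainfall grids, the latent spatial field, and the
# respondent generator.

test_that("constant-mode grid is exactly constant and determinism holds", {
  g <- fixture_constant_grid(mean_mm = 10)
  expect_true(all(g$values == 10))
  g1 <- generate_rainfall_grid(seed = 42, n_years = 21)
  g2 <- generate_rainfall_grid(seed = 42, n_years = 21)
  expect_identical(g1$values, g2$values)
  g3 <- generate_rainfall_grid(seed = 43, n_years = 21)
  expect_false(identical(g1$values, g3$values))
})

test_that("grid constructor validates shape and values", {
  expect_error(generate_rainfall_grid(n_years = 1), "at least 2 years")
  expect_error(generate_rainfall_grid(lat_range = c(3, 3)), "degenerate")
  expect_error(rainfall_grid(c(1, 0), c(0, 1), 1981,
                             array(1, c(12, 2, 2))), "ascending")
  expect_error(rainfall_grid(c(0, 1), c(0, 1), 1981,
                             array(-1, c(12, 2, 2))), "non-negative")
  expect_error(rainfall_grid(c(0, 1), c(0, 1), 1981,
                             array(1, c(13, 2, 2))), "multiple of 12")
})

test_that("per-cell annual total CV is close to the configured CV", {
  g <- generate_rainfall_grid(lat_range = c(0, 5), lon_range = c(30, 35),
                              res_deg = 1, n_years = 30, annual_cv = 0.3,
                              seed = 5)
  d <- dim(g$values)
  yr <- rep(seq_len(30), each = 12)
  cvs <- apply(g$values, c(2, 3), function(s) {
    tot <- tapply(s, yr, sum)
    sd(tot) / mean(tot)
  })
  expect_lt(abs(mean(cvs) - 0.3) / 0.3, 0.25)
})

test_that("rainfall CSV round trip preserves the cube", {
  g <- fixture_grid(seed = 3, n_years = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rainfall_csv(g, path)
  g2 <- read_rainfall_csv(path)
  expect_equal(g2$lat_axis, g$lat_axis)
  expect_equal(g2$start_year, g$start_year)
  expect_equal(g2$values, g$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("spatial field honours degenerate and closed-form cases", {
  expect_identical(sample_spatial_field(c(0, 1), c(30, 30), sd = 0,
                                        range_km = 100), c(0, 0))
  expect_error(sample_spatial_field(0, 30, sd = 1, range_km = 0),
               "positive")
  # coincident coordinates get identical values (correlation 1 at d = 0)
  f <- sample_spatial_field(c(2, 2, 3), c(31, 31, 31), sd = 1,
                            range_km = 200, seed = 9)
  expect_equal(f[1], f[2], tolerance = 1e-8)
  # Monte-Carlo correlation of two points ~1 km apart vs closed form
  f2 <- sample_spatial_field(c(0, 1 / 111.1949), c(30, 30), sd = 1,
                             range_km = 100, seed = 10, n_draws = 500)
  expect_lt(abs(cor(f2[1, ], f2[2, ]) - exp(-1 / 100)), 0.05)
})

test_that("empirical variogram of the field increases with distance", {
  set.seed(31)
  co <- rand_coords(150, span = 6)
  f <- sample_spatial_field(co[, 1], co[, 2], sd = 1, range_km = 300,
                            seed = 13, n_draws = 40)
  D <- matrix(0, 150, 150)
  for (i in 1:150) D[i, ] <- hav_km(co[i, 1], co[i, 2], co[, 1], co[, 2])
  pair <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  gamma_ij <- rowMeans((f[pair[, 1], ] - f[pair[, 2], ])^2) / 2
  bins <- cut(d, breaks = c(0, 100, 250, 450, Inf))
  vario <- tapply(gamma_ij, bins, mean)
  expect_true(all(diff(vario) > 0))
})

test_that("population generator calibrates prevalence and is deterministic", {
  grid <- fixture_constant_grid()
  zero_effects <- list(
    married = 0, literate = 0, rural = 0,
    age_band = c(`<20` = 0, `20-29` = 0, `30-39` = 0, `40-49` = 0),
    births_band = c(`0-2` = 0, `3-4` = 0, `>4` = 0),
    partner_education = c(none = 0, primary = 0, secondary = 0, higher = 0),
    partner_age_band = c(`<20` = 0, `20-29` = 0, `30-39` = 0, `40-49` = 0,
                         `>49` = 0),
    hh_size_band = c(`1-3` = 0, `4-5` = 0, `>5` = 0))
  base <- list(n_surveys = 2L, n_clusters_per_survey = 25L,
               n_women_per_cluster = 20L, beta_covariates = zero_effects,
               survey_effects = c(0, 0), spatial_sd = 0,
               drought_confound = 0, seed = 21L)
  # all coefficients zero -> prevalence 1/2
  cfg0 <- do.call(simulation_config, c(base, list(beta0 = 0)))
  rec0 <- generate_population(cfg0, grid)
  se <- sqrt(0.25 / nrow(rec0))
  expect_lt(abs(mean(rec0$physical) - 0.5), 3 * se)
  # logistic(-1.386) = 0.2000
  cfg2 <- do.call(simulation_config, c(base, list(beta0 = -1.386)))
  rec2 <- generate_population(cfg2, grid)
  p <- plogis(-1.386)
  expect_lt(abs(mean(rec2$sexual) - p), 3 * sqrt(p * (1 - p) / nrow(rec2)))
  # determinism
  expect_identical(generate_population(cfg2, grid), rec2)
})

test_that("prevalence matches mean logistic(linear predictor) generally", {
  rec <- fixture_records(seed = 15, n_clusters = 25, n_women = 20,
                         spatial_sd = 0)
  expected <- mean(plogis(rec$true_lp))
  se <- sqrt(expected * (1 - expected) / nrow(rec))
  for (o in c("controlling", "emotional", "physical", "sexual")) {
    expect_lt(abs(mean(rec[[o]]) - expected), 3 * se)
  }
})

test_that("respondent records satisfy structural invariants", {
  rec <- fixture_records(seed = 8)
  expect_true(all(rec$latitude >= -90 & rec$latitude <= 90))
  expect_true(all(rec$longitude >= -180 & rec$longitude <= 180))
  expect_true(all(rec$wealth_quintile %in% 1:5))
  expect_true(all(rec$employment %in%
                    c("agriculture", "manual", "professional", "unemployed")))
  # all women in a cluster share coordinates and survey
  sp <- split(rec[c("latitude", "longitude", "survey_id")], rec$cluster_id)
  expect_true(all(vapply(sp, function(d) nrow(unique(d)) == 1L, logical(1))))
  # binary consistent with category
  expect_identical(rec$drought_binary == "drought",
                   rec$drought_category != "none")
})

test_that("generator rejects interviews without an exposure window", {
  grid <- fixture_constant_grid()
  cfg <- simulation_config(seed = 1, interview_year = grid$start_year)
  expect_error(generate_population(cfg, grid), "precedes grid start")
})

test_that("respondent CSV round trip preserves types", {
  rec <- fixture_records(seed = 4, n_clusters = 5, n_women = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_respondents(rec, path)
  rec2 <- read_respondents(path)
  expect_equal(levels(rec2$drought_category),
               c("none", "moderate", "severe", "extreme"))
  expect_equal(rec2$true_lp, rec$true_lp, tolerance = 1e-12)
  expect_identical(as.character(rec2$water_source),
                   as.character(rec$water_source))
})
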