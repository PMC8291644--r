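# Small in-code fixtures shared across test files.

# Fast constant grid (no randomness) covering a 4 x 4 degree box.
fixture_constant_grid <- function(mean_mm = 10, n_years = 25) {
  generate_rainfall_grid(lat_range = c(0, 4), lon_range = c(30, 34),
                         res_deg = 1, n_years = n_years,
                         mean_monthly_mm = mean_mm, monthly_shape = Inf,
                         annual_cv = 0, seed = 1)
}

# Default stochastic grid for pipeline tests.
fixture_grid <- function(seed = 11, n_years = 25) {
  generate_rainfall_grid(lat_range = c(0, 6), lon_range = c(30, 36),
                         res_deg = 1, n_years = n_years, seed = seed)
}

# Small synthetic population with exposure columns.
fixture_records <- function(seed = 7, n_surveys = 2, n_clusters = 15,
                            n_women = 10, spatial_sd = 0.5,
                            drought_confound = 0, beta_drought = c(
                              moderate = 0, severe = 0, extreme = 0),
                            grid = fixture_grid(seed + 1)) {
  cfg <- simulation_config(
    n_surveys = n_surveys, n_clusters_per_survey = n_clusters,
    n_women_per_cluster = n_women, spatial_sd = spatial_sd,
    drought_confound = drought_confound, beta_drought = beta_drought,
    seed = seed)
  generate_population(cfg, grid)
}
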