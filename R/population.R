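# Synthetic DHS-like respondents: clustered, geolocated women with
# categorical covariates, survey fixed effects, a spatially correlated latent
# risk field, and Bernoulli outcomes from a logistic model with a known
# (possibly zero) drought effect.

COVARIATE_LEVELS <- list(
  age_band = c("<20", "20-29", "30-39", "40-49"),
  births_band = c("0-2", "3-4", ">4"),
  partner_education = c("none", "primary", "secondary", "higher"),
  partner_age_band = c("<20", "20-29", "30-39", "40-49", ">49"),
  hh_size_band = c("1-3", "4-5", ">5"),
  employment = c("agriculture", "manual", "professional", "unemployed"),
  water_source = c("dug well", "piped", "purchased", "rain", "surface",
                   "tube well", "other")
)

IPV_OUTCOMES <- c("controlling", "emotional", "physical", "sexual")

# Default covariate margins: the sub-Saharan Africa column of the summary
# table of the continental study (married 84.1%, rural 69.1%, ...); factor
# frequencies renormalized to sum to 1.
default_covariate_freqs <- function() {
  norm <- function(x) x / sum(x)
  list(
    married = 0.841, literate = 0.415, rural = 0.691,
    age_band = norm(c(`<20` = 0.070, `20-29` = 0.421, `30-39` = 0.332,
                      `40-49` = 0.177)),
    births_band = norm(c(`0-2` = 0.316, `3-4` = 0.287, `>4` = 0.330)),
    partner_education = norm(c(none = 0.300, primary = 0.334,
                               secondary = 0.294, higher = 0.072)),
    partner_age_band = norm(c(`<20` = 0.004, `20-29` = 0.207, `30-39` = 0.367,
                              `40-49` = 0.254, `>49` = 0.168)),
    hh_size_band = norm(c(`1-3` = 0.217, `4-5` = 0.348, `>5` = 0.434)),
    employment = norm(c(agriculture = 0.45, manual = 0.15,
                        professional = 0.15, unemployed = 0.25)),
    water_source = norm(c(`dug well` = 0.15, piped = 0.30, purchased = 0.05,
                          rain = 0.05, surface = 0.15, `tube well` = 0.20,
                          other = 0.10))
  )
}

# Conventional covariate log-odds (|effect| <= 1); reference level first.
default_covariate_effects <- function() {
  list(
    married = 0.3, literate = -0.3, rural = 0.2,
    age_band = c(`<20` = 0, `20-29` = 0.10, `30-39` = 0.15, `40-49` = 0.10),
    births_band = c(`0-2` = 0, `3-4` = 0.15, `>4` = 0.30),
    partner_education = c(none = 0, primary = -0.10, secondary = -0.25,
                          higher = -0.50),
    partner_age_band = c(`<20` = 0, `20-29` = 0, `30-39` = 0.05,
                         `40-49` = 0.05, `>49` = 0.10),
    hh_size_band = c(`1-3` = 0, `4-5` = 0.05, `>5` = 0.10)
  )
}

#' Configuration for the synthetic-population generator
#'
#' Houses the ground truth of the data-generating logistic model: the
#' intercept, covariate log-odds, the true drought effect (by category),
#' survey fixed effects, and the latent spatial risk field parameters.
#' `drought_confound` adds `drought_confound * (0.5 - percentile)` to the
#' cluster's latent risk, directly correlating the confounder with exposure
#' (the precondition for the spatial Type-I-error phenomenon); set it to 0
#' for an unconfounded world.
#'
#' @param n_surveys,n_clusters_per_survey,n_women_per_cluster Design sizes
#'   (all >= 1).
#' @param beta0 Intercept log-odds.
#' @param beta_covariates Covariate effects; see
#'   `spatipv:::default_covariate_effects()` for the shape.
#' @param beta_drought Named log-odds for `moderate`, `severe`, `extreme`
#'   (reference: no drought).
#' @param survey_effects Log-odds offsets, one per survey (first survey is
#'   the analysis reference); default evenly spaced in `[-0.2, 0.2]`.
#' @param spatial_sd,spatial_range_km Latent field marginal SD (>= 0) and
#'   exponential-covariance range (> 0).
#' @param drought_confound Log-odds per unit of (0.5 - drought percentile).
#' @param covariate_freqs Sampling frequencies; defaults to the documented
#'   Africa-like margins.
#' @param outcome_offsets Optional per-outcome intercept offsets (named by
#'   outcome); default all zero so the four outcomes share `beta0`.
#' @param interview_year Calendar year of all interviews; defaults to the
#'   grid's final year at generation time.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_surveys = 3L, n_clusters_per_survey = 50L,
                              n_women_per_cluster = 20L, beta0 = -1.386,
                              beta_covariates = default_covariate_effects(),
                              beta_drought = c(moderate = 0, severe = 0,
                                               extreme = 0),
                              survey_effects = NULL, spatial_sd = 1,
                              spatial_range_km = 300, drought_confound = 0,
                              covariate_freqs = default_covariate_freqs(),
                              outcome_offsets = NULL, interview_year = NULL,
                              seed = 1L) {
  stopifnot(n_surveys >= 1, n_clusters_per_survey >= 1,
            n_women_per_cluster >= 1)
  if (spatial_sd < 0) stop("spatial_sd must be >= 0")
  if (spatial_range_km <= 0) stop("spatial_range_km must be positive")
  if (is.null(survey_effects)) {
    survey_effects <- if (n_surveys == 1L) 0 else
      seq(-0.2, 0.2, length.out = n_surveys)
  }
  stopifnot(length(survey_effects) == n_surveys)
  miss <- setdiff(c("moderate", "severe", "extreme"), names(beta_drought))
  if (length(miss)) stop("beta_drought must name moderate, severe, extreme")
  if (is.null(outcome_offsets)) {
    outcome_offsets <- setNames(numeric(4), IPV_OUTCOMES)
  }
  structure(
    list(n_surveys = as.integer(n_surveys),
         n_clusters_per_survey = as.integer(n_clusters_per_survey),
         n_women_per_cluster = as.integer(n_women_per_cluster),
         beta0 = beta0, beta_covariates = beta_covariates,
         beta_drought = beta_drought, survey_effects = survey_effects,
         spatial_sd = spatial_sd, spatial_range_km = spatial_range_km,
         drought_confound = drought_confound,
         covariate_freqs = covariate_freqs,
         outcome_offsets = outcome_offsets,
         interview_year = interview_year, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("sim_config: %d surveys x %d clusters x %d women ",
           "(spatial_sd = %.2f, range = %.0f km, confound = %.2f)\n"),
    x$n_surveys, x$n_clusters_per_survey, x$n_women_per_cluster,
    x$spatial_sd, x$spatial_range_km, x$drought_confound))
  invisible(x)
}

sample_level <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Generate a synthetic respondent table
#'
#' Places clusters uniformly in the rainfall-grid extent, samples covariates
#' from the configured category frequencies, computes each cluster's drought
#' exposure from the grid, draws a latent spatially correlated risk field at
#' the cluster coordinates, and generates the four binary outcomes from the
#' logistic model
#' `logit(p) = beta0 + X beta + beta_d x_d + delta_survey + field + confound`.
#' One woman per household, so the woman id doubles as the household id.
#' Ground-truth columns (`field`, `true_lp`) are returned alongside the
#' observables.
#'
#' @param config A [simulation_config()].
#' @param grid A [rainfall_grid()]; interviews default to its final year.
#' @return A `data.frame`, one row per woman.
#' @export
generate_population <- function(config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "rainfall_grid"))
  iy <- config$interview_year
  if (is.null(iy)) iy <- grid$start_year + n_years(grid) - 1L
  if (iy < grid$start_year + 1L) {
    stop("interview year precedes grid start + 1 year; no exposure window")
  }
  if (iy > grid$start_year + n_years(grid) - 1L) {
    stop("interview year beyond grid coverage")
  }
  ns <- config$n_surveys; nc <- config$n_clusters_per_survey
  nw <- config$n_women_per_cluster
  ncl <- ns * nc
  n <- ncl * nw
  fq <- config$covariate_freqs
  ce <- config$beta_covariates

  with_seed(config$seed, {
    cl_lat <- runif(ncl, min(grid$lat_axis), max(grid$lat_axis))
    cl_lon <- runif(ncl, min(grid$lon_axis), max(grid$lon_axis))
    cl_survey <- rep(seq_len(ns), each = nc)
    survey_month <- sample(1:12, ns, replace = TRUE)

    clusters <- data.frame(
      cluster_id = seq_len(ncl), survey_id = cl_survey,
      latitude = cl_lat, longitude = cl_lon,
      interview_year = iy, interview_month = survey_month[cl_survey])
    clusters <- classify_exposure(clusters, grid)
    field <- sample_spatial_field(cl_lat, cl_lon, config$spatial_sd,
                                  config$spatial_range_km)
    confound <- config$drought_confound * (0.5 - clusters$drought_percentile)

    rows <- rep(seq_len(ncl), each = nw)
    rec <- data.frame(
      woman_id = seq_len(n),
      cluster_id = clusters$cluster_id[rows],
      survey_id = clusters$survey_id[rows],
      latitude = clusters$latitude[rows],
      longitude = clusters$longitude[rows],
      interview_year = clusters$interview_year[rows],
      interview_month = clusters$interview_month[rows],
      stringsAsFactors = FALSE)
    rec$married <- as.integer(runif(n) < fq$married)
    rec$literate <- as.integer(runif(n) < fq$literate)
    rec$rural <- as.integer(runif(n) < fq$rural)
    for (v in c("age_band", "births_band", "partner_education",
                "partner_age_band", "hh_size_band", "employment",
                "water_source")) {
      rec[[v]] <- factor(sample_level(n, fq[[v]]), levels = COVARIATE_LEVELS[[v]])
    }
    # pooled wealth: continuous index with a survey-level shift, quintiled
    # across all surveys (the pooled-quintile rule of the wealth analysis)
    rec$wealth_index <- rnorm(n) + 0.3 * scale(rec$survey_id)[, 1]
    rec$wealth_quintile <- wealth_quintiles(rec$wealth_index)

    rec$drought_total_mm <- clusters$drought_total_mm[rows]
    rec$drought_percentile <- clusters$drought_percentile[rows]
    rec$drought_category <- clusters$drought_category[rows]
    rec$drought_binary <- clusters$drought_binary[rows]
    rec$field <- field[rows]

    lp <- config$beta0 +
      ce$married * rec$married + ce$literate * rec$literate +
      ce$rural * rec$rural +
      ce$age_band[as.character(rec$age_band)] +
      ce$births_band[as.character(rec$births_band)] +
      ce$partner_education[as.character(rec$partner_education)] +
      ce$partner_age_band[as.character(rec$partner_age_band)] +
      ce$hh_size_band[as.character(rec$hh_size_band)] +
      c(none = 0, config$beta_drought)[as.character(rec$drought_category)] +
      config$survey_effects[rec$survey_id] +
      rec$field + confound[rows]
    lp <- unname(lp)
    rec$true_lp <- lp
    for (o in IPV_OUTCOMES) {
      rec[[o]] <- rbinom(n, 1L, plogis(lp + config$outcome_offsets[[o]]))
    }
    rec
  })
}

#' Write / read a respondent table as CSV
#'
#' @param records Respondent table (as from [generate_population()]).
#' @param path File path.
#' @return `write_respondents` returns `path` invisibly; `read_respondents`
#'   returns a `data.frame` with the documented factor levels restored.
#' @export
write_respondents <- function(records, path) {
  data.table::fwrite(records, path)
  invisible(path)
}

#' @rdname write_respondents
#' @export
read_respondents <- function(path) {
  rec <- as.data.frame(data.table::fread(path))
  for (v in names(COVARIATE_LEVELS)) {
    if (v %in% names(rec)) rec[[v]] <- factor(rec[[v]], COVARIATE_LEVELS[[v]])
  }
  if ("drought_category" %in% names(rec)) {
    rec$drought_category <- factor(rec$drought_category, DROUGHT_LEVELS)
  }
  if ("drought_binary" %in% names(rec)) {
    rec$drought_binary <- factor(rec$drought_binary, c("normal", "drought"))
  }
  rec
}
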