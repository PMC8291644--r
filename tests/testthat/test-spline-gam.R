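# spline_gam module: design construction, knot placement, the thin-plate
# basis, and the PIRLS fitter against independent oracles.

make_fit_design <- function(n = 300, seed = 1, p_drought = 0.3,
                            two_class = TRUE) {
  set.seed(seed)
  co <- rand_coords(n)
  rec <- data.frame(
    latitude = co[, 1], longitude = co[, 2],
    survey_id = sample(1:2, n, TRUE),
    married = rbinom(n, 1, 0.8), literate = rbinom(n, 1, 0.4),
    rural = rbinom(n, 1, 0.7),
    drought_binary = factor(ifelse(runif(n) < p_drought, "drought",
                                   "normal"), c("normal", "drought")),
    physical = rbinom(n, 1, 0.3))
  rec$drought_category <- factor(
    ifelse(rec$drought_binary == "drought",
           sample(c("moderate", "severe", "extreme"), n, TRUE,
                  c(0.6, 0.3, 0.1)), "none"),
    c("none", "moderate", "severe", "extreme"))
  rec
}

test_that("build_design counts columns and encodes references", {
  rec <- fixture_records(seed = 30, n_clusters = 30, n_women = 15)
  des <- suppressWarnings(build_design(rec, "physical"))
  # counting oracle: 1 intercept + binaries + sum(observed levels - 1) over
  # factors + identified drought dummies + (surveys - 1)
  levels_sum <- sum(vapply(
    c("age_band", "births_band", "partner_education", "partner_age_band",
      "hh_size_band"),
    function(v) length(unique(rec[[v]])) - 1L, integer(1)))
  n_drought <- length(des$drought_cols)
  expect_equal(ncol(des$X), 1 + 3 + levels_sum + n_drought + (2 - 1))
  expect_equal(sum(grepl("^survey=", colnames(des$X))), 1)
  expect_equal(unname(des$references["drought"]), "none")
  expect_error(build_design(rec, "height"), "outcome must be one of")
})

test_that("absent drought categories are dropped as unidentifiable", {
  rec <- make_fit_design(200, seed = 2)
  rec$drought_category[] <- "none"
  rec$drought_binary[] <- "normal"
  expect_warning(des <- build_design(rec, "physical",
                                     covariates = c("married", "literate",
                                                    "rural")),
                 "unidentifiable")
  expect_length(des$drought_cols, 0)
})

test_that("make_knots honours K = 0, K = n and the bounding cap", {
  set.seed(3)
  co <- rand_coords(40)
  expect_equal(nrow(make_knots(co[, 1], co[, 2], 0)), 0)
  all_k <- make_knots(co[, 1], co[, 2], 40, seed = 1)
  expect_setequal(paste(round(all_k[, 1], 9), round(all_k[, 2], 9)),
                  paste(round(co[, 1], 9), round(co[, 2], 9)))
  expect_error(make_knots(co[, 1], co[, 2], 41), "smaller K")
  k <- make_knots(co[, 1], co[, 2], 10, seed = 5)
  expect_identical(k, make_knots(co[, 1], co[, 2], 10, seed = 5))
  # every knot inside the spherical cap bounding the input points
  emb <- spatipv:::sphere_embed(co[, 1], co[, 2])
  ctr <- colMeans(emb); ctr <- ctr / sqrt(sum(ctr^2))
  cap <- min(emb %*% ctr)
  kemb <- spatipv:::sphere_embed(k[, 1], k[, 2])
  expect_true(all(kemb %*% ctr >= cap - 1e-9))
})

test_that("spline basis has thin-plate closed forms", {
  knots <- cbind(lat = c(0, 10), lon = c(30, 40))
  b <- spline_basis(c(0, 0), c(30, 210), knots)
  expect_equal(b$basis[1, 1], 0)                 # observation at knot 1
  expect_equal(b$basis[2, 1], 4 * log(2))        # antipodal: chord 2
  expect_equal(b$penalty, t(b$penalty))
  expect_equal(diag(b$penalty), c(0, 0))
  expect_gte(min(eigen(b$penalty_fit, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
  # identical coordinates give identical basis rows
  b2 <- spline_basis(c(5, 5), c(33, 33), knots)
  expect_equal(b2$basis[1, ], b2$basis[2, ])
  expect_error(spline_basis(c(0), c(30), rbind(knots, knots[1, ])),
               "duplicate")
})

test_that("intercept-only fit recovers the closed-form MLE", {
  n <- 100
  rec <- data.frame(latitude = runif(n), longitude = runif(n),
                    survey_id = 1L,
                    drought_binary = factor(rep("normal", n),
                                            c("normal", "drought")),
                    physical = rep(c(1, 0), c(25, 75)))
  des <- suppressWarnings(build_design(rec, "physical",
                                       covariates = character(0),
                                       drought = "binary"))
  fit <- fit_penalized_logistic(des)
  expect_equal(unname(fit$coefficients[1]), log(25 / 75), tolerance = 1e-8)
  expect_equal(fit$edf, 1)
})

test_that("K = 0 fits match an independent Newton MLE", {
  for (s in 1:5) {
    rec <- make_fit_design(n = 100 + 80 * s, seed = s)
    des <- build_design(rec, "physical",
                        covariates = c("married", "literate", "rural"))
    fit <- fit_penalized_logistic(des)
    oracle <- newton_logistic(des$X, des$y)
    expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-8)
    if (max(abs(oracle$beta)) < 10) {  # skip quasi-separated coefficients
      expect_equal(unname(fit$coefficients), unname(oracle$beta),
                   tolerance = 1e-6)
    }
  }
})

test_that("huge lambda collapses the spline to the fixed-effects fit", {
  rec <- make_fit_design(n = 250, seed = 4)
  des <- build_design(rec, "physical",
                      covariates = c("married", "literate", "rural"))
  knots <- make_knots(des$coords[, 1], des$coords[, 2], 12, seed = 1)
  basis <- spline_basis(des$coords[, 1], des$coords[, 2], knots)
  fit_inf <- fit_penalized_logistic(des, basis, lambda_grid = 1e12)
  fit0 <- fit_penalized_logistic(des)
  w <- fit_inf$coefficients[-(1:fit_inf$n_fixed)]
  expect_lt(sqrt(sum(w^2)), 1e-4)
  expect_equal(unname(fit_inf$coefficients[1:fit_inf$n_fixed]),
               unname(fit0$coefficients), tolerance = 1e-3)
})

test_that("deviance is monotone in lambda and AIC selects from the grid", {
  rec <- make_fit_design(n = 250, seed = 6)
  des <- build_design(rec, "physical",
                      covariates = c("married", "literate", "rural"))
  knots <- make_knots(des$coords[, 1], des$coords[, 2], 15, seed = 2)
  basis <- spline_basis(des$coords[, 1], des$coords[, 2], knots)
  fit <- fit_penalized_logistic(des, basis)
  tab <- fit$lambda_table
  expect_true(all(diff(tab$deviance) >= -1e-6))    # toward the rigid fit
  expect_true(all(diff(tab$edf) <= 1e-6))          # complexity shrinks
  expect_equal(fit$aic, min(tab$aic))
  fit0 <- fit_penalized_logistic(des)
  expect_lte(max(tab$deviance), fit0$deviance + 1e-3)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_gte(fit$edf, fit$n_fixed - 1e-8)
  expect_lte(fit$edf, fit$n_fixed + nrow(knots) + 1e-8)
})

test_that("edf equals the dense influence-matrix trace", {
  rec <- make_fit_design(n = 150, seed = 7)
  des <- build_design(rec, "physical",
                      covariates = c("married", "literate"))
  knots <- make_knots(des$coords[, 1], des$coords[, 2], 10, seed = 3)
  basis <- spline_basis(des$coords[, 1], des$coords[, 2], knots)
  fit <- fit_penalized_logistic(des, basis, lambda_grid = 1.0)
  # dense oracle: trace of W^1/2 C (C'WC + lambda P)^-1 C' W^1/2
  C <- fit$C
  mu <- fit$fitted
  w <- pmax(mu * (1 - mu), 1e-10)
  P <- matrix(0, ncol(C), ncol(C))
  sp <- (fit$n_fixed + 1):ncol(C)
  P[sp, sp] <- basis$penalty_fit
  A <- (sqrt(w) * C) %*% solve(crossprod(sqrt(w) * C) + 1.0 * P,
                               t(sqrt(w) * C))
  expect_equal(fit$edf, sum(diag(A)), tolerance = 1e-6)
})

test_that("fitter rejects degenerate inputs", {
  rec <- make_fit_design(n = 80, seed = 8)
  rec$physical <- 1
  des <- suppressWarnings(build_design(rec, "physical",
                                       covariates = c("married")))
  expect_error(fit_penalized_logistic(des), "both classes")
})

test_that("residuals match the Pearson formula elementwise", {
  rec <- make_fit_design(n = 120, seed = 9)
  des <- build_design(rec, "physical", covariates = c("married", "rural"))
  fit <- fit_penalized_logistic(des)
  r <- model_residuals(fit)
  oracle <- vapply(seq_along(des$y), function(i) {
    (des$y[i] - fit$fitted[i]) / sqrt(fit$fitted[i] * (1 - fit$fitted[i]))
  }, numeric(1))
  expect_equal(r, oracle, tolerance = 1e-10)
  # y = 1, p = 0.5 -> +1 and y = 0, p = 0.5 -> -1
  toy <- fit
  toy$fitted <- rep(0.5, 2)
  toy$design$y <- c(1, 0)
  expect_equal(model_residuals(toy), c(1, -1))
})
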