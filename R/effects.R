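# Average marginal effects of drought in percentage points: the mean change
# in predicted probability when every woman's drought exposure is toggled
# counterfactually from the reference (no drought) to a given level, holding
# covariates, survey effects and the fitted spatial term at their observed
# values.

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of hypotheses (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m %% 1 != 0) {
    stop("m must be a positive integer")
  }
  alpha / m
}

# eta under a counterfactual drought assignment. level = "none"/"normal"
# zeroes all drought dummies; otherwise the level's dummy is set to 1 and
# the others to 0, for every row.
counterfactual_eta <- function(fit, level, theta = NULL) {
  cols <- fit$design$drought_cols
  if (is.null(theta)) theta <- fit$coefficients
  eta <- if (is.null(dim(theta))) drop(fit$C %*% theta) else fit$C %*% theta
  if (!length(cols)) return(eta)
  Xd <- fit$C[, cols, drop = FALSE]
  bd <- if (is.null(dim(theta))) theta[cols] else theta[cols, , drop = FALSE]
  obs <- if (is.null(dim(theta))) drop(Xd %*% bd) else Xd %*% bd
  eta <- eta - obs
  if (!level %in% c("none", "normal")) {
    target <- if (fit$design$drought == "binary") {
      if (level != "drought") {
        stop(sprintf("drought level '%s' is not identified in this model",
                     level))
      }
      "drought"
    } else paste0("drought=", level)
    if (!target %in% cols) {
      stop(sprintf("drought level '%s' is not identified in this model",
                   level))
    }
    if (is.null(dim(theta))) {
      eta <- eta + theta[target]
    } else {
      eta <- sweep(eta, 2, theta[target, ], "+")
    }
  }
  eta
}

#' Average marginal effect of a drought level
#'
#' `AME = 100 * mean_i [ p_i(level) - p_i(reference) ]` where `p_i(.)` is
#' the fitted probability with row i's drought exposure counterfactually set
#' and everything else (including the spatial term) held at observed values.
#' When the level's coefficient is exactly zero the AME is exactly zero.
#'
#' @param fit An [fit_penalized_logistic()] fit.
#' @param level Drought level to toggle on: `"moderate"`, `"severe"`,
#'   `"extreme"` (categorical models) or `"drought"` (binary models).
#' @param reference Baseline level, default no drought.
#' @return AME in percentage points.
#' @export
average_marginal_effect <- function(fit, level, reference = "none") {
  stopifnot(inherits(fit, "ipv_fit"))
  eta1 <- counterfactual_eta(fit, level)
  eta0 <- counterfactual_eta(fit, reference)
  100 * mean(plogis(eta1) - plogis(eta0))
}

#' Simulation-based uncertainty for an AME
#'
#' Draws coefficient vectors from the Gaussian approximation at the optimum
#' (mean = estimates, covariance = penalized-information inverse),
#' recomputes the AME for each draw, and reports the sample standard
#' deviation as the standard error plus a two-sided normal p-value for
#' `AME / se`.
#'
#' @inheritParams average_marginal_effect
#' @param n_draws Number of coefficient draws.
#' @param seed Seed for the draws.
#' @return List with `ame`, `se`, `p_value`, `draws` (the per-draw AMEs).
#' @export
ame_uncertainty <- function(fit, level, reference = "none", n_draws = 1000L,
                            seed = 1L) {
  stopifnot(inherits(fit, "ipv_fit"), n_draws >= 2)
  L <- tryCatch(chol(fit$covariance), error = function(e)
    stop("coefficient covariance is not positive definite"))
  m <- length(fit$coefficients)
  theta <- with_seed(seed,
    fit$coefficients + t(L) %*% matrix(rnorm(m * n_draws), m, n_draws))
  rownames(theta) <- names(fit$coefficients)
  ame_draws <- 100 * colMeans(plogis(counterfactual_eta(fit, level, theta)) -
                              plogis(counterfactual_eta(fit, reference,
                                                        theta)))
  ame <- average_marginal_effect(fit, level, reference)
  se <- sd(ame_draws)
  list(ame = ame, se = se,
       p_value = if (se > 0) 2 * pnorm(-abs(ame / se)) else NA_real_,
       draws = ame_draws)
}

#' Pooled wealth quintiles
#'
#' Cuts a wealth index pooled across all surveys at the empirical
#' 20/40/60/80 percentiles via ranks; tied blocks take the lower quintile.
#'
#' @param wealth_index Numeric vector with at least 5 distinct values.
#' @return Integer quintile labels 1..5.
#' @export
wealth_quintiles <- function(wealth_index) {
  if (anyNA(wealth_index)) stop("wealth_index contains missing values")
  if (length(unique(wealth_index)) < 5) {
    stop("need at least 5 distinct wealth values")
  }
  r <- rank(wealth_index, ties.method = "min")
  as.integer(ceiling(5 * r / length(wealth_index)))
}

SUBGROUP_VARS <- c(wealth = "wealth_quintile", employment = "employment",
                   water_source = "water_source", urbanization = "rural")

#' Subgroup analyses with binary drought
#'
#' For each category of the grouping variable and each outcome, runs the
#' full pipeline on the subgroup — binary-drought design, knot escalation,
#' AME of drought vs normal — with Bonferroni correction for the four
#' outcomes (m = 4). Subgroups lacking both outcome classes or both drought
#' states (or smaller than `min_n`) are reported as skipped with a reason.
#'
#' @param records Respondent table with exposure columns.
#' @param grouping One of `"wealth"`, `"employment"`, `"water_source"`,
#'   `"urbanization"`.
#' @param outcomes Outcomes to analyse (default all four).
#' @param ladder,alpha,weights,lambda_grid,seed Passed to
#'   [knot_escalation()].
#' @param m Bonferroni divisor (default 4, one per outcome).
#' @param n_draws Draws for [ame_uncertainty()].
#' @param min_n Minimum subgroup size.
#' @return Data frame, one row per category x outcome: n, selected knots,
#'   AME, se, p-value, significance flag, or a skip reason.
#' @export
subgroup_analysis <- function(records, grouping, outcomes = IPV_OUTCOMES,
                              ladder = c(0, 25, 50), alpha = 0.05,
                              weights = weight_spec(),
                              lambda_grid = default_lambda_grid(),
                              m = 4L, n_draws = 500L, min_n = 50L,
                              seed = 1L) {
  if (!grouping %in% names(SUBGROUP_VARS)) {
    stop("unknown grouping; use one of: ",
         paste(names(SUBGROUP_VARS), collapse = ", "))
  }
  gvar <- SUBGROUP_VARS[[grouping]]
  if (!gvar %in% names(records)) stop("records lack column ", gvar)
  g <- records[[gvar]]
  if (grouping == "urbanization") {
    g <- factor(ifelse(g == 1, "rural", "urban"), c("rural", "urban"))
  }
  cats <- if (is.factor(g)) levels(g) else sort(unique(g))
  thr <- bonferroni_threshold(alpha, m)
  out <- list()
  for (cat_i in cats) {
    sub <- records[which(g == cat_i), , drop = FALSE]
    for (o in outcomes) {
      row <- data.frame(grouping = grouping, category = as.character(cat_i),
                        outcome = o, n = nrow(sub), selected_knots = NA,
                        ame = NA_real_, se = NA_real_, p_value = NA_real_,
                        threshold = thr, significant = NA, skipped = "",
                        stringsAsFactors = FALSE)
      reason <- NULL
      if (nrow(sub) < min_n) {
        reason <- sprintf("subgroup smaller than %d", min_n)
      } else if (length(unique(sub[[o]])) < 2) {
        reason <- "outcome has a single class"
      } else if (length(unique(sub$drought_binary)) < 2) {
        reason <- "subgroup has a single drought state"
      }
      if (is.null(reason)) {
        res <- tryCatch({
          des <- build_design(sub, o, drought = "binary")
          sel <- knot_escalation(des, ladder = ladder, alpha = alpha,
                                 weights = weights, seed = seed,
                                 lambda_grid = lambda_grid)
          unc <- ame_uncertainty(sel$selected_model, "drought",
                                 reference = "normal", n_draws = n_draws,
                                 seed = seed)
          row$selected_knots <- sel$selected_knots
          row$ame <- unc$ame; row$se <- unc$se; row$p_value <- unc$p_value
          row$significant <- unc$p_value < thr
          row
        }, error = function(e) {
          row$skipped <- paste("failed:", conditionMessage(e)); row
        })
        row <- res
      } else {
        row$skipped <- reason
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
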