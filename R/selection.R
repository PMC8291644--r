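# Knot-ladder model selection: fit increasingly complex spatial splines and
# keep the first (smallest) basis whose residuals show no statistically
# significant Moran autocorrelation at level alpha. Selection depends only
# on the Moran p-value; AIC is recorded per rung for reporting.

#' Escalate spline knots until residual autocorrelation disappears
#'
#' Fits the penalized logistic model for each knot count in `ladder`
#' (ascending; 0 = no spatial term) and stops at the first rung whose
#' residual Moran p-value is at least `alpha`. Rungs exceeding the number of
#' distinct coordinate points are skipped with a warning; rungs whose fit
#' errors are recorded and skipped. If no rung passes, the largest fitted
#' rung is returned with `exhausted = TRUE`.
#'
#' @param design An [build_design()] object.
#' @param ladder Strictly increasing knot counts; default
#'   `c(0, 50, 100, 500, 1000, 1500)`.
#' @param alpha Moran significance level (default 0.05).
#' @param weights A [weight_spec()] for the residual Moran test.
#' @param seed Seed for knot placement.
#' @param lambda_grid Smoothing grid passed to the fitter.
#' @param block_size Moran streaming block size.
#' @param residual_type Residuals used in the Moran test.
#' @return An object of class `selection_result`: `ladder`, `per_rung`
#'   (knots, edf, aic, moran_I, moran_p, status per attempted rung),
#'   `selected_knots`, `selected_model`, `model0` (the rung-0 fit if
#'   attempted), `exhausted`.
#' @export
knot_escalation <- function(design, ladder = c(0, 50, 100, 500, 1000, 1500),
                            alpha = 0.05, weights = weight_spec(),
                            seed = 1L, lambda_grid = default_lambda_grid(),
                            block_size = 512L,
                            residual_type = c("pearson", "deviance")) {
  stopifnot(inherits(design, "ipv_design"))
  residual_type <- match.arg(residual_type)
  if (is.unsorted(ladder, strictly = TRUE)) {
    stop("ladder must be strictly increasing")
  }
  nd <- nrow(unique(design$coords))
  usable <- ladder <= nd
  if (!all(usable)) {
    warning(sprintf("skipping rungs beyond the %d distinct locations: %s",
                    nd, paste(ladder[!usable], collapse = ", ")))
  }
  rungs <- ladder[usable]
  per <- data.frame(knots = integer(0), edf = numeric(0), aic = numeric(0),
                    moran_I = numeric(0), moran_p = numeric(0),
                    status = character(0), stringsAsFactors = FALSE)
  model0 <- NULL
  selected_model <- NULL
  selected_knots <- NA_integer_
  last_model <- NULL
  last_knots <- NA_integer_
  for (K in rungs) {
    fit <- tryCatch({
      basis <- if (K > 0) {
        spline_basis(design$coords[, 1], design$coords[, 2],
                     make_knots(design$coords[, 1], design$coords[, 2], K,
                                seed = seed))
      } else NULL
      fit_penalized_logistic(design, basis, lambda_grid = lambda_grid)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      per <- rbind(per, data.frame(knots = K, edf = NA, aic = NA,
                                   moran_I = NA, moran_p = NA,
                                   status = paste("failed:",
                                                  conditionMessage(fit))))
      next
    }
    mt <- moran_test(model_residuals(fit, residual_type), weights,
                     coords = design$coords, method = "analytic",
                     block_size = block_size)
    per <- rbind(per, data.frame(knots = K, edf = fit$edf, aic = fit$aic,
                                 moran_I = mt$I, moran_p = mt$p_value,
                                 status = "ok"))
    if (K == 0) model0 <- fit
    last_model <- fit; last_knots <- K
    if (mt$p_value >= alpha) {
      selected_model <- fit
      selected_knots <- K
      break
    }
  }
  exhausted <- is.null(selected_model)
  if (exhausted) {
    if (is.null(last_model)) stop("every rung failed to fit")
    selected_model <- last_model
    selected_knots <- last_knots
  }
  structure(list(ladder = ladder, alpha = alpha, per_rung = per,
                 selected_knots = selected_knots,
                 selected_model = selected_model, model0 = model0,
                 exhausted = exhausted),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: selected %d knots%s (alpha = %g)\n",
              x$selected_knots,
              if (x$exhausted) " [ladder exhausted]" else "", x$alpha))
  print(x$per_rung, row.names = FALSE)
  invisible(x)
}

# Wald z / two-sided p for each drought column of a fit.
drought_wald <- function(fit) {
  cols <- fit$design$drought_cols
  if (!length(cols)) {
    return(data.frame(term = character(0), estimate = numeric(0),
                      se = numeric(0), p_value = numeric(0)))
  }
  est <- fit$coefficients[cols]
  se <- sqrt(diag(fit$covariance)[cols])
  data.frame(term = cols, estimate = unname(est), se = unname(se),
             p_value = unname(2 * pnorm(-abs(est / se))),
             row.names = NULL)
}

#' Compare the selected spatial model against the no-spline fit
#'
#' Reports the AIC difference (naive minus spatial), the drought-term
#' estimates under both models, and how many drought terms are significant
#' at the Bonferroni threshold `alpha / m` under each.
#'
#' @param selection A [knot_escalation()] result whose ladder included rung
#'   0.
#' @param alpha Family-wise level.
#' @param m Number of hypotheses for the Bonferroni correction.
#' @return List with `aic_naive`, `aic_spatial`, `aic_diff`,
#'   `selected_knots`, `threshold`, and a `drought` table with both models'
#'   estimates and significance.
#' @export
compare_spatial_vs_naive <- function(selection, alpha = 0.05, m = 12L) {
  stopifnot(inherits(selection, "selection_result"))
  if (is.null(selection$model0)) {
    stop("selection did not include (or failed to fit) rung 0")
  }
  thr <- bonferroni_threshold(alpha, m)
  w0 <- drought_wald(selection$model0)
  ws <- drought_wald(selection$selected_model)
  tab <- merge(w0, ws, by = "term", suffixes = c("_naive", "_spatial"),
               sort = FALSE)
  tab$significant_naive <- tab$p_value_naive < thr
  tab$significant_spatial <- tab$p_value_spatial < thr
  list(aic_naive = selection$model0$aic,
       aic_spatial = selection$selected_model$aic,
       aic_diff = selection$model0$aic - selection$selected_model$aic,
       selected_knots = selection$selected_knots, threshold = thr,
       n_significant_naive = sum(tab$significant_naive),
       n_significant_spatial = sum(tab$significant_spatial),
       drought = tab)
}
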