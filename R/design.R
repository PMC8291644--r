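# Fixed-effects design for the outcome model: intercept, covariate dummies
# (reference level dropped), drought terms (reference: no drought), and
# survey fixed effects (reference: first survey).

DEFAULT_COVARIATES <- c("married", "literate", "age_band", "births_band",
                        "partner_education", "partner_age_band",
                        "hh_size_band", "rural")

#' Build the fixed-effects design matrix for one outcome
#'
#' Dummy-encodes the covariates (first listed level is the reference), the
#' drought exposure (reference: `none` / `normal`), and the survey fixed
#' effects (reference: first survey id). Rows with missing values in any used
#' column are dropped with a warning (mirroring the exclusion of respondents
#' with missing data). All-constant dummy columns — e.g. a drought category
#' absent from the data — are dropped with a warning flagging the term as
#' unidentifiable; remaining columns must be full rank.
#'
#' @param records Respondent table including exposure columns (see
#'   [classify_exposure()]).
#' @param outcome One of `"controlling"`, `"emotional"`, `"physical"`,
#'   `"sexual"`.
#' @param covariates Character vector of covariate columns to include.
#' @param drought `"category"` for the three ordinal dummies, `"binary"` for
#'   a single drought indicator.
#' @return An object of class `ipv_design`: list with the response `y`,
#'   fixed matrix `X`, per-row `coords` (lat, lon), the drought column names
#'   `drought_cols`, and bookkeeping (references, dropped columns).
#' @export
build_design <- function(records, outcome,
                         covariates = DEFAULT_COVARIATES,
                         drought = c("category", "binary")) {
  drought <- match.arg(drought)
  if (!outcome %in% IPV_OUTCOMES) {
    stop("outcome must be one of: ", paste(IPV_OUTCOMES, collapse = ", "))
  }
  dcol <- if (drought == "category") "drought_category" else "drought_binary"
  used <- c(outcome, covariates, dcol, "survey_id", "latitude", "longitude")
  miss <- setdiff(used, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  cc <- complete.cases(records[used])
  if (!all(cc)) {
    warning(sprintf("dropping %d rows with missing values", sum(!cc)))
    records <- records[cc, , drop = FALSE]
  }
  n <- nrow(records)
  y <- as.numeric(records[[outcome]])
  stopifnot(all(y %in% c(0, 1)))

  cols <- list(`(Intercept)` = rep(1, n))
  refs <- character(0)
  for (v in covariates) {
    x <- records[[v]]
    if (is.factor(x)) {
      # reference = first *observed* level; an empty reference level would
      # make the remaining dummies sum to the intercept
      present <- levels(x)[tabulate(x, nbins = nlevels(x)) > 0]
      if (length(present) == 0L) next
      if (present[1] != levels(x)[1]) {
        warning(sprintf("covariate '%s': reference level '%s' absent; using '%s'",
                        v, levels(x)[1], present[1]))
      }
      refs[v] <- present[1]
      for (lev in present[-1]) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(x == lev)
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  drought_cols <- character(0)
  if (drought == "category") {
    x <- records$drought_category
    for (lev in c("moderate", "severe", "extreme")) {
      nm <- paste0("drought=", lev)
      cols[[nm]] <- as.numeric(x == lev)
      drought_cols <- c(drought_cols, nm)
    }
  } else {
    cols[["drought"]] <- as.numeric(records$drought_binary == "drought")
    drought_cols <- "drought"
  }
  sids <- sort(unique(records$survey_id))
  for (s in sids[-1]) {
    cols[[paste0("survey=", s)]] <- as.numeric(records$survey_id == s)
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col)
    length(unique(col)) > 1L))
  if (!all(keep)) {
    dropped <- colnames(X)[!keep]
    warning("dropping constant (unidentifiable) columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    drought_cols <- intersect(drought_cols, colnames(X))
  } else {
    dropped <- character(0)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient after reference-level drops")
  }
  structure(
    list(y = y, X = X, coords = cbind(lat = records$latitude,
                                      lon = records$longitude),
         outcome = outcome, drought = drought, drought_cols = drought_cols,
         dropped = dropped,
         references = c(refs,
                        drought = if (drought == "category") "none" else
                          "normal",
                        survey = as.character(sids[1]))),
    class = "ipv_design")
}

#' @export
print.ipv_design <- function(x, ...) {
  cat(sprintf("ipv_design: outcome '%s', n = %d, %d fixed columns (%s drought)\n",
              x$outcome, length(x$y), ncol(x$X), x$drought))
  invisible(x)
}
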