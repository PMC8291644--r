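# Moran's I with on-the-fly spatial weights. The n x n weights matrix is
# never built: the C++ kernel recomputes each row block's weights from the
# coordinates, so peak auxiliary memory is O(block_size * n).

#' Specify a spatial weighting scheme
#'
#' Default: row-standardized inverse great-circle distance with a 100 km
#' distance band (weight zero beyond the band). Survey clusters share exact
#' coordinates, so off-diagonal distances of zero are floored at
#' `min_dist_km` (1 km) under inverse distance — without the floor those
#' weights would be infinite.
#'
#' @param scheme `"inverse_distance"`, `"k_nearest"` or `"distance_band"`.
#' @param cutoff_km Band radius in km (inverse_distance, distance_band).
#' @param k Number of neighbours (k_nearest); ties broken by lower index.
#' @param row_standardize Divide each row by its sum?
#' @param min_dist_km Distance floor for inverse-distance weights.
#' @param coords Optional default `n x 2` coordinate matrix (lat, lon);
#'   functions taking a `weight_spec` also accept coordinates directly.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(scheme = c("inverse_distance", "k_nearest",
                                   "distance_band"),
                        cutoff_km = 100, k = 10L, row_standardize = TRUE,
                        min_dist_km = 1, coords = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(cutoff_km > 0, k >= 1, min_dist_km > 0)
  structure(list(scheme = scheme, cutoff_km = cutoff_km, k = as.integer(k),
                 row_standardize = isTRUE(row_standardize),
                 min_dist_km = min_dist_km, coords = coords),
            class = "weight_spec")
}

#' @export
print.weight_spec <- function(x, ...) {
  par <- if (x$scheme == "k_nearest") sprintf("k = %d", x$k) else
    sprintf("band = %g km", x$cutoff_km)
  cat(sprintf("weight_spec: %s (%s), %srow-standardized, floor %g km\n",
              x$scheme, par, if (x$row_standardize) "" else "not ",
              x$min_dist_km))
  invisible(x)
}

scheme_code <- function(spec) {
  match(spec$scheme, c("inverse_distance", "k_nearest", "distance_band")) - 1L
}

resolve_coords <- function(spec, coords) {
  if (is.null(coords)) coords <- spec$coords
  if (is.null(coords)) stop("coordinates required (in the spec or directly)")
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  coords
}

moran_core <- function(values, spec, coords, block_size) {
  coords <- resolve_coords(spec, coords)
  n <- length(values)
  if (nrow(coords) != n) stop("values and coordinates differ in length")
  if (n < 3) stop("Moran's I requires at least 3 observations")
  z <- values - mean(values)
  if (all(z == 0)) stop("Moran's I is undefined for constant values")
  st <- moran_stream_cpp(z, coords[, 1], coords[, 2], scheme_code(spec),
                         spec$cutoff_km, spec$k, spec$row_standardize,
                         spec$min_dist_km, as.integer(block_size))
  if (st$S0 <= 0) stop("all spatial weights are zero under this spec")
  m2 <- sum(z^2)
  list(I = (n / st$S0) * st$num / m2, S0 = st$S0, S1 = st$S1, S2 = st$S2,
       z = z, n = n)
}

#' Moran's I statistic with streamed weights
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = values - mean(values)`; weights are recomputed from coordinates in
#' row blocks of at most `block_size` rows, and the result is independent of
#' `block_size`.
#'
#' @param values Numeric vector (e.g. model residuals), not all equal,
#'   length >= 3.
#' @param spec A [weight_spec()].
#' @param coords Optional `n x 2` (lat, lon) matrix overriding
#'   `spec$coords`.
#' @param block_size Rows per weight block.
#' @return The statistic (numeric scalar).
#' @export
moran_statistic <- function(values, spec = weight_spec(), coords = NULL,
                            block_size = 512L) {
  moran_core(values, spec, coords, block_size)$I
}

#' Randomization moments of Moran's I
#'
#' `E[I] = -1/(n-1)`; the variance is the classical randomization
#' (permutation) variance from `S0`, `S1`, `S2` and the sample kurtosis of
#' the centred values, with the weight sums accumulated blockwise.
#'
#' @inheritParams moran_statistic
#' @return List with `expectation` and `variance`.
#' @export
moran_moments <- function(values, spec = weight_spec(), coords = NULL,
                          block_size = 512L) {
  st <- moran_core(values, spec, coords, block_size)
  list(expectation = -1 / (st$n - 1),
       variance = moran_var_from_sums(st$z, st$n, st$S0, st$S1, st$S2))
}

moran_var_from_sums <- function(z, n, S0, S1, S2) {
  b2 <- n * sum(z^4) / sum(z^2)^2
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - 1 / (n - 1)^2
}

#' Moran's I test
#'
#' Analytic method: `z = (I - E[I]) / sqrt(Var[I])` with the randomization
#' variance and a two-sided normal p-value. Permutation method: seeded label
#' shuffles, `p = (1 + #\{|I_perm - E| >= |I_obs - E|\}) / (B + 1)`.
#'
#' @inheritParams moran_statistic
#' @param method `"analytic"` or `"permutation"`.
#' @param n_permutations Number of shuffles `B` (>= 99) for the permutation
#'   method.
#' @param seed Seed for the shuffles.
#' @return An object of class `moran_result`: `I`, `expectation`,
#'   `variance`, `z`, `p_value`, `method`, `n_permutations`, `spec`.
#' @export
moran_test <- function(values, spec = weight_spec(), coords = NULL,
                       method = c("analytic", "permutation"),
                       n_permutations = 999L, seed = 1L, block_size = 512L) {
  method <- match.arg(method)
  coords <- resolve_coords(spec, coords)
  st <- moran_core(values, spec, coords, block_size)
  e <- -1 / (st$n - 1)
  v <- moran_var_from_sums(st$z, st$n, st$S0, st$S1, st$S2)
  zstat <- (st$I - e) / sqrt(v)
  if (method == "analytic") {
    p <- 2 * pnorm(-abs(zstat))
    B <- NA_integer_
  } else {
    if (n_permutations < 99) stop("permutation method needs >= 99 shuffles")
    B <- as.integer(n_permutations)
    Z <- with_seed(seed, vapply(seq_len(B), function(b) sample(st$z),
                                numeric(st$n)))
    nums <- moran_num_multi_cpp(Z, coords[, 1], coords[, 2],
                                scheme_code(spec), spec$cutoff_km, spec$k,
                                spec$row_standardize, spec$min_dist_km)
    Iperm <- (st$n / st$S0) * nums / sum(st$z^2)
    p <- (1 + sum(abs(Iperm - e) >= abs(st$I - e))) / (B + 1)
  }
  structure(list(I = st$I, expectation = e, variance = v, z = zstat,
                 p_value = p, method = method, n_permutations = B,
                 S0 = st$S0, S1 = st$S1, S2 = st$S2, n = st$n,
                 spec = spec[c("scheme", "cutoff_km", "k", "row_standardize",
                               "min_dist_km")]),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E = %.4f, sd = %.4f), %s p = %.4g\n",
              x$I, x$expectation, sqrt(x$variance), x$method, x$p_value))
  invisible(x)
}
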