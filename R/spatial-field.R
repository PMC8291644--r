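#' Draw a Gaussian random field with exponential covariance
#'
#' Samples a zero-mean Gaussian random field at the supplied coordinates with
#' covariance `sd^2 * exp(-d / range_km)`, `d` the great-circle distance in
#' km. This is the generator-side latent confounder: a single-parameter field
#' that is smooth at cluster scale. The dense covariance is factorized by an
#' eigendecomposition (negative eigenvalues from round-off clipped at zero),
#' so coincident coordinates receive exactly proportional rows and hence
#' identical draws.
#'
#' @param lat,lon Coordinate vectors in degrees.
#' @param sd Marginal standard deviation; `sd = 0` returns zeros.
#' @param range_km Correlation length in km (> 0).
#' @param seed Optional integer seed.
#' @param n_draws Number of independent field draws.
#' @return A vector of length `n` (if `n_draws = 1`) or an `n x n_draws`
#'   matrix.
#' @export
sample_spatial_field <- function(lat, lon, sd, range_km, seed = NULL,
                                 n_draws = 1L) {
  n <- length(lat)
  stopifnot(length(lon) == n, n >= 1)
  if (range_km <= 0) stop("range_km must be positive")
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    out <- matrix(0, n, n_draws)
    return(if (n_draws == 1L) out[, 1] else out)
  }
  D <- gc_dist_matrix(lat, lon)
  C <- sd^2 * exp(-D / range_km)
  ee <- eigen(C, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), n)
  out <- with_seed(seed, L %*% matrix(rnorm(n * n_draws), n, n_draws))
  if (n_draws == 1L) out[, 1] else out
}
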