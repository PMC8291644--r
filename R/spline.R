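# Low-rank thin-plate spline smoother on the sphere: radial basis functions
# of chord distance, eta(c) = c^2 log(c), centred at knots placed by
# k-means on the unit-sphere embedding of the distinct cluster locations.
# This is the standard knot-based approximation to a full thin-plate spline;
# the Gram matrix of eta at the knots plays the role of the roughness
# penalty.

#' Place spline knots by spherical k-means
#'
#' Knots are chosen by k-means on the unit-sphere embedding of the distinct
#' coordinate points, with centroids projected back to the sphere.
#' Deterministic under `seed`. `K = 0` returns an empty knot set (the model
#' then reduces to a plain logistic regression); `K` equal to the number of
#' distinct points returns those points.
#'
#' @param lat,lon Coordinate vectors in degrees (typically cluster
#'   locations, duplicates allowed).
#' @param K Number of knots (`0 <= K <=` number of distinct points).
#' @param seed Integer seed for the k-means initialisation.
#' @return `K x 2` matrix with columns `lat`, `lon`.
#' @export
make_knots <- function(lat, lon, K, seed = 1L) {
  pts <- unique(cbind(lat = as.numeric(lat), lon = as.numeric(lon)))
  nd <- nrow(pts)
  if (K > nd) {
    stop(sprintf(
      "K = %d exceeds the %d distinct coordinate points; choose a smaller K",
      K, nd))
  }
  if (K == 0L) return(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("lat", "lon"))))
  if (K == nd) return(pts)
  emb <- sphere_embed(pts[, 1], pts[, 2])
  centers <- with_seed(seed, {
    km <- tryCatch(
      kmeans(emb, centers = K, iter.max = 100L, nstart = 3L),
      error = function(e) NULL)
    if (is.null(km)) emb[sample.int(nd, K), , drop = FALSE] else km$centers
  })
  knots <- sphere_unembed(centers)
  colnames(knots) <- c("lat", "lon")
  knots
}

# Thin-plate radial function of chord distance, eta(0) = 0.
tps_eta <- function(c) {
  out <- numeric(length(c))
  pos <- c > 0
  out[pos] <- c[pos]^2 * log(c[pos])
  dim(out) <- dim(c)
  out
}

#' Evaluate the low-rank thin-plate spline basis and its penalty
#'
#' `basis[i, j] = eta(c_ij)` with `c_ij` the unit-sphere chord distance
#' between observation i and knot j and `eta(c) = c^2 log(c)` (`eta(0) = 0`).
#' `penalty` is the Gram matrix of `eta` at the knots — the roughness
#' penalty of the knot-based thin-plate approximation. Because `eta` is only
#' conditionally positive definite, the raw Gram matrix is indefinite
#' (trace zero); `penalty_fit` is the eigenvalue-clipped positive part plus
#' a small relative ridge, and is what the fitter penalizes so that the
#' whole spline term vanishes in the large-lambda limit.
#'
#' @param lat,lon Observation coordinates in degrees.
#' @param knots Knot matrix from [make_knots()] (at least 1 knot, no
#'   duplicates).
#' @return An object of class `spline_basis`: list with `knots`, `basis`
#'   (n x K), `penalty` (raw Gram, K x K), `penalty_fit` (PSD, K x K).
#' @export
spline_basis <- function(lat, lon, knots) {
  stopifnot(is.matrix(knots), ncol(knots) == 2)
  K <- nrow(knots)
  if (K < 1) stop("at least one knot is required")
  kd <- chord_dist_matrix(knots[, 1], knots[, 2])
  if (any(kd[upper.tri(kd)] < 1e-10)) stop("duplicate knots")
  B <- tps_eta(chord_dist_matrix(lat, lon, knots[, 1], knots[, 2]))
  S <- tps_eta(kd)
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  ridge <- 1e-6 * mean(abs(ee$values))
  Sfit <- ee$vectors %*% (pmax(ee$values, 0) * t(ee$vectors))
  Sfit <- (Sfit + t(Sfit)) / 2 + diag(ridge, K)
  structure(list(knots = knots, basis = B, penalty = S, penalty_fit = Sfit),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("spline_basis: %d knots, %d observations\n",
              nrow(x$knots), nrow(x$basis)))
  invisible(x)
}
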