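# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive dense / loop implementations, sharing no code with
# the package internals they check.

EARTH_KM <- 6371.0088

hav_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * EARTH_KM * asin(sqrt(pmin(pmax(a, 0), 1)))
}

# Dense spatial weights matrix for a weight_spec-like list.
dense_weights <- function(coords, spec) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- hav_km(coords[i, 1], coords[i, 2], coords[, 1], coords[, 2])
  }
  A <- matrix(0, n, n)
  if (spec$scheme == "inverse_distance") {
    A <- ifelse(D <= spec$cutoff_km, 1 / pmax(D, spec$min_dist_km), 0)
  } else if (spec$scheme == "distance_band") {
    A <- ifelse(D <= spec$cutoff_km, 1, 0)
  } else if (spec$scheme == "k_nearest") {
    for (i in seq_len(n)) {
      ord <- order(D[i, -i], (seq_len(n))[-i])
      nb <- ((seq_len(n))[-i])[ord][seq_len(spec$k)]
      A[i, nb] <- 1
    }
  }
  diag(A) <- 0
  if (spec$row_standardize) {
    rs <- rowSums(A)
    A <- A / ifelse(rs > 0, rs, 1)
    A[rowSums(A) == 0, ] <- 0
  }
  A
}

# Dense-matrix Moran's I with the classical randomization moments.
dense_moran <- function(values, coords, spec) {
  W <- dense_weights(coords, spec)
  n <- length(values)
  z <- values - mean(values)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  I <- (n / S0) * sum(W * outer(z, z)) / sum(z^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  EI <- -1 / (n - 1)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
         b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  list(I = I, S0 = S0, S1 = S1, S2 = S2, expectation = EI, variance = VI)
}

# Plain Newton-Raphson logistic MLE (no penalty, no reweighting shortcuts).
newton_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(g)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  list(beta = beta, deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# Random coordinates in a small region (degrees).
rand_coords <- function(n, lat0 = 0, lon0 = 30, span = 3) {
  cbind(lat = runif(n, lat0, lat0 + span), lon = runif(n, lon0, lon0 + span))
}
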