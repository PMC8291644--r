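# Geodesy helpers shared by the generator, the spline basis and the Moran
# weights. All user-facing coordinates are decimal degrees (WGS84-like
# spherical earth); distances are great-circle km on a sphere of mean radius.

EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * (pi / 180)

#' Great-circle distance in kilometres (haversine)
#'
#' Vectorised over the first pair of coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @keywords internal
gc_dist_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Pairwise great-circle distance matrix (km) between two coordinate sets.
gc_dist_matrix <- function(lat1, lon1, lat2 = lat1, lon2 = lon1) {
  e1 <- sphere_embed(lat1, lon1)
  e2 <- sphere_embed(lat2, lon2)
  ct <- tcrossprod(e1, e2)
  ct <- pmin(pmax(ct, -1), 1)
  EARTH_RADIUS_KM * acos(ct)
}

# Embed (lat, lon) degrees on the unit sphere as (x, y, z) rows.
sphere_embed <- function(lat, lon) {
  phi <- deg2rad(lat)
  lam <- deg2rad(lon)
  cbind(x = cos(phi) * cos(lam), y = cos(phi) * sin(lam), z = sin(phi))
}

# Inverse of sphere_embed; rows need not be exactly unit norm.
sphere_unembed <- function(xyz) {
  nrm <- sqrt(rowSums(xyz^2))
  xyz <- xyz / nrm
  cbind(lat = asin(pmin(pmax(xyz[, 3], -1), 1)) * 180 / pi,
        lon = atan2(xyz[, 2], xyz[, 1]) * 180 / pi)
}

# Chord distances on the unit sphere between two coordinate sets.
chord_dist_matrix <- function(lat1, lon1, lat2 = lat1, lon2 = lon1) {
  e1 <- sphere_embed(lat1, lon1)
  e2 <- sphere_embed(lat2, lon2)
  ct <- tcrossprod(e1, e2)
  d2 <- pmax(2 - 2 * ct, 0)
  sqrt(d2)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one integer seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
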