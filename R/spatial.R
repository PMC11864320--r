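# Inverse-squared-distance spatial weights with a distance cutoff, spatial
# lags, and Moran's I with permutation inference.

#' Great-circle (haversine) distance in kilometres
#'
#' Spherical-earth distance with radius 6371 km. All package distances use
#' this formula so that the 660 km neighbourhood cutoff is reproducible.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in WGS84 decimal degrees
#'   (vectorized, recycled).
#' @return distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

.fc_pairwise_km <- function(lon, lat) {
  r <- 6371
  to_rad <- pi / 180
  phi <- lat * to_rad
  lam <- lon * to_rad
  cphi <- cos(phi)
  # haversine form: numerically stable at short range, unlike acos
  a <- sin(outer(phi, phi, "-") / 2)^2 +
    outer(cphi, cphi) * sin(outer(lam, lam, "-") / 2)^2
  d <- 2 * r * asin(pmin(sqrt(a), 1)) # pmin arg order keeps the dim attrs
  diag(d) <- 0
  d
}

#' Build inverse-squared-distance spatial weights
#'
#' Edges connect every pair of units closer than `cutoff_km` (great-circle
#' distance), with raw weight `w_ij = 1 / d_ij^2`, `d` in km. Weights are
#' symmetric, there are no self-neighbours, and pairs at or beyond the
#' cutoff share no edge.
#'
#' @param coords two-column matrix or data frame of (lon, lat) in decimal
#'   degrees; row order defines the unit order.
#' @param cutoff_km neighbourhood distance cutoff in km.
#' @param ids optional unit identifiers (default `1..n` as character).
#' @return an object of class `spatial_weights`: list with `ids`, `coords`,
#'   `w` (sparse symmetric matrix of raw weights), `cutoff_km`, and
#'   `w_total` (sum of all ordered-pair weights).
#' @export
build_weights <- function(coords, cutoff_km = 660, ids = NULL) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 locations")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (anyDuplicated(coords)) {
    stop("duplicate coordinates: inverse-squared-distance weight is infinite")
  }
  d <- .fc_pairwise_km(coords[, 1], coords[, 2])
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate coordinates: inverse-squared-distance weight is infinite")
  }
  keep <- d > 0 & d < cutoff_km
  w <- matrix(0, n, n)
  w[keep] <- 1 / d[keep]^2
  w <- Matrix::Matrix(w, sparse = TRUE)
  if (all(w == 0)) {
    warning("all units are isolated at this cutoff", call. = FALSE)
  }
  out <- list(ids = ids, coords = coords, w = w, cutoff_km = cutoff_km,
              w_total = sum(w), cache = new.env(parent = emptyenv()))
  class(out) <- "spatial_weights"
  out
}

#' @export
print.spatial_weights <- function(x, ...) {
  n <- length(x$ids)
  nn <- Matrix::nnzero(x$w)
  cat(sprintf(
    "<spatial_weights: %d units, %d directed edges, cutoff %g km, W = %g>\n",
    n, nn, x$cutoff_km, x$w_total))
  invisible(x)
}

#' Spatial lag of a variable
#'
#' Row-standardized by default: `lag_i = sum_j w_ij x_j / sum_j w_ij`, the
#' inverse-squared-distance weighted mean over the neighbours within the
#' cutoff. With `row_standardize = FALSE` the raw weighted sum is returned.
#' Units without neighbours get lag 0 with a warning.
#'
#' @param values numeric vector aligned with the weights' unit order.
#' @param weights a [build_weights()] object.
#' @param row_standardize logical.
#' @return numeric vector of lagged values.
#' @export
spatial_lag <- function(values, weights, row_standardize = TRUE) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(weights$ids)
  if (length(values) != n) stop("values length does not match unit count")
  num <- as.numeric(weights$w %*% values)
  if (!row_standardize) return(num)
  rs <- Matrix::rowSums(weights$w)
  iso <- rs == 0
  if (any(iso)) {
    warning(sprintf("%d isolated unit(s): lag set to 0", sum(iso)),
            call. = FALSE)
  }
  out <- numeric(n)
  out[!iso] <- num[!iso] / rs[!iso]
  out
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W` the sum of all weights.
#'
#' @param values numeric vector aligned with the weights.
#' @param weights a [build_weights()] object.
#' @return the statistic.
#' @export
morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(weights$ids)
  if (length(values) != n) stop("values length does not match unit count")
  if (n < 3) stop("need at least 3 units")
  if (weights$w_total == 0) stop("weights have no edges")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("Moran's I undefined: zero variance")
  (n / weights$w_total) * as.numeric(z %*% (weights$w %*% z)) / ss
}

#' Moran's I permutation test
#'
#' Two-sided permutation inference: the observed statistic is compared with
#' `n_perm` random relabelings of the values over the units, and
#' `p = (1 + #{|I*| >= |I_obs|}) / (n_perm + 1)`. Reproducible for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param values numeric vector aligned with the weights.
#' @param weights a [build_weights()] object.
#' @param n_perm number of permutations (`>= 99`).
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
morans_i_test <- function(values, weights, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  i_obs <- morans_i(values, weights)
  n <- length(values)
  z <- values - mean(values)
  ss <- sum(z^2)
  scale <- n / weights$w_total / ss
  perm_stats <- .fc_with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      zp <- z[sample.int(n)]
      scale * as.numeric(zp %*% (weights$w %*% zp))
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_stats) >= abs(i_obs))) / (n_perm + 1)
  list(statistic = i_obs, p_value = p, n_perm = n_perm)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.fc_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Export / import spatial weights as an edge list
#'
#' One row per unordered neighbour pair: `i`, `j` (unit ids), the
#' great-circle distance in km and the raw weight `1/d^2`.
#'
#' @param weights a [build_weights()] object.
#' @return a data frame (`weights_to_edges`); `write_weights` /
#'   `read_weights` round-trip it through CSV (`read_weights` needs the
#'   original coordinates to rebuild the object).
#' @export
weights_to_edges <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  tw <- Matrix::triu(weights$w)
  sm <- methods::as(methods::as(tw, "generalMatrix"), "TsparseMatrix")
  ord <- order(sm@i, sm@j)
  data.frame(
    i = weights$ids[sm@i[ord] + 1L],
    j = weights$ids[sm@j[ord] + 1L],
    distance_km = 1 / sqrt(sm@x[ord]),
    weight = sm@x[ord],
    stringsAsFactors = FALSE
  )
}

#' @rdname weights_to_edges
#' @param path CSV path.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(weights_to_edges(weights), path, row.names = FALSE)
  invisible(path)
}
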