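# Synthetic landscape generator. Emulates the statistical structure of
# national forest-inventory plot data: spatially autocorrelated climate
# surfaces, clustered federal ownership, right-skewed biomass, a ~7%
# spatially clustered fire incidence, and a zero-inflated mortality
# fraction on burned plots. Construction: independent Gaussian random
# fields (exponential covariance, simulated on a coarse grid and bilinearly
# interpolated) plus a white-noise nugget give one standardized latent per
# variable; a Gaussian copula (Cholesky mixing of an attenuation-adjusted
# latent correlation matrix) imposes the cross-variable correlations; each
# latent is then pushed through its marginal transform.

#' Calibration profile for the synthetic landscape
#'
#' Default targets reproduce the descriptive statistics of the emulated
#' inventory: marginal means/SDs per variable, the quoted pairwise Pearson
#' correlations, the latent-field spatial range, and the domain bounding
#' box (roughly 1000 x 1000 km so a 660 km cutoff yields non-trivial
#' neighbour structure).
#'
#' @param ... named overrides of the default fields (`means`, `sds`,
#'   `correlations`, `spatial_range_km`, `nugget`, `bbox`,
#'   `fire_rate`, `own_rate`, `treeloss_zero_prob`, `diurnal_range_c`,
#'   `grid_n`).
#' @return an object of class `calibration_profile`.
#' @export
calibration_profile <- function(...) {
  prof <- list(
    means = c(PPT = 82.00, TEMP = 25.09, ET = 405, PPTs = 87.28,
              TEMPs = 12.08, ETs = 220, AGBIO = 26.82, AGE = 65.24,
              TREELOSS = 0.23),
    sds = c(PPT = 33.13, TEMP = 4.52, ET = 69, PPTs = 50.41,
            TEMPs = 6.56, ETs = 72, AGBIO = 30.80, AGE = 55.40,
            TREELOSS = 0.36),
    fire_rate = 0.07,
    own_rate = 0.25,
    # quoted pairwise Pearson correlation targets; untargeted pairs stay 0
    correlations = data.frame(
      v1 = c("TEMP", "ET", "TEMP", "AGBIO", "AGE", "OWN", "AGE", "OWN"),
      v2 = c("TEMPs", "TEMPs", "ET", "PPTs", "AGBIO", "AGE", "TEMP",
             "TEMPs"),
      target = c(0.95, 0.69, 0.65, 0.40, 0.39, 0.33, -0.32, -0.39),
      stringsAsFactors = FALSE
    ),
    spatial_range_km = 150,
    nugget = 0.3,
    bbox = c(lon_min = -110.0, lon_max = -98.3,
             lat_min = 37.0, lat_max = 46.0),
    treeloss_zero_prob = 0.45,
    diurnal_range_c = 11,
    grid_n = 40
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(prof))
  if (length(unknown)) stop("unknown profile field(s): ",
                            paste(unknown, collapse = ", "))
  prof[names(override)] <- override
  stopifnot(all(prof$sds > 0),
            all(abs(prof$correlations$target) <= 1),
            prof$spatial_range_km > 0,
            prof$nugget >= 0, prof$nugget < 1)
  class(prof) <- "calibration_profile"
  prof
}

# Simulate k independent unit-variance exponential-covariance Gaussian
# random fields at coords, via Cholesky on a regular grid + bilinear
# interpolation. Each interpolated field is re-standardized empirically.
.fc_grf <- function(k, lon, lat, bbox, range_km, grid_n) {
  gx <- seq(bbox["lon_min"], bbox["lon_max"], length.out = grid_n)
  gy <- seq(bbox["lat_min"], bbox["lat_max"], length.out = grid_n)
  gcoords <- cbind(lon = rep(gx, times = grid_n),
                   lat = rep(gy, each = grid_n))
  d <- .fc_pairwise_km(gcoords[, 1], gcoords[, 2])
  cv <- exp(-d / range_km)
  diag(cv) <- diag(cv) + 1e-8
  u <- chol(cv)
  zg <- crossprod(u, matrix(rnorm(nrow(gcoords) * k), nrow(gcoords), k))
  # bilinear interpolation from the grid to the plot coordinates
  ix <- pmin(pmax(findInterval(lon, gx), 1), grid_n - 1)
  iy <- pmin(pmax(findInterval(lat, gy), 1), grid_n - 1)
  tx <- (lon - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (lat - gy[iy]) / (gy[iy + 1] - gy[iy])
  idx <- function(i, j) (j - 1L) * grid_n + i
  f <- zg[idx(ix, iy), , drop = FALSE] * (1 - tx) * (1 - ty) +
    zg[idx(ix + 1L, iy), , drop = FALSE] * tx * (1 - ty) +
    zg[idx(ix, iy + 1L), , drop = FALSE] * (1 - tx) * ty +
    zg[idx(ix + 1L, iy + 1L), , drop = FALSE] * tx * ty
  scale(f) # interpolation shrinks variance between knots; re-standardize
}

# Pearson correlation of (g1(Z1), g2(Z2)) for bivariate-normal latents with
# correlation rho, evaluated on an equiprobable product grid.
.fc_pearson_from_latent <- function(g1, g2, rho, m = 400) {
  z <- qnorm((seq_len(m) - 0.5) / m)
  x1 <- g1(z)
  mu1 <- mean(x1); s1 <- sqrt(mean((x1 - mu1)^2))
  x2m <- g2(z) # for marginal moments
  mu2 <- mean(x2m); s2 <- sqrt(mean((x2m - mu2)^2))
  if (s1 == 0 || s2 == 0) return(0)
  zz <- outer(rho * z, sqrt(1 - rho^2) * z, "+")
  exy <- mean(x1 * rowMeans(matrix(g2(zz), m, m)))
  (exy - mu1 * mu2) / (s1 * s2)
}

# Latent correlation achieving a target Pearson correlation between the two
# transformed marginals (inverse of .fc_pearson_from_latent by bisection).
.fc_latent_corr <- function(g1, g2, target) {
  f <- function(rho) .fc_pearson_from_latent(g1, g2, rho) - target
  lo <- -0.999; hi <- 0.999
  if (f(hi) < 0) return(hi)
  if (f(lo) > 0) return(lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}

# Positive-semidefinite completion with fixed entries: alternating
# projections between the PSD cone and the affine set that pins the
# targeted entries and the unit diagonal, leaving untargeted entries free
# to move off zero. Falls back to a plain eigenvalue-clipped repair if the
# completion does not converge.
.fc_psd_complete <- function(r, fixed) {
  x <- r
  for (it in seq_len(500)) {
    e <- eigen(x, symmetric = TRUE)
    if (min(e$values) > 1e-7 && max(abs(x[fixed] - r[fixed])) < 1e-8) {
      return(list(r = x, repaired = it > 1, deviation = 0))
    }
    x <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
    x[fixed] <- r[fixed]
    diag(x) <- 1
    x <- (x + t(x)) / 2
  }
  e <- eigen(x, symmetric = TRUE)
  x <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
  d <- sqrt(diag(x))
  x <- x / tcrossprod(d)
  dev <- max(abs(x[fixed] - r[fixed]))
  if (dev > 0.05) {
    stop(sprintf(
      "correlation targets infeasible: max deviation %.3f after repair", dev))
  }
  list(r = x, repaired = TRUE, deviation = dev)
}

#' Generate a synthetic plot table
#'
#' Draws `n` plots at uniform random coordinates in the profile's bounding
#' box and fills in the full plot-table schema: terrain, clustered
#' ownership, stand age and aboveground biomass (gamma and lognormal
#' marginals), the six seasonal climate covariates, monthly climate normals
#' back-filled so that re-aggregating the monthly precipitation and maximum
#' temperature reproduces the seasonal values exactly, a spatially
#' clustered binary fire outcome thresholded at the target incidence, and a
#' zero-inflated Beta mortality fraction on burned plots. County
#' identifiers are a regular spatial partition and ecoregions a two-class
#' threshold of an independent latent field, so counties can straddle
#' ecoregion boundaries. Deterministic for a fixed seed.
#'
#' @param n number of plots (`>= 10`).
#' @param profile a [calibration_profile()].
#' @param seed integer seed.
#' @param config an [run_config()]; supplies the bole/other biomass split.
#' @return a plot-table `data.frame` (see [read_plot_table()]) with the
#'   seasonal covariate columns appended.
#' @export
generate_plots <- function(n, profile = calibration_profile(), seed = 1L,
                           config = run_config()) {
  if (n < 10) stop("n must be >= 10")
  .fc_with_seed(seed, .fc_generate_plots_impl(n, profile, config))
}

.fc_generate_plots_impl <- function(n, profile, config) {
  bb <- profile$bbox
  # quasi-systematic sampling design: one plot placed uniformly at random
  # within each cell of a regular grid (emulating a national inventory's
  # spatial sampling intensity, and bounding the minimum pair distance so
  # inverse-squared-distance weights are not dominated by near-duplicates)
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  cells <- sample(nx * ny, n)
  cx <- (cells - 1) %% nx
  cy <- (cells - 1) %/% nx
  dx <- (bb["lon_max"] - bb["lon_min"]) / nx
  dy <- (bb["lat_max"] - bb["lat_min"]) / ny
  lon <- bb["lon_min"] + (cx + runif(n)) * dx
  lat <- bb["lat_min"] + (cy + runif(n)) * dy

  vars <- c("PPT", "TEMP", "ET", "PPTs", "TEMPs", "ETs",
            "AGBIO", "AGE", "OWN", "FIRE")
  k <- length(vars)

  # marginal transforms (standard normal latent -> variable scale)
  mu <- profile$means; sg <- profile$sds
  lnorm_pars <- function(m, s) {
    m <- unname(m); s <- unname(s)
    s2 <- log(1 + (s / m)^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  agb <- lnorm_pars(mu["AGBIO"], sg["AGBIO"])
  age_shape <- (mu["AGE"] / sg["AGE"])^2
  age_scale <- sg["AGE"]^2 / mu["AGE"]
  transforms <- list(
    PPT = function(z) pmax(mu["PPT"] + sg["PPT"] * z, 0),
    TEMP = function(z) mu["TEMP"] + sg["TEMP"] * z,
    ET = function(z) pmax(mu["ET"] + sg["ET"] * z, 0),
    PPTs = function(z) pmax(mu["PPTs"] + sg["PPTs"] * z, 0),
    TEMPs = function(z) mu["TEMPs"] + sg["TEMPs"] * z,
    ETs = function(z) pmax(mu["ETs"] + sg["ETs"] * z, 0),
    AGBIO = function(z) exp(agb["meanlog"] + agb["sdlog"] * z),
    AGE = function(z) qgamma(pnorm(z), shape = age_shape, scale = age_scale),
    OWN = function(z) as.numeric(z > qnorm(1 - profile$own_rate)),
    FIRE = function(z) as.numeric(z > qnorm(1 - profile$fire_rate))
  )

  # latent correlation matrix: each targeted pair is inverted through the
  # two marginal transforms (Gaussian-copula calibration), then the matrix
  # is completed to PSD holding the targeted entries fixed
  r <- diag(k)
  dimnames(r) <- list(vars, vars)
  fixed <- diag(TRUE, k)
  dimnames(fixed) <- list(vars, vars)
  for (i in seq_len(nrow(profile$correlations))) {
    p <- profile$correlations[i, ]
    val <- .fc_latent_corr(transforms[[p$v1]], transforms[[p$v2]], p$target)
    r[p$v1, p$v2] <- r[p$v2, p$v1] <- val
    fixed[p$v1, p$v2] <- fixed[p$v2, p$v1] <- TRUE
  }
  comp <- .fc_psd_complete(r, fixed)
  if (comp$repaired) {
    message("latent correlation matrix completed to PSD ",
            sprintf("(max target deviation %.2g)", comp$deviation))
  }
  mix <- chol(comp$r + diag(1e-8, k))

  # one independent spatial latent per variable (+1 for ecoregions), mixed
  # through the copula correlation
  f <- .fc_grf(k + 1, lon, lat, bb, profile$spatial_range_km, profile$grid_n)
  eco_field <- f[, k + 1]
  nug <- profile$nugget
  lat_f <- sqrt(1 - nug) * f[, seq_len(k)] +
    sqrt(nug) * matrix(rnorm(n * k), n, k)
  # empirically whiten the latent matrix before mixing: the spatial fields'
  # finite-domain correlation noise (~0.05 even at n = 50,000) would
  # otherwise leak into every cross-correlation; after whitening the
  # realized latent correlation equals the calibrated matrix exactly
  lat_f <- sweep(lat_f, 2, colMeans(lat_f))
  lat_f <- lat_f %*% backsolve(chol(crossprod(lat_f) / n),
                               diag(ncol(lat_f)))
  z <- lat_f %*% mix
  colnames(z) <- vars

  out <- data.frame(plot_id = sprintf("P%06d", seq_len(n)),
                    lon = lon, lat = lat, stringsAsFactors = FALSE)
  for (v in setdiff(vars, c("OWN", "FIRE"))) out[[v]] <- transforms[[v]](z[, v])
  # binary fields: threshold at the realized empirical quantile so the
  # sample incidence is calibrated to the target rate
  out$OWN <- as.numeric(z[, "OWN"] > quantile(z[, "OWN"],
                                              1 - profile$own_rate))
  out$FIRE <- as.numeric(z[, "FIRE"] > quantile(z[, "FIRE"],
                                                1 - profile$fire_rate))

  # terrain: elevation follows the ecoregion latent; slope/aspect uniform
  out$elevation <- pmax(0, 800 + 400 * eco_field)
  out$slope <- runif(n, 0, 30)
  out$aspect <- runif(n, 0, 360)

  # administrative units: ~1 degree county cells; 2-class ecoregions
  cellx <- floor((lon - bb["lon_min"]) / 1.17)
  celly <- floor((lat - bb["lat_min"]) / 0.9)
  out$county_id <- sprintf("C%02d%02d", cellx, celly)
  out$ecoregion_id <- ifelse(eco_field > stats::median(eco_field),
                             "E1", "E2")

  # biomass pools
  out$Bb <- config$bb_fraction * out$AGBIO
  out$Bo <- (1 - config$bb_fraction) * out$AGBIO

  # zero-inflated Beta mortality on burned plots, moment-matched to the
  # target mean/SD given the zero-inflation probability
  p0 <- profile$treeloss_zero_prob
  mt <- mu["TREELOSS"]; st <- sg["TREELOSS"]
  mb <- mt / (1 - p0)
  vb <- (st^2 + mt^2) / (1 - p0) - mb^2
  if (vb <= 0 || vb >= mb * (1 - mb)) {
    stop("infeasible zero-inflated Beta moments for TREELOSS")
  }
  nu <- mb * (1 - mb) / vb - 1
  burned <- which(out$FIRE == 1)
  tl <- rep(NA_real_, n)
  nz <- runif(length(burned)) >= p0
  tl[burned] <- 0
  tl[burned[nz]] <- rbeta(sum(nz), mb * nu, (1 - mb) * nu)
  out$TREELOSS <- tl

  # monthly normals back-filled from the seasonal values: fire-season and
  # spring months carry their seasonal mean exactly; other months a blend
  fs <- config$fire_season_months
  sp <- config$spring_months
  for (m in 1:12) {
    wgt <- if (m %in% fs) 1 else if (m %in% sp) 0 else 0.5
    out[[sprintf("ppt_%02d", m)]] <- wgt * out$PPT + (1 - wgt) * out$PPTs
    out[[sprintf("tmax_%02d", m)]] <- wgt * out$TEMP + (1 - wgt) * out$TEMPs
  }
  for (m in 1:12) {
    out[[sprintf("tmin_%02d", m)]] <-
      out[[sprintf("tmax_%02d", m)]] - profile$diurnal_range_c
  }
  out$AGE <- as.numeric(out$AGE)
  out[c(.fc_required_cols(), .fc_mains)]
}

#' Simulate a SAR-process response
#'
#' Draws `eps ~ N(0, sigma^2)` and solves the simultaneous system
#' `y = rho * lag(y) + (X - rho*lag(X)) %*% beta + eps` by fixed-point
#' iteration (the row-standardized lag operator is a contraction for
#' `|rho| < 1`). Used as the data-generating process for parameter-recovery
#' simulations.
#'
#' @param x covariate matrix.
#' @param weights a [build_weights()] object aligned with `x` rows.
#' @param rho spatial autocorrelation, `|rho| < 1`.
#' @param beta coefficient vector (length `ncol(x)`).
#' @param sigma noise SD (`>= 0`).
#' @param seed integer seed.
#' @param alpha intercept (default 0).
#' @param tol fixed-point convergence tolerance.
#' @return the response vector.
#' @export
generate_sar_data <- function(x, weights, rho, beta, sigma, seed = 1L,
                              alpha = 0, tol = 1e-10) {
  if (abs(rho) >= 1) {
    stop("|rho| must be < 1 for the generative solve to contract")
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(beta), sigma >= 0)
  n <- nrow(x)
  eps <- .fc_with_seed(seed, rnorm(n, 0, sigma))
  lag_x <- apply(x, 2, spatial_lag, weights = weights)
  const <- alpha + as.numeric((x - rho * lag_x) %*% beta) + eps
  y <- const
  for (it in seq_len(10000)) {
    y_new <- rho * spatial_lag(y, weights) + const
    if (max(abs(y_new - y)) < tol) return(y_new)
    y <- y_new
  }
  stop("fixed-point solve did not converge in 10000 iterations ",
       sprintf("(last delta %g)", max(abs(y_new - y))))
}
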