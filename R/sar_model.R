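# Spatial autoregressive (SAR) regression:
#   y = alpha + rho * lag(y) + sum_k beta_k (X_k - rho * lag(X_k))
#       + sum_j delta_j Z_j + eps
# where lag() is the spatial lag under inverse-squared-distance weights.
# At fixed rho the model is linear, so estimation profiles rho over a grid
# with golden-section refinement and solves least squares at each candidate.

.fc_mains <- c("PPT", "TEMP", "ET", "PPTs", "TEMPs", "ETs")
.fc_inters <- c("PPT*TEMP", "PPT*ET", "PPT*PPTs",
                "TEMP*TEMPs", "TEMP*ET", "ET*ETs")

#' Model term specifications
#'
#' The fire-risk specification regresses fire incidence on the six seasonal
#' climate covariates, their six squares and six pairwise interactions (all
#' lag-transformed), plus untransformed ownership: 19 covariate terms. The
#' biomass-loss (mortality) specification adds untransformed stand age and
#' aboveground biomass: 21 terms. The non-lagged attributes (`delta` terms)
#' are never lag-transformed.
#'
#' @return an object of class `model_spec` with fields `response`, `mains`,
#'   `quadratics`, `interactions`, `deltas`.
#' @export
fire_model_spec <- function() {
  spec <- list(response = "FIRE",
               mains = .fc_mains,
               quadratics = paste0(.fc_mains, "^2"),
               interactions = .fc_inters,
               deltas = "OWN")
  class(spec) <- "model_spec"
  spec
}

#' @rdname fire_model_spec
#' @export
treebio_model_spec <- function() {
  spec <- fire_model_spec()
  spec$response <- "TREELOSS"
  spec$deltas <- c("OWN", "AGE", "AGBIO")
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s ~ %d beta terms + %d delta terms>\n",
              x$response,
              length(x$mains) + length(x$quadratics) + length(x$interactions),
              length(x$deltas)))
  invisible(x)
}

.fc_beta_terms <- function(spec) {
  c(spec$mains, spec$quadratics, spec$interactions)
}

# Evaluate named terms ("PPT", "PPT^2", "PPT*TEMP") against data columns.
.fc_term_matrix <- function(data, terms) {
  out <- matrix(NA_real_, nrow(data), length(terms),
                dimnames = list(NULL, terms))
  getcol <- function(nm) {
    if (is.null(data[[nm]])) stop("missing covariate column: ", nm)
    data[[nm]]
  }
  for (tm in terms) {
    if (grepl("*", tm, fixed = TRUE)) {
      parts <- strsplit(tm, "*", fixed = TRUE)[[1]]
      out[, tm] <- getcol(parts[1]) * getcol(parts[2])
    } else if (grepl("^2", tm, fixed = TRUE)) {
      out[, tm] <- getcol(sub("\\^2$", "", tm))^2
    } else {
      out[, tm] <- getcol(tm)
    }
  }
  if (anyNA(out)) stop("covariates contain missing values")
  out
}

.fc_apply_scaling <- function(data, config) {
  for (nm in names(config$unit_scaling)) {
    if (!is.null(data[[nm]])) data[[nm]] <- data[[nm]] * config$unit_scaling[nm]
  }
  data
}

#' Aggregate plots to county-by-ecoregion units
#'
#' One unit per distinct (county, ecoregion) pair: all numeric fields are
#' averaged over the member plots (so the binary fire outcome becomes an
#' incidence fraction, and mortality averages over the burned members) and
#' the unit centroid is the mean of member coordinates.
#'
#' @param records plot-table data frame with `county_id` and `ecoregion_id`.
#' @return data frame of aggregate units with `county_id`, `ecoregion_id`,
#'   `n_plots`, and the averaged numeric columns.
#' @export
aggregate_county_ecoregion <- function(records) {
  if (is.null(records$county_id) || is.null(records$ecoregion_id)) {
    stop("records need county_id and ecoregion_id")
  }
  key <- interaction(records$county_id, records$ecoregion_id, drop = TRUE,
                     sep = "\r")
  numcols <- names(records)[vapply(records, is.numeric, logical(1))]
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(split_idx, function(ix) {
    block <- records[ix, , drop = FALSE]
    means <- vapply(numcols, function(cc) {
      mean(block[[cc]], na.rm = TRUE)
    }, numeric(1))
    means[is.nan(means)] <- NA_real_
    cbind(
      data.frame(county_id = block$county_id[1],
                 ecoregion_id = block$ecoregion_id[1],
                 n_plots = length(ix), stringsAsFactors = FALSE),
      as.data.frame(as.list(means))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # restore syntactic names mangled by as.data.frame (none expected, but be
  # safe for columns like "PPT^2" appended upstream)
  names(out)[-(1:3)] <- numcols
  out
}

#' Build the SAR design matrices
#'
#' Beta columns are the lag-transformed terms `X - rho * lag(X)`, with
#' quadratics and interactions formed on the original covariates *before*
#' lagging (the product is lagged as a whole column, not the factors).
#' Delta columns are untransformed. Per-column unit scaling from the
#' configuration is applied to the base covariates first.
#'
#' @param data data frame of units or plots carrying the response and
#'   covariate columns.
#' @param spec a [fire_model_spec()] / [treebio_model_spec()].
#' @param weights a [build_weights()] aligned with `data` rows.
#' @param rho spatial autocorrelation parameter (finite).
#' @param config an [run_config()].
#' @return list with `y`, `x_tilde` (transformed beta-term matrix), `z`
#'   (delta matrix), `lag_y`, `x_raw`, `lag_x`.
#' @export
build_design <- function(data, spec, weights, rho, config = run_config()) {
  if (!is.finite(rho)) stop("rho must be finite")
  data <- .fc_apply_scaling(data, config)
  y <- data[[spec$response]]
  if (is.null(y)) stop("missing response column: ", spec$response)
  x <- .fc_term_matrix(data, .fc_beta_terms(spec))
  z <- .fc_term_matrix(data, spec$deltas)
  lag_x <- apply(x, 2, spatial_lag, weights = weights,
                 row_standardize = config$row_standardize)
  lag_y <- spatial_lag(y, weights, row_standardize = config$row_standardize)
  list(y = y, x_tilde = x - rho * lag_x, z = z,
       lag_y = lag_y, x_raw = x, lag_x = lag_x)
}

#' Fit index (pseudo R-squared)
#'
#' `1 - SSE / SST` with `SST` taken about the mean of `y`; equals the usual
#' R-squared for a linear fit and can be negative for a fit worse than the
#' mean.
#'
#' @param y observed values.
#' @param y_hat fitted values.
#' @return a number `<= 1`.
#' @export
fit_index <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("fit index undefined: zero variance in y")
  1 - sum((y - y_hat)^2) / sst
}

# Least-squares solve at fixed rho. Returns sse and, if wanted, the fit.
.fc_sar_solve <- function(rho, y, x, lag_x, lag_y, z, full = FALSE) {
  m <- cbind(`(Intercept)` = 1, x - rho * lag_x, z)
  yt <- y - rho * lag_y
  fit <- lm.fit(m, yt)
  if (fit$rank < ncol(m)) {
    dropped <- colnames(m)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  sse <- sum(fit$residuals^2)
  if (!full) return(sse)
  p <- ncol(m)
  n <- length(y)
  sigma2 <- sse / (n - p)
  rinv <- backsolve(qr.R(fit$qr), diag(p))
  vcov <- sigma2 * tcrossprod(rinv)
  se <- sqrt(diag(vcov))
  names(se) <- colnames(m)
  coefs <- fit$coefficients[colnames(m)]
  list(sse = sse, coef = coefs, se = se, residuals = fit$residuals,
       fitted = y - fit$residuals)
}

#' Fit the SAR model by profiled least squares
#'
#' For each candidate `rho` on the configured grid the remaining parameters
#' are the exact least-squares solution of `y - rho*lag(y)` on the intercept,
#' the lag-transformed beta terms and the untransformed delta terms; the
#' profile criterion is then refined around the grid minimizer with
#' [stats::optimize()] (golden section). With the default
#' `sar_method = "ml"` the criterion is the concentrated Gaussian negative
#' log-likelihood, `n/2 log(SSE/n) - sum(log|1 - rho*lambda_i|)` over the
#' lag operator's eigenvalues — the log-determinant term corrects the
#' upward simultaneity bias that makes the raw SSE profile (`"ls"`)
#' inconsistent for `rho`. The grid deliberately extends beyond `|rho| = 1`
#' since published fits report autocorrelation parameters above 1 (the
#' likelihood itself diverges at `rho` equal to a reciprocal eigenvalue and
#' such candidates are never selected). If the model fits the data
#' perfectly `rho` is unidentified and the smallest `|rho|` with zero error
#' is reported. Standard errors are conditional on the profiled `rho` (OLS
#' formulas at the optimum) and labelled as such.
#'
#' @param data data frame of units/plots with response and covariates.
#' @param spec a model spec.
#' @param weights aligned [build_weights()] object.
#' @param config an [run_config()].
#' @return an object of class `sar_fit`: `alpha`, `rho`, `beta`, `delta`
#'   (named vectors), `se`, `rmse` (the df-adjusted residual standard error
#'   `sqrt(SSE / (n - p))`, `p` counting all estimated parameters including
#'   `rho` — in-sample `sqrt(SSE/n)` cannot decrease when a term is dropped,
#'   which would make backward elimination vacuous), `fit_index`,
#'   `residuals`, `fitted`, `moran_residuals` (Moran's I of residuals),
#'   `convergence` metadata, and the `spec`.
#' @export
fit_sar <- function(data, spec, weights, config = run_config()) {
  data <- .fc_apply_scaling(data, config)
  y <- data[[spec$response]]
  if (is.null(y)) stop("missing response column: ", spec$response)
  x <- .fc_term_matrix(data, .fc_beta_terms(spec))
  z <- .fc_term_matrix(data, spec$deltas)
  fit <- .fc_profile_sar(y, x, z, weights, config)
  fit$spec <- spec
  fit
}

#' Fit the SAR model from raw matrices
#'
#' Engine behind [fit_sar()], exposed for simulation studies: `x` columns
#' are lag-transformed beta terms, `z` (optional) untransformed columns.
#'
#' @inheritParams fit_sar
#' @param y response vector.
#' @param x numeric matrix of beta-term covariates (named columns).
#' @param z optional matrix of untransformed covariates.
#' @return an `sar_fit` object.
#' @export
fit_sar_xy <- function(y, x, z = NULL, weights, config = run_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (is.null(colnames(z))) colnames(z) <- paste0("z", seq_len(ncol(z)))
  }
  .fc_profile_sar(y, x, z, weights, config)
}

# Eigenvalues of the lag operator. For the row-standardized lag D^-1 W the
# operator is similar to the symmetric D^-1/2 W D^-1/2, so its spectrum is
# real; isolated units (zero row sum) contribute eigenvalue ~0.
.fc_lag_eigenvalues <- function(weights, row_standardize) {
  key <- if (row_standardize) "eig_rs" else "eig_raw"
  cache <- weights$cache
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  w <- weights$w
  if (row_standardize) {
    rs <- Matrix::rowSums(w)
    d <- ifelse(rs > 0, rs, 1)
    s <- 1 / sqrt(d)
    sym <- as.matrix(w) * tcrossprod(s)
  } else {
    sym <- as.matrix(w)
  }
  lam <- eigen(sym, symmetric = TRUE, only.values = TRUE)$values
  if (!is.null(cache)) cache[[key]] <- lam
  lam
}

.fc_profile_sar <- function(y, x, z, weights, config) {
  n <- length(y)
  p <- 2 + ncol(x) + if (is.null(z)) 0 else ncol(z)
  if (n <= p) stop("too few observations for the number of terms")
  lag_x <- apply(x, 2, spatial_lag, weights = weights,
                 row_standardize = config$row_standardize)
  lag_y <- spatial_lag(y, weights, row_standardize = config$row_standardize)
  # profile criterion: concentrated negative log-likelihood (default) or
  # the raw profiled error sum of squares
  if (config$sar_method == "ml") {
    lam <- .fc_lag_eigenvalues(weights, config$row_standardize)
    crit <- function(rho) {
      sse <- .fc_sar_solve(rho, y, x, lag_x, lag_y, z)
      n / 2 * log(sse / n) - sum(log(abs(1 - rho * lam)))
    }
  } else {
    crit <- function(rho) .fc_sar_solve(rho, y, x, lag_x, lag_y, z)
  }
  grid <- seq(config$rho_grid[1], config$rho_grid[2], by = config$rho_grid[3])
  sse_grid <- vapply(grid, .fc_sar_solve, numeric(1),
                     y = y, x = x, lag_x = lag_x, lag_y = lag_y, z = z)
  if (min(sse_grid) <= 1e-16 * max(1, sum(y^2))) {
    # degenerate perfect fit: rho is unidentified, every candidate explains
    # the data; tie-break to the smallest |rho| with (near) zero error
    ties <- which(sse_grid <= 1e-14 * max(1, sum(y^2)))
    k <- ties[which.min(abs(grid[ties]))]
    rho_hat <- grid[k]
  } else {
    crit_grid <- if (config$sar_method == "ml") {
      n / 2 * log(sse_grid / n) -
        vapply(grid, function(r) sum(log(abs(1 - r * lam))), numeric(1))
    } else {
      sse_grid
    }
    k <- which.min(crit_grid)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
    rho_hat <- if (lo < hi) {
      opt <- stats::optimize(crit, c(lo, hi), tol = 1e-10)
      # optimize() can return an interior point marginally worse than the
      # grid minimizer on a flat profile; keep the better of the two
      if (opt$objective <= crit_grid[k]) opt$minimum else grid[k]
    } else {
      grid[k]
    }
    if (k == 1 || k == length(grid)) {
      warning(sprintf(
        "profiled rho at the grid boundary (%g); widen rho_grid if this is unexpected",
        grid[k]), call. = FALSE)
    }
  }
  sol <- .fc_sar_solve(rho_hat, y, x, lag_x, lag_y, z, full = TRUE)
  # fitted y on the original scale: rho*lag(y) + [1, x_tilde, z] %*% coef,
  # which equals y minus the regression residual
  fitted_y <- y - sol$residuals
  beta_names <- colnames(x)
  delta_names <- if (is.null(z)) character(0) else colnames(z)
  moran_res <- tryCatch(morans_i(sol$residuals, weights),
                        error = function(e) NA_real_)
  out <- list(
    alpha = unname(sol$coef["(Intercept)"]),
    rho = rho_hat,
    beta = sol$coef[beta_names],
    delta = if (length(delta_names)) sol$coef[delta_names] else numeric(0),
    se = sol$se,
    se_note = "conditional on profiled rho (OLS formulas at the optimum)",
    # residual standard error: df-adjusted (p linear coefficients plus rho)
    # so that backward elimination can trade terms against fit
    rmse = sqrt(sol$sse / (n - length(sol$coef) - 1)),
    fit_index = fit_index(y, fitted_y),
    sse = sol$sse,
    residuals = sol$residuals,
    fitted = fitted_y,
    lag_y = lag_y,
    moran_residuals = moran_res,
    n = n,
    convergence = list(grid_min = grid[k], refined = rho_hat,
                       grid_range = range(grid), grid_step = config$rho_grid[3])
  )
  class(out) <- "sar_fit"
  out
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit: n = %d, rho = %.4f, RMSE = %.4g, FI = %.3f>\n",
              x$n, x$rho, x$rmse, x$fit_index))
  invisible(x)
}

#' Backward elimination of interaction terms
#'
#' Greedy search: at each step every single remaining interaction term is
#' tentatively removed and the model refitted; the removal that most reduces
#' RMSE is made permanent, and the loop stops when no removal reduces RMSE.
#' Main effects and quadratics are never candidates (terms that are not
#' individually significant stay in the model when they improve fit).
#'
#' @inheritParams fit_sar
#' @return list with `spec` (the pruned spec), `fit` (the final
#'   [fit_sar()] result) and `trace` (data frame of removals).
#' @export
backward_eliminate <- function(data, spec, weights, config = run_config()) {
  if (length(spec$interactions) < 1) {
    stop("spec has no interaction terms to eliminate")
  }
  current <- spec
  fit <- fit_sar(data, current, weights, config)
  trace <- data.frame(step = integer(0), removed = character(0),
                      rmse = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current$interactions) == 0) break
    cand_rmse <- vapply(current$interactions, function(tm) {
      trial <- current
      trial$interactions <- setdiff(trial$interactions, tm)
      fit_sar(data, trial, weights, config)$rmse
    }, numeric(1))
    best <- which.min(cand_rmse)
    if (cand_rmse[best] >= fit$rmse) break
    step <- step + 1L
    removed <- current$interactions[best]
    current$interactions <- setdiff(current$interactions, removed)
    fit <- fit_sar(data, current, weights, config)
    trace <- rbind(trace, data.frame(step = step, removed = removed,
                                     rmse = fit$rmse,
                                     stringsAsFactors = FALSE))
  }
  list(spec = current, fit = fit, trace = trace)
}

#' Plug-in prediction of fire probability or mortality fraction
#'
#' Linear predictor `eta = alpha + rho * observed_lag +
#' sum beta (X - rho*lag(X)) + sum delta Z`, evaluated with fitted or
#' published coefficients and an observed (or synthetic) spatial lag of the
#' response. The returned probability is `eta` clipped to `[0, 1]`; the raw
#' predictor is also returned. The plug-in form is used (rather than solving
#' the simultaneous spatial system) because a published autocorrelation
#' parameter above 1 makes the simultaneous solve ill-posed.
#'
#' @param coeffs an `sar_fit` or `published_coefficients` object.
#' @param data data frame with the covariate columns required by the
#'   coefficient names.
#' @param weights aligned [build_weights()] object.
#' @param observed_lag numeric vector: spatial lag of the observed response.
#' @param config an [run_config()]; `unit_scaling` must match the
#'   convention of the coefficient source.
#' @return list with `eta` (raw linear predictor) and `prob` (clipped to
#'   `[0, 1]`).
#' @export
predict_response <- function(coeffs, data, weights, observed_lag,
                             config = run_config()) {
  if (missing(observed_lag) || is.null(observed_lag)) {
    stop("observed_lag must be supplied for plug-in prediction")
  }
  if (length(observed_lag) != nrow(data)) {
    stop("observed_lag length does not match data rows")
  }
  data <- .fc_apply_scaling(data, config)
  rho <- coeffs$rho
  beta <- coeffs$beta
  delta <- coeffs$delta
  x <- .fc_term_matrix(data, names(beta))
  lag_x <- apply(x, 2, spatial_lag, weights = weights,
                 row_standardize = config$row_standardize)
  xt <- x - rho * lag_x
  eta <- coeffs$alpha + rho * observed_lag + as.numeric(xt %*% beta)
  if (length(delta)) {
    z <- .fc_term_matrix(data, names(delta))
    eta <- eta + as.numeric(z %*% delta)
  }
  list(eta = eta, prob = pmin(1, pmax(0, eta)))
}
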