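test_that("county-by-ecoregion aggregation averages member plots", {
  # 51 plots in one county split 17/34 across two ecoregions
  df <- make_plot_df(51)
  df$county_id <- "Latah"
  df$ecoregion_id <- c(rep("Palouse", 17), rep("Mountain", 34))
  units <- aggregate_county_ecoregion(df)
  expect_equal(nrow(units), 2)
  expect_setequal(units$n_plots, c(17, 34))
  pal <- units[units$ecoregion_id == "Palouse", ]
  expect_equal(pal$AGE, mean(df$AGE[1:17]))
  expect_equal(pal$lon, mean(df$lon[1:17]))

  # single plot: unit means equal the plot's values
  one <- aggregate_county_ecoregion(make_plot_df(1))
  expect_equal(nrow(one), 1)
  expect_equal(one$AGBIO, 21)
  expect_equal(one$n_plots, 1)

  # binary fire outcome becomes an incidence fraction
  two <- make_plot_df(2)
  two$county_id <- "C"; two$ecoregion_id <- "E"
  two$FIRE <- c(0, 1); two$TREELOSS <- c(NA, 0.4)
  agg <- aggregate_county_ecoregion(two)
  expect_equal(agg$FIRE, 0.5)
  expect_equal(agg$TREELOSS, 0.4) # mean over the burned member
})

test_that("design matrices implement the lag transform term-by-term", {
  df <- seasonal_aggregate(make_plot_df(30))
  w <- build_weights(df[c("lon", "lat")], 660)
  spec <- fire_model_spec()

  d0 <- build_design(df, spec, w, rho = 0)
  expect_equal(ncol(d0$x_tilde) + ncol(d0$z), 19)
  expect_equal(d0$x_tilde, d0$x_raw) # rho = 0: transform is the identity
  d_tree <- build_design(df, treebio_model_spec(), w, rho = 0)
  expect_equal(ncol(d_tree$x_tilde) + ncol(d_tree$z), 21)

  # a constant covariate lags to itself, so X - rho*lag(X) = (1-rho)*X
  df2 <- df
  df2$PPT <- 5
  d4 <- build_design(df2, spec, w, rho = 0.4)
  expect_equal(unname(d4$x_tilde[, "PPT"]), rep(0.6 * 5, nrow(df2)),
               tolerance = 1e-9)
  # the interaction column is the lagged *product*, not a product of lags
  dd <- build_design(df, spec, w, rho = 0.4)
  prod_raw <- df$PPT * df$TEMP
  expect_equal(unname(dd$x_tilde[, "PPT*TEMP"]),
               prod_raw - 0.4 * spatial_lag(prod_raw, w), tolerance = 1e-9)
  expect_error(build_design(df, spec, w, rho = Inf), "finite")
})

test_that("unit scaling is applied before term construction", {
  df <- seasonal_aggregate(make_plot_df(20))
  w <- build_weights(df[c("lon", "lat")], 660)
  cfg <- run_config(unit_scaling = c(ET = 0.01))
  d <- build_design(df, fire_model_spec(), w, rho = 0, config = cfg)
  d1 <- build_design(df, fire_model_spec(), w, rho = 0)
  expect_equal(d$x_tilde[, "ET"], 0.01 * d1$x_tilde[, "ET"])
  expect_equal(d$x_tilde[, "ET^2"], 1e-4 * d1$x_tilde[, "ET^2"])
})

test_that("fit index matches the worked examples", {
  expect_equal(fit_index(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(fit_index(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(fit_index(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_error(fit_index(rep(1, 3), c(1, 2, 3)), "zero variance")
  expect_error(fit_index(1:3, 1:4), "length")
})

test_that("fit at rho = 0 coincides with ordinary least squares", {
  co <- jitter_grid_coords(120, seed = 5)
  w <- build_weights(co, 150)
  set.seed(8)
  x <- cbind(a = rnorm(120), b = rnorm(120))
  y <- 1 + x %*% c(2, -1) + rnorm(120, 0, 0.3)
  cfg <- run_config(rho_grid = c(0, 0, 1))
  # a few units are isolated at this cutoff; their lag-0 fallback warns
  fit <- suppressWarnings(fit_sar_xy(as.numeric(y), x, NULL, w, cfg))
  ols <- stats::lm.fit(cbind(1, x), as.numeric(y))
  expect_equal(c(fit$alpha, unname(fit$beta)),
               unname(ols$coefficients), tolerance = 1e-8)
  expect_equal(fit$rho, 0)
  expect_equal(fit$fit_index,
               1 - sum(ols$residuals^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
})

test_that("noiseless data identify beta exactly with rho tie-broken to 0", {
  co <- jitter_grid_coords(80, seed = 6)
  w <- build_weights(co, 150)
  set.seed(9)
  x <- cbind(a = rnorm(80), b = rnorm(80))
  y <- generate_sar_data(x, w, rho = 0, beta = c(1, -2), sigma = 0, seed = 2)
  fit <- fit_sar_xy(y, x, NULL, w)
  expect_equal(unname(fit$beta), c(1, -2), tolerance = 1e-8)
  expect_equal(fit$rho, 0)
})

test_that("parameters are recovered from a simulated SAR process", {
  n <- 400
  co <- jitter_grid_coords(n, seed = 7)
  set.seed(1007) # covariate stream independent of the coordinate jitter
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  w <- build_weights(co, 150)
  y <- generate_sar_data(x, w, rho = 0.4, beta = c(1, -2), sigma = 0.1,
                         seed = 7)
  fit <- fit_sar_xy(y, x, NULL, w)
  expect_gte(fit$rho, 0.2)
  expect_lte(fit$rho, 0.6)
  expect_true(all(abs(fit$beta - c(1, -2)) <=
                    3 * fit$se[c("x1", "x2")]))
  expect_lte(fit$rmse, 0.15)
  # profiled criterion attains its minimum at the reported rho
  expect_equal(fit$rho, fit$convergence$refined)
})

test_that("rank-deficient designs error naming the collinear column", {
  co <- jitter_grid_coords(50, seed = 3)
  w <- build_weights(co, 150)
  set.seed(3)
  x <- cbind(a = rnorm(50), b = rnorm(50))
  x <- cbind(x, c = x[, "a"]) # exact duplicate
  y <- rnorm(50)
  expect_error(suppressWarnings(fit_sar_xy(y, x, NULL, w)), "collinear.*c")
})

test_that("backward elimination drops a null interaction and stops", {
  n <- 300
  co <- jitter_grid_coords(n, seed = 10)
  w <- build_weights(co, 150)
  set.seed(10)
  df <- data.frame(
    PPT = rnorm(n), TEMP = rnorm(n), ET = rnorm(n),
    PPTs = rnorm(n), TEMPs = rnorm(n), ETs = rnorm(n),
    OWN = rbinom(n, 1, 0.3)
  )
  spec <- fire_model_spec()
  x <- firecarb:::.fc_term_matrix(df, firecarb:::.fc_beta_terms(spec))
  # every interaction active except PPT*TEMP, whose coefficient is zero
  beta <- setNames(rep(0.5, ncol(x)), colnames(x))
  beta["PPT*TEMP"] <- 0
  df$FIRE <- as.numeric(1 + x %*% beta + rnorm(n, 0, 0.05))
  res <- backward_eliminate(df, spec, w)
  expect_false("PPT*TEMP" %in% res$spec$interactions)
  expect_true(all(setdiff(firecarb:::.fc_inters, "PPT*TEMP") %in%
                    res$spec$interactions))
  expect_lte(nrow(res$trace), length(spec$interactions))
  expect_identical(res$spec$mains, spec$mains) # mains never removed
})

test_that("plug-in prediction reproduces published-coefficient arithmetic", {
  fire <- load_published_coefficients("fire_risk")
  n <- 4
  df <- data.frame(PPT = 0, TEMP = 0, ET = 0, PPTs = 0, TEMPs = 0, ETs = 0,
                   OWN = c(1, 0, 1, 0),
                   lon = c(-105, -104, -103, -102), lat = c(40, 40.5, 41, 41.5))
  w <- build_weights(df[c("lon", "lat")], 660)
  pr <- predict_response(fire, df, w, observed_lag = rep(0, n))
  # eta = alpha + delta1*OWN with everything else zero
  expect_equal(pr$eta[1], -0.17030 + 0.01358, tolerance = 1e-12)
  expect_equal(pr$prob[1], 0) # negative eta clips to 0
  expect_equal(pr$eta[1] - pr$eta[2], 0.01358, tolerance = 1e-12)
  expect_gt(pr$eta[1], pr$eta[2]) # monotone increasing in OWN

  tree <- load_published_coefficients("treebio_loss")
  df$OWN <- 1 # hold ownership fixed so the contrast isolates AGE
  df$AGE <- c(0, 100, 0, 0)
  df$AGBIO <- 0
  pt <- predict_response(tree, df, w, observed_lag = rep(0, n))
  expect_equal(pt$eta[2] - pt$eta[1], 100 * -0.00245, tolerance = 1e-12)
  expect_equal(pt$prob[1], 1) # alpha = 2.267 pushes eta above 1: clips
  expect_gt(pt$eta[1], 1)
  expect_error(predict_response(tree, df, w, observed_lag = NULL), "lag")
})
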