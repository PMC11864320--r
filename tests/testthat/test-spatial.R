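deg_per_km <- 180 / (pi * 6371) # longitude degrees per km on the equator

test_that("weights follow the inverse-squared-distance contract", {
  co <- cbind(c(0, deg_per_km), c(0, 0)) # two points 1 km apart
  w <- build_weights(co, cutoff_km = 5)
  expect_equal(w$w[1, 2], 1, tolerance = 1e-9)
  expect_equal(w$w[2, 1], w$w[1, 2])
  expect_equal(w$w_total, 2, tolerance = 1e-9)

  co3 <- cbind(c(0, 1, 2) * deg_per_km, c(0, 0, 0)) # collinear at 0,1,2 km
  w3 <- build_weights(co3, cutoff_km = 5)
  expect_equal(w3$w[1, 2], 1, tolerance = 1e-9)
  expect_equal(w3$w[2, 3], 1, tolerance = 1e-9)
  expect_equal(w3$w[1, 3], 0.25, tolerance = 1e-9)

  far <- cbind(c(0, 6.3), c(0, 0)) # ~700 km apart
  expect_warning(wf <- build_weights(far, cutoff_km = 660), "isolated")
  expect_equal(wf$w_total, 0)

  expect_error(build_weights(cbind(c(0, 0), c(1, 1))), "duplicate")
  expect_error(build_weights(cbind(0, 0)), "at least 2")
})

test_that("build_weights is invariant to input ordering up to relabeling", {
  set.seed(4)
  co <- cbind(runif(20, -105, -100), runif(20, 38, 42))
  w1 <- build_weights(co, 300)
  perm <- sample(20)
  w2 <- build_weights(co[perm, ], 300)
  expect_equal(as.matrix(w2$w), as.matrix(w1$w)[perm, perm],
               tolerance = 1e-12)
  expect_equal(w2$w_total, w1$w_total)
})

test_that("spatial lag is the weighted neighbour mean", {
  co3 <- cbind(c(0, 1, 2) * deg_per_km, c(0, 0, 0))
  w3 <- build_weights(co3, cutoff_km = 5)
  lag <- spatial_lag(c(0, 1, 2), w3)
  expect_equal(lag[2], 1, tolerance = 1e-9) # (1*0 + 1*2) / 2
  expect_equal(spatial_lag(c(7, 7, 7), w3), c(7, 7, 7), tolerance = 1e-9)
  # unstandardized variant returns the raw weighted sum
  expect_equal(spatial_lag(c(0, 1, 2), w3, row_standardize = FALSE)[1],
               1 * 1 + 0.25 * 2, tolerance = 1e-8)
  expect_error(spatial_lag(1:2, w3), "length")
  # isolated unit gets 0 with a warning
  co4 <- cbind(c(0, deg_per_km, 7), c(0, 0, 0))
  w4 <- build_weights(co4, cutoff_km = 5)
  expect_warning(l4 <- spatial_lag(c(1, 2, 3), w4), "isolated")
  expect_equal(l4[3], 0)
})

test_that("Moran's I equals the checkerboard closed form and the oracle", {
  s <- 0.01
  sq <- cbind(c(0, s, s, 0), c(0, 0, s, s))
  w <- build_weights(sq, cutoff_km = 10)
  expect_equal(morans_i(c(1, -1, 1, -1), w), -0.6, tolerance = 1e-6)

  for (seed in 1:10) {
    set.seed(seed)
    co <- cbind(runif(50, -106, -102), runif(50, 39, 43))
    vals <- rnorm(50)
    w <- build_weights(co, cutoff_km = 250)
    expect_equal(morans_i(vals, w), moran_oracle(vals, co, 250),
                 tolerance = 1e-10)
  }

  expect_error(morans_i(rep(2, 4), build_weights(sq, 10)), "zero variance")
  far <- cbind(c(0, 6.3, 12.6), c(0, 0, 0))
  suppressWarnings(wf <- build_weights(far, cutoff_km = 300))
  expect_error(morans_i(c(1, 2, 3), wf), "no edges")
})

test_that("permutation test is reproducible, bounded, and affine-invariant", {
  co <- jitter_grid_coords(100, seed = 3)
  vals <- co[, "lon"] + co[, "lat"] # smooth gradient: strongly clustered
  w <- build_weights(co, 660)
  t1 <- morans_i_test(vals, w, n_perm = 999, seed = 5)
  expect_gte(t1$p_value, 1 / 1000)
  expect_lte(t1$p_value, 0.01) # construction guarantees an extreme I
  t2 <- morans_i_test(vals, w, n_perm = 999, seed = 5)
  expect_identical(t1, t2)
  t3 <- morans_i_test(3 + 10 * vals, w, n_perm = 999, seed = 5)
  expect_equal(t3$p_value, t1$p_value)
  expect_equal(t3$statistic, t1$statistic, tolerance = 1e-12)
  expect_error(morans_i_test(vals, w, n_perm = 10), "99")
})

test_that("permutation test holds its type-I error rate under independence", {
  # scaled down from the spec's 200x999 sketch to stay inside the time
  # budget: 200 replicate iid datasets on 120 units, 99 permutations each
  co <- jitter_grid_coords(120, seed = 11)
  w <- build_weights(co, 660)
  set.seed(42)
  rejections <- vapply(1:200, function(i) {
    morans_i_test(rnorm(120), w, n_perm = 99, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("a field's own lag is more autocorrelated than its permutation", {
  co <- jitter_grid_coords(150, seed = 9)
  w <- build_weights(co, 300)
  set.seed(1)
  x <- rnorm(150)
  smooth <- spatial_lag(x, w)
  i_smooth <- morans_i(smooth, w)
  i_perm <- morans_i(sample(smooth), w)
  expect_gt(i_smooth, i_perm)
})

test_that("weights round-trip through the edge-list CSV", {
  co <- jitter_grid_coords(25, seed = 2)
  w <- build_weights(co, 400)
  edges <- weights_to_edges(w)
  expect_true(all(edges$weight > 0))
  expect_equal(sum(edges$weight) * 2, w$w_total, tolerance = 1e-9)
  expect_equal(edges$distance_km, 1 / sqrt(edges$weight), tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights(w, path)
  back <- utils::read.csv(path)
  expect_equal(back$weight, edges$weight)
})
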