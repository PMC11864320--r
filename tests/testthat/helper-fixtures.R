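# Shared fixture builders (all deterministic; data built in code, no files).

# Minimal valid plot table with n rows spread over two counties/ecoregions.
make_plot_df <- function(n = 3) {
  i <- seq_len(n)
  df <- data.frame(
    plot_id = sprintf("P%03d", i),
    lon = -105 + 0.37 * i,
    lat = 40 + 0.21 * i,
    elevation = 500 + 10 * i,
    slope = 5 + (i %% 4),
    aspect = (i * 73) %% 360,
    county_id = ifelse(i %% 2 == 0, "C01", "C02"),
    ecoregion_id = ifelse(i %% 3 == 0, "E1", "E2"),
    OWN = as.numeric(i %% 4 == 0),
    AGE = 40 + 2 * i,
    AGBIO = 20 + i,
    Bb = 0.7 * (20 + i),
    Bo = 0.3 * (20 + i),
    FIRE = as.numeric(i %% 5 == 0),
    TREELOSS = ifelse(i %% 5 == 0, 0.2 + 0.01 * (i %% 3), NA),
    stringsAsFactors = FALSE
  )
  for (m in 1:12) {
    df[[sprintf("ppt_%02d", m)]] <- 50 + 3 * m + i %% 7
    df[[sprintf("tmax_%02d", m)]] <- 10 + m + 0.1 * i
    df[[sprintf("tmin_%02d", m)]] <- 2 + m + 0.1 * i
  }
  df
}

# Jittered-grid coordinates over the default bounding box (the recovery
# experiments' pre-registered geometry).
jitter_grid_coords <- function(n, seed) {
  set.seed(seed)
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  cells <- sample(nx * ny, n)
  cx <- (cells - 1) %% nx
  cy <- (cells - 1) %/% nx
  cbind(lon = -110 + (cx + runif(n)) * 11.7 / nx,
        lat = 37 + (cy + runif(n)) * 9 / ny)
}

# Independent dense O(n^2) Moran's I oracle (plain double loop on a full
# haversine distance matrix; shares no code path with the package internals
# beyond the distance formula's definition).
moran_oracle <- function(values, coords, cutoff_km) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  wtot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- haversine_km(coords[i, 1], coords[i, 2],
                        coords[j, 1], coords[j, 2])
      if (d > 0 && d < cutoff_km) {
        w <- 1 / d^2
        num <- num + w * z[i] * z[j]
        wtot <- wtot + w
      }
    }
  }
  (n / wtot) * num / sum(z^2)
}
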