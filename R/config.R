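#' Run configuration
#'
#' Bundles every tunable constant of the pipeline in one validated object.
#' Defaults encode the analysis conventions: a July--October fire season and
#' February--April spring, a 660 km spatial-weights cutoff, a plot expansion
#' area of 6000 acres (2428.1 ha), a 15-year observation window for
#' annualizing observed fire incidence, a biomass carbon fraction of 0.5 and
#' the CO2:C mass ratio 44/12.
#'
#' @param fire_season_months integer months defining the fire season.
#' @param spring_months integer months defining spring.
#' @param cutoff_km spatial-weights distance cutoff in kilometres; pairs at
#'   or beyond this distance share no edge.
#' @param plot_area_ha expansion area represented by one plot, hectares.
#' @param window_years length of the observation window used to annualize
#'   observed fire incidence.
#' @param carbon_fraction fraction of dry biomass that is carbon.
#' @param co2_to_c_mass_ratio mass ratio converting carbon to CO2.
#' @param n_permutations default permutation count for Moran inference.
#' @param rng_seed integer seed recorded in artifacts.
#' @param unit_scaling named numeric vector of multiplicative factors applied
#'   to covariate columns before coefficients are applied (default identity).
#' @param row_standardize logical; row-standardize spatial lags (default) or
#'   use the unstandardized weighted sum.
#' @param transmittance_sea_level clear-sky atmospheric transmittance at sea
#'   level (dimensionless).
#' @param transmittance_per_m increase in transmittance per metre of
#'   elevation; total is capped at 1.
#' @param et_monthly_total logical; if `TRUE` (default) seasonal ET averages
#'   monthly ET totals (daily ET times days in month), otherwise daily means.
#' @param bb_fraction fraction of aboveground biomass assigned to the bole
#'   and stump pool when splitting a single biomass total.
#' @param rho_grid numeric `c(min, max, step)` for the profiled SAR search.
#' @param sar_method `"ml"` (default) profiles the concentrated Gaussian
#'   likelihood over rho (the sum-of-squares criterion plus the
#'   log-determinant correction `sum(log|1 - rho*lambda_i|)` over the lag
#'   operator's eigenvalues), which is consistent for the simultaneous SAR
#'   error process; `"ls"` profiles the raw error sum of squares, which is
#'   simpler but biased toward stronger autocorrelation.
#'
#' @return an object of class `fc_config` (a named list).
#' @export
run_config <- function(fire_season_months = 7:10,
                       spring_months = 2:4,
                       cutoff_km = 660,
                       plot_area_ha = 2428.1,
                       window_years = 15,
                       carbon_fraction = 0.5,
                       co2_to_c_mass_ratio = 44 / 12,
                       n_permutations = 999,
                       rng_seed = 1L,
                       unit_scaling = numeric(0),
                       row_standardize = TRUE,
                       transmittance_sea_level = 0.75,
                       transmittance_per_m = 2e-5,
                       et_monthly_total = TRUE,
                       bb_fraction = 0.7,
                       rho_grid = c(-1.5, 1.5, 0.01),
                       sar_method = c("ml", "ls")) {
  sar_method <- match.arg(sar_method)
  fire_season_months <- as.integer(fire_season_months)
  spring_months <- as.integer(spring_months)
  stopifnot(
    length(fire_season_months) > 0, all(fire_season_months %in% 1:12),
    length(spring_months) > 0, all(spring_months %in% 1:12)
  )
  if (length(intersect(fire_season_months, spring_months)) > 0) {
    stop("fire_season_months and spring_months must be disjoint")
  }
  if (!is.numeric(cutoff_km) || cutoff_km <= 0) stop("cutoff_km must be > 0")
  if (carbon_fraction <= 0 || carbon_fraction > 1) {
    stop("carbon_fraction must be in (0, 1]")
  }
  if (co2_to_c_mass_ratio <= 1) stop("co2_to_c_mass_ratio must be > 1")
  if (plot_area_ha <= 0) stop("plot_area_ha must be > 0")
  if (window_years <= 0) stop("window_years must be > 0")
  if (length(unit_scaling) &&
      (is.null(names(unit_scaling)) || any(names(unit_scaling) == ""))) {
    stop("unit_scaling must be a named numeric vector")
  }
  stopifnot(length(rho_grid) == 3, rho_grid[1] <= rho_grid[2], rho_grid[3] > 0)
  cfg <- list(
    fire_season_months = fire_season_months,
    spring_months = spring_months,
    cutoff_km = cutoff_km,
    plot_area_ha = plot_area_ha,
    window_years = window_years,
    carbon_fraction = carbon_fraction,
    co2_to_c_mass_ratio = co2_to_c_mass_ratio,
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    unit_scaling = unit_scaling,
    row_standardize = isTRUE(row_standardize),
    transmittance_sea_level = transmittance_sea_level,
    transmittance_per_m = transmittance_per_m,
    et_monthly_total = isTRUE(et_monthly_total),
    bb_fraction = bb_fraction,
    rho_grid = as.numeric(rho_grid),
    sar_method = sar_method
  )
  class(cfg) <- "fc_config"
  cfg
}

#' @export
print.fc_config <- function(x, ...) {
  cat("<fc_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' The file format is a minimal TOML-like `key = value` text file; vectors
#' are comma-separated, and keys absent from the file keep their defaults.
#'
#' @param path file path.
#' @param config an `fc_config` to serialize.
#' @return `read_config` returns an `fc_config`; `write_config` returns the
#'   path invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(p) length(p) < 2, logical(1))
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    if (keys[i] == "unit_scaling") {
      # entries of the form name:factor
      parts <- strsplit(v, ":", fixed = TRUE)
      us <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
      names(us) <- vapply(parts, `[[`, "", 1)
      args[[keys[i]]] <- us
    } else if (v[1] %in% c("true", "false", "TRUE", "FALSE")) {
      args[[keys[i]]] <- toupper(v[1]) == "TRUE"
    } else {
      num <- suppressWarnings(as.numeric(v))
      args[[keys[i]]] <- if (anyNA(num)) v else num
    }
  }
  do.call(run_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fc_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(tolower(as.character(v)))
    paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = ", ")
  }
  lines <- character(0)
  for (nm in names(config)) {
    v <- config[[nm]]
    if (nm == "unit_scaling") {
      if (!length(v)) next
      lines <- c(lines, paste0(nm, " = ", paste0(names(v), ":", v,
                                                 collapse = ", ")))
    } else {
      lines <- c(lines, paste0(nm, " = ", fmt(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Stable content hash of a configuration
#'
#' FNV-1a hash of the canonical serialized form; changes iff any
#' configuration field changes. Used to stamp pipeline artifacts.
#'
#' @param config an `fc_config`.
#' @return an 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "fc_config"))
  txt <- paste(vapply(names(config), function(nm) {
    paste0(nm, "=", paste(format(config[[nm]], digits = 15), collapse = ","))
  }, ""), collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # XOR and multiply by the FNV prime (0x01000193) in 16-bit halves so the
    # arithmetic stays exact in doubles without 32-bit integer overflow
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- (lo * 403 + ((hi * 403 + lo * 256) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
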