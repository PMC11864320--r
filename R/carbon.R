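# Burned area, combusted biomass and CO2 emissions under combustion
# scenarios. Per-plot accounting:
#   A            = sum_i a * p_i                      (burned area)
#   B_mortality  = sum_i a * p_i * m_i * (Bb_i + Bo_i)  (killed biomass)
#   B_combusted  = sum_i a * p_i * m_i * (Bb_i*fb + Bo_i*fo)
#   C            = carbon_fraction * (44/12) * B_combusted
# where a is the per-plot expansion area, p the annual burn probability,
# m the mortality fraction, Bb/Bo the bole-and-stump vs tops/branches/
# sapling biomass pools and fb/fo their combustion conversion fractions.

#' Annual burned area
#'
#' `A = sum(a * p)` with `a` the expansion area represented by each plot.
#'
#' @param p per-unit annual fire probabilities in `[0, 1]`.
#' @param plot_area_ha expansion area per plot, hectares.
#' @return burned area in hectares.
#' @export
burned_area <- function(p, plot_area_ha = 2428.1) {
  if (any(p < 0)) stop("negative probability")
  if (any(p > 1)) stop("probability above 1")
  sum(plot_area_ha * p)
}

#' Combusted (and mortality) biomass
#'
#' Combusted biomass is `sum(a * p * m * (Bb*fb + Bo*fo))`; the
#' pre-combustion mortality biomass (no combustion fractions) is
#' `sum(a * p * m * (Bb + Bo))`. Both are returned.
#'
#' @param p annual fire probabilities.
#' @param m mortality fractions in `[0, 1]`.
#' @param bb,bo bole-and-stump and tops/branches/sapling biomass per plot
#'   (any consistent mass unit).
#' @param fb,fo combustion conversion fractions in `[0, 1]` for the two
#'   pools.
#' @param plot_area_ha expansion area per plot.
#' @return list with `combusted` and `mortality` (same units as `bb`/`bo`
#'   times area).
#' @export
combusted_biomass <- function(p, m, bb, bo, fb, fo, plot_area_ha = 2428.1) {
  if (fb < 0 || fb > 1 || fo < 0 || fo > 1) {
    stop("combustion fractions must be in [0, 1]")
  }
  if (any(p < 0) || any(m < 0) || any(bb < 0) || any(bo < 0)) {
    stop("probabilities and masses must be nonnegative")
  }
  apm <- plot_area_ha * p * m
  list(
    combusted = sum(apm * (bb * fb + bo * fo)),
    mortality = sum(apm * (bb + bo))
  )
}

#' CO2 emissions from combusted biomass
#'
#' `C = carbon_fraction * (44/12) * combusted`: half the dry biomass is
#' carbon, and each unit of carbon mass corresponds to 44/12 units of CO2
#' mass. With the defaults `C = (11/6) * combusted`.
#'
#' @param combusted combusted biomass mass (nonnegative).
#' @param config an [run_config()] supplying `carbon_fraction` and
#'   `co2_to_c_mass_ratio`.
#' @return CO2 mass in the same units.
#' @export
co2_emissions <- function(combusted, config = run_config()) {
  if (any(combusted < 0)) stop("combusted biomass must be nonnegative")
  config$carbon_fraction * config$co2_to_c_mass_ratio * combusted
}

#' The default combustion scenario grid
#'
#' Twelve scenarios: three probability sources (AVG historical county
#' means, ECP model predictions at county-by-ecoregion units, PLT model
#' predictions at plots) crossed with four combustion-rate levels
#' (low `fb=0.05, fo=0.5`; med `fb=0.3, fo=0.8`; high `fb=0.46, fo=0.92`;
#' cats `fb=0.8, fo=1`). AVG scenarios use the historical mean mortality,
#' ECP and PLT the per-plot model predictions.
#'
#' @return data frame with columns `name`, `prob_source`, `mort_source`,
#'   `fb`, `fo`.
#' @export
default_scenarios <- function() {
  levels <- data.frame(
    suffix = c("low", "med", "high", "cats"),
    fb = c(0.05, 0.30, 0.46, 0.80),
    fo = c(0.50, 0.80, 0.92, 1.00),
    stringsAsFactors = FALSE
  )
  fam <- data.frame(
    prob_source = c("AVG", "ECP", "PLT"),
    mort_source = c("AVG", "model", "model"),
    stringsAsFactors = FALSE
  )
  out <- merge(fam, levels, by = NULL)
  out$name <- paste(out$prob_source, out$suffix, sep = "_")
  ord <- order(match(out$prob_source, fam$prob_source),
               match(out$suffix, levels$suffix))
  out <- out[ord, c("name", "prob_source", "mort_source", "fb", "fo")]
  rownames(out) <- NULL
  out
}

#' Run the emission scenario grid
#'
#' For each scenario row the probability and mortality sources are looked
#' up on `records` as columns `prob_<source>` (lower case: `prob_avg`,
#' `prob_ecp`, `prob_plt`) and `mort_<source>` (`mort_avg`, `mort_model`),
#' and the burned-area / biomass / CO2 ledger is evaluated. Burned area and
#' total biomass in the burn area depend only on the probability source, so
#' they repeat within each scenario family.
#'
#' @param records data frame with per-plot probability and mortality
#'   columns plus `Bb` and `Bo` biomass pools.
#' @param scenarios scenario data frame as from [default_scenarios()]
#'   (columns `name`, `prob_source`, `mort_source`, `fb`, `fo`).
#' @param config an [run_config()].
#' @param mass_scale multiplicative factor applied to biomass-derived
#'   columns (e.g. to express results in MMt); default 1.
#' @return data frame, one row per scenario: `scenario`, `fb`, `fo`,
#'   `burned_area_ha`, `biomass_burn_area`, `mortality_biomass`,
#'   `combusted_biomass`, `co2`.
#' @export
run_scenarios <- function(records, scenarios = default_scenarios(),
                          config = run_config(), mass_scale = 1) {
  need <- c("Bb", "Bo")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  a <- config$plot_area_ha
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    pcol <- paste0("prob_", tolower(sc$prob_source))
    mcol <- paste0("mort_", tolower(sc$mort_source))
    if (is.null(records[[pcol]])) {
      stop(sprintf("scenario '%s': missing probability column '%s'",
                   sc$name, pcol))
    }
    if (is.null(records[[mcol]])) {
      stop(sprintf("scenario '%s': missing mortality column '%s'",
                   sc$name, mcol))
    }
    p <- records[[pcol]]
    m <- records[[mcol]]
    bm <- combusted_biomass(p, m, records$Bb, records$Bo, sc$fb, sc$fo, a)
    data.frame(
      scenario = sc$name,
      fb = sc$fb, fo = sc$fo,
      burned_area_ha = burned_area(p, a),
      biomass_burn_area = sum(a * p * (records$Bb + records$Bo)) * mass_scale,
      mortality_biomass = bm$mortality * mass_scale,
      combusted_biomass = bm$combusted * mass_scale,
      co2 = co2_emissions(bm$combusted, config) * mass_scale,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
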