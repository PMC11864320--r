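# End-to-end pipeline: simulate -> features -> diagnostics -> SAR fits ->
# predictions -> emission scenarios, with artifacts written to disk.

.fc_fit_to_table <- function(fit) {
  data.frame(
    term = c("Intercept", names(fit$beta), names(fit$delta), "rho"),
    coefficient = c(fit$alpha, unname(fit$beta), unname(fit$delta), fit$rho),
    std_error = c(fit$se["(Intercept)"], fit$se[names(fit$beta)],
                  if (length(fit$delta)) fit$se[names(fit$delta)], NA),
    stringsAsFactors = FALSE
  )
}

#' Run the full pipeline on a synthetic landscape
#'
#' Executes, in order: plot simulation; county-by-ecoregion aggregation;
#' Moran diagnostics of the fire field at plot and unit level; a naive OLS
#' baseline and the SAR fit of fire incidence on aggregate units; the SAR
#' fit of the mortality fraction on burned plots; plug-in predictions at
#' plot and unit level (annualized by the configured window length);
#' the 12-scenario emission grid; and a gridded export of the plot-level
#' risk surface. Six artifacts are written under `out_dir`, each stamped
#' with the seed and configuration hash: `plots.csv`,
#' `fire_coefficients.csv`, `treebio_coefficients.csv`, `diagnostics.json`,
#' `emissions.csv`, `risk_surface.asc`.
#'
#' @param config an [run_config()].
#' @param out_dir output directory (created if needed).
#' @param n_plots number of synthetic plots.
#' @param profile a [calibration_profile()].
#' @param seed integer seed (defaults to `config$rng_seed`).
#' @param eliminate logical; run backward elimination of interaction terms
#'   on the fire model (slower; default `FALSE`).
#' @return invisibly, a list with the in-memory results (`plots`, `units`,
#'   `fire_fit`, `treebio_fit`, `diagnostics`, `emissions`, `artifacts`).
#' @export
run_full <- function(config = run_config(), out_dir = tempfile("firecarb_"),
                     n_plots = 2000, profile = calibration_profile(),
                     seed = config$rng_seed, eliminate = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  plots <- stage("simulate",
                 generate_plots(n_plots, profile, seed, config))
  units <- stage("aggregate", aggregate_county_ecoregion(plots))

  uw <- stage("weights", build_weights(units[c("lon", "lat")],
                                       config$cutoff_km))
  pw <- stage("weights", build_weights(plots[c("lon", "lat")],
                                       config$cutoff_km))

  diag_list <- stage("diagnose", {
    plot_moran <- morans_i_test(plots$FIRE, pw,
                                n_perm = config$n_permutations,
                                seed = seed)
    unit_moran <- morans_i_test(units$FIRE, uw,
                                n_perm = config$n_permutations,
                                seed = seed)
    list(plot_fire = plot_moran, unit_fire = unit_moran)
  })

  fire_spec <- fire_model_spec()
  fire_res <- stage("fit", {
    if (eliminate) {
      el <- backward_eliminate(units, fire_spec, uw, config)
      fire_spec <- el$spec
      el$fit
    } else {
      fit_sar(units, fire_spec, uw, config)
    }
  })
  ols_res <- stage("fit", {
    x <- .fc_term_matrix(units, c(.fc_beta_terms(fire_spec),
                                  fire_spec$deltas))
    stats::lm.fit(cbind(1, x), units$FIRE)$residuals
  })
  diag_list$ols_residual_moran <-
    morans_i_test(ols_res, uw, config$n_permutations, seed)
  diag_list$sar_residual_moran <-
    morans_i_test(fire_res$residuals, uw, config$n_permutations, seed)

  burned <- plots[plots$FIRE == 1, , drop = FALSE]
  bw <- stage("weights", build_weights(burned[c("lon", "lat")],
                                       config$cutoff_km))
  treebio_res <- stage("fit",
                       fit_sar(burned, treebio_model_spec(), bw, config))

  preds <- stage("predict", {
    wy <- config$window_years
    # fire risk at plots (PLT) and at aggregate units mapped back (ECP);
    # window-scale linear predictors are annualized by the window length
    plot_lag <- spatial_lag(plots$FIRE, pw,
                            row_standardize = config$row_standardize)
    p_plt <- predict_response(fire_res, plots, pw, plot_lag, config)
    unit_lag <- spatial_lag(units$FIRE, uw,
                            row_standardize = config$row_standardize)
    p_ecp_unit <- predict_response(fire_res, units, uw, unit_lag, config)
    key_u <- paste(units$county_id, units$ecoregion_id)
    key_p <- paste(plots$county_id, plots$ecoregion_id)
    p_ecp <- p_ecp_unit$prob[match(key_p, key_u)]
    # historical county mean incidence (AVG)
    cmean <- tapply(plots$FIRE, plots$county_id, mean)
    p_avg <- as.numeric(cmean[plots$county_id])
    # mortality: model prediction at every plot, lag of the observed
    # mortality field (zero off burned plots) as the plug-in lag
    m_obs <- ifelse(is.na(plots$TREELOSS), 0, plots$TREELOSS)
    m_lag <- spatial_lag(m_obs, pw,
                         row_standardize = config$row_standardize)
    m_model <- predict_response(treebio_res, plots, pw, m_lag, config)
    data.frame(
      prob_plt = p_plt$prob / wy,
      prob_ecp = p_ecp / wy,
      prob_avg = p_avg / wy,
      mort_model = m_model$prob,
      mort_avg = mean(burned$TREELOSS)
    )
  })
  plots <- cbind(plots, preds)

  emissions <- stage("emissions",
                     run_scenarios(plots, default_scenarios(), config))

  grid_path <- file.path(out_dir, "risk_surface.asc")
  stage("export-grid",
        export_grid(plots, value_col = "prob_plt", cell_deg = 0.5,
                    path = grid_path))

  stamp <- list(seed = seed, config_hash = config_hash(config),
                n_plots = n_plots)
  diagnostics <- c(stamp, list(
    moran_plot_fire = diag_list$plot_fire,
    moran_unit_fire = diag_list$unit_fire,
    moran_ols_residuals = diag_list$ols_residual_moran,
    moran_sar_residuals = diag_list$sar_residual_moran,
    fire_fit = list(rho = fire_res$rho, rmse = fire_res$rmse,
                    fit_index = fire_res$fit_index, n = fire_res$n),
    treebio_fit = list(rho = treebio_res$rho, rmse = treebio_res$rmse,
                       fit_index = treebio_res$fit_index, n = treebio_res$n)
  ))

  paths <- list(
    plots = file.path(out_dir, "plots.csv"),
    fire_coefficients = file.path(out_dir, "fire_coefficients.csv"),
    treebio_coefficients = file.path(out_dir, "treebio_coefficients.csv"),
    diagnostics = file.path(out_dir, "diagnostics.json"),
    emissions = file.path(out_dir, "emissions.csv"),
    grid = grid_path
  )
  write_plot_table(plots, paths$plots)
  utils::write.csv(.fc_fit_to_table(fire_res), paths$fire_coefficients,
                   row.names = FALSE)
  utils::write.csv(.fc_fit_to_table(treebio_res),
                   paths$treebio_coefficients, row.names = FALSE)
  jsonlite::write_json(diagnostics, paths$diagnostics, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  utils::write.csv(emissions, paths$emissions, row.names = FALSE)

  invisible(list(plots = plots, units = units, fire_fit = fire_res,
                 treebio_fit = treebio_res, diagnostics = diagnostics,
                 emissions = emissions, artifacts = paths))
}

#' Export plot predictions as an ESRI ASCII grid
#'
#' Bins plot values to square cells (mean per cell) and writes the
#' human-readable ESRI ASCII raster format; cells without plots get the
#' nodata marker.
#'
#' @param records data frame with `lon`, `lat` and the value column.
#' @param value_col name of the value column (values expected in `[0, 1]`).
#' @param cell_deg cell size in degrees (`> 0`).
#' @param path output file path.
#' @param nodata nodata marker.
#' @return the path, invisibly; the grid matrix is attached as attribute
#'   `grid`.
#' @export
export_grid <- function(records, value_col, cell_deg, path,
                        nodata = -9999) {
  if (nrow(records) < 1) stop("need at least one record")
  if (cell_deg <= 0) stop("cell size must be positive")
  v <- records[[value_col]]
  if (is.null(v)) stop("missing value column: ", value_col)
  x0 <- floor(min(records$lon) / cell_deg) * cell_deg
  y0 <- floor(min(records$lat) / cell_deg) * cell_deg
  ix <- floor((records$lon - x0) / cell_deg) + 1L
  iy <- floor((records$lat - y0) / cell_deg) + 1L
  ncols <- max(ix)
  nrows <- max(iy)
  g <- matrix(nodata, nrows, ncols)
  sums <- tapply(v, list(iy, ix), mean)
  g[cbind(as.integer(rep(rownames(sums), ncol(sums))),
          as.integer(rep(colnames(sums), each = nrow(sums))))] <-
    ifelse(is.na(as.vector(sums)), nodata, as.vector(sums))
  lines <- c(
    sprintf("ncols %d", ncols),
    sprintf("nrows %d", nrows),
    sprintf("xllcorner %.10g", x0),
    sprintf("yllcorner %.10g", y0),
    sprintf("cellsize %.10g", cell_deg),
    sprintf("NODATA_value %g", nodata),
    # ESRI ASCII rows run north to south
    vapply(nrows:1, function(r) {
      paste(format(g[r, ], digits = 8, trim = TRUE, scientific = FALSE),
            collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  out <- invisible(path)
  attr(out, "grid") <- g
  out
}
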