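# Seasonal climate covariates: solar geometry, modified-Hargreaves potential
# evapotranspiration, and fire-season / spring aggregation.

.fc_days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.fc_month_mid_doy <- cumsum(c(0, .fc_days_in_month[-12])) + 15

#' Incident solar radiation for a month's midpoint day
#'
#' Daily-mean incident shortwave radiation on a (possibly tilted) plot
#' surface: the standard closed-form extraterrestrial radiation from
#' latitude and day of year, times an elevation-adjusted clear-sky
#' transmittance, times a slope/aspect tilt factor. The tilt factor is the
#' solar-noon incidence ratio `cos(theta_tilted) / cos(theta_flat)` with the
#' sun on the equatorward meridian, clamped to be nonnegative; a flat
#' surface has tilt factor exactly 1.
#'
#' @param latitude degrees, positive north.
#' @param month integer 1..12; the month is represented by its midpoint day.
#' @param slope surface slope in degrees, `0 <= slope < 90`.
#' @param aspect surface aspect in degrees clockwise from north.
#' @param elevation metres above sea level.
#' @param transmittance atmospheric transmittance in (0, 1]; if `NULL`
#'   (default) it is computed from the configured sea-level value plus the
#'   per-metre elevation adjustment, capped at 1.
#' @param config an [run_config()].
#' @return incident radiation in MJ/m^2/day. Returns 0 with a warning for a
#'   polar-night month.
#' @export
solar_radiation <- function(latitude, month, slope = 0, aspect = 180,
                            elevation = 0, transmittance = NULL,
                            config = run_config()) {
  stopifnot(all(month %in% 1:12), all(slope >= 0), all(slope < 90),
            all(abs(latitude) <= 90))
  if (is.null(transmittance)) {
    transmittance <- pmin(1, config$transmittance_sea_level +
                            config$transmittance_per_m * elevation)
  }
  stopifnot(all(transmittance > 0), all(transmittance <= 1))
  doy <- .fc_month_mid_doy[month]
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  polar_night <- x >= 1
  polar_day <- x <= -1
  ws <- acos(pmin(1, pmax(-1, x)))
  gsc <- 0.0820 # MJ/m^2/min
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  ra <- pmax(ra, 0)
  if (any(polar_night)) {
    warning("polar night: extraterrestrial radiation is 0", call. = FALSE)
    ra[polar_night] <- 0
  }
  # noon incidence tilt factor; sun azimuth 180 deg (N hemisphere) / 0 (S)
  zen <- abs(phi - delta)
  sun_az <- ifelse(phi >= delta, pi, 0)
  beta <- slope * pi / 180
  gam <- aspect * pi / 180
  cos_tilt <- cos(beta) * cos(zen) + sin(beta) * sin(zen) * cos(gam - sun_az)
  tilt <- ifelse(cos(zen) > 0, pmax(cos_tilt, 0) / cos(zen), 1)
  tilt[polar_day & slope == 0] <- 1
  ra * transmittance * tilt
}

#' Modified-Hargreaves potential evapotranspiration
#'
#' `ET = 0.0135 * (Tmean + 17.78) * Ra * 238.80 / (595.5 - 0.55 * Tmean)`
#' with `Tmean = (tmax + tmin) / 2` and `Ra` the incident radiation in
#' MJ/m^2/day; the temperature-dependent divisor is the latent heat of
#' vaporization in cal/g, so the 238.80 constant converts MJ/m^2 to mm of
#' evaporated water. Negative values (very cold months) clamp to 0.
#'
#' @param tmax,tmin monthly maximum and minimum temperature, degrees C.
#' @param ra incident solar radiation, MJ/m^2/day.
#' @return potential ET in mm/day.
#' @export
hargreaves_et <- function(tmax, tmin, ra) {
  stopifnot(all(tmax >= tmin), all(ra >= 0))
  tmean <- (tmax + tmin) / 2
  if (any(tmean >= 595.5 / 0.55)) {
    stop("non-physical temperature: mean >= 595.5 / 0.55 degrees C")
  }
  et <- 0.0135 * (tmean + 17.78) * ra * 238.80 / (595.5 - 0.55 * tmean)
  pmax(et, 0)
}

#' Derive the six seasonal regression covariates
#'
#' Appends (or overwrites) the covariate columns `PPT`, `TEMP`, `ET`
#' (fire season) and `PPTs`, `TEMPs`, `ETs` (spring) on a plot table:
#' seasonal means of monthly precipitation and of monthly maximum
#' temperature, and the seasonal mean of monthly ET, where monthly ET is
#' the daily modified-Hargreaves ET at the month midpoint times the days in
#' the month (a monthly total, the default) or the daily mean if
#' `config$et_monthly_total` is `FALSE`. Solar radiation uses each plot's
#' latitude, slope, aspect and elevation.
#'
#' @param records plot-table data frame (see [read_plot_table()]).
#' @param config an [run_config()]; defines the month sets.
#' @return `records` with the six covariate columns filled in.
#' @export
seasonal_aggregate <- function(records, config = run_config()) {
  fs <- config$fire_season_months
  sp <- config$spring_months
  if (length(fs) == 0 || length(sp) == 0) stop("season month set is empty")
  ppt <- as.matrix(records[month_cols("ppt")])
  tmax <- as.matrix(records[month_cols("tmax")])
  tmin <- as.matrix(records[month_cols("tmin")])
  if (anyNA(ppt) || anyNA(tmax) || anyNA(tmin)) {
    stop("monthly climate vectors must be complete")
  }
  et_month <- matrix(0, nrow(records), 12)
  for (m in 1:12) {
    ra <- solar_radiation(records$lat, m, records$slope, records$aspect,
                          records$elevation, config = config)
    etd <- hargreaves_et(tmax[, m], tmin[, m], ra)
    et_month[, m] <- if (config$et_monthly_total) {
      etd * .fc_days_in_month[m]
    } else {
      etd
    }
  }
  records$PPT <- rowMeans(ppt[, fs, drop = FALSE])
  records$TEMP <- rowMeans(tmax[, fs, drop = FALSE])
  records$ET <- rowMeans(et_month[, fs, drop = FALSE])
  records$PPTs <- rowMeans(ppt[, sp, drop = FALSE])
  records$TEMPs <- rowMeans(tmax[, sp, drop = FALSE])
  records$ETs <- rowMeans(et_month[, sp, drop = FALSE])
  records
}

#' Pearson correlation coefficient
#'
#' `cov(x, y) / (sd(x) * sd(y))`. Provided as the diagnostic used to audit
#' inter-covariate correlation structure.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
}
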