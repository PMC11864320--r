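# Plot-table schema: one row per inventory plot. Monthly climate normals are
# stored as 12 suffixed columns per variable (ppt_01..ppt_12 etc.).

.fc_id_cols <- c("plot_id", "county_id", "ecoregion_id")
.fc_num_cols <- c("lon", "lat", "elevation", "slope", "aspect",
                  "OWN", "AGE", "AGBIO", "Bb", "Bo", "FIRE", "TREELOSS")

#' Monthly column names of the plot table
#' @param prefix one of "ppt", "tmax", "tmin".
#' @return 12 column names, `prefix_01` .. `prefix_12`.
#' @export
month_cols <- function(prefix) sprintf("%s_%02d", prefix, 1:12)

.fc_required_cols <- function() {
  c(.fc_id_cols, .fc_num_cols,
    month_cols("ppt"), month_cols("tmax"), month_cols("tmin"))
}

#' Validate plot records against the data-model invariants
#'
#' Checks, per row: `FIRE` and `OWN` binary; `TREELOSS` present in `[0, 1]`
#' exactly when `FIRE = 1` (mortality is undefined off burned plots and
#' mandatory on them); `AGE`, `AGBIO`, `Bb`, `Bo` nonnegative; latitude in
#' `[-90, 90]`; monthly `tmax >= tmin`.
#'
#' @param df data frame with the plot-table schema.
#' @return a list with `ok` (logical per row) and `reasons` (character,
#'   `NA` for valid rows).
#' @export
validate_plot_records <- function(df) {
  n <- nrow(df)
  reasons <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- msg
  }
  isna <- function(x) is.na(x)
  flag(!(df$FIRE %in% c(0, 1)), "FIRE must be 0 or 1")
  flag(!(df$OWN %in% c(0, 1)), "OWN must be 0 or 1")
  flag(df$FIRE == 1 & isna(df$TREELOSS),
       "TREELOSS missing on a burned plot (FIRE = 1)")
  flag(df$FIRE == 0 & !isna(df$TREELOSS),
       "TREELOSS present on an unburned plot (FIRE = 0)")
  flag(!isna(df$TREELOSS) & (df$TREELOSS < 0 | df$TREELOSS > 1),
       "TREELOSS outside [0, 1]")
  flag(isna(df$AGE) | df$AGE < 0, "AGE must be >= 0")
  flag(isna(df$AGBIO) | df$AGBIO < 0, "AGBIO must be >= 0")
  flag(isna(df$Bb) | df$Bb < 0, "Bb must be >= 0")
  flag(isna(df$Bo) | df$Bo < 0, "Bo must be >= 0")
  flag(isna(df$lat) | df$lat < -90 | df$lat > 90, "lat outside [-90, 90]")
  flag(isna(df$lon), "lon missing")
  tmax <- as.matrix(df[month_cols("tmax")])
  tmin <- as.matrix(df[month_cols("tmin")])
  ppt <- as.matrix(df[month_cols("ppt")])
  flag(rowSums(is.na(ppt) | ppt < 0) > 0, "monthly ppt missing or negative")
  flag(rowSums(is.na(tmax) | is.na(tmin)) > 0, "monthly temperature missing")
  flag(rowSums(!is.na(tmax) & !is.na(tmin) & tmax < tmin) > 0,
       "monthly tmax < tmin")
  list(ok = is.na(reasons), reasons = reasons)
}

#' Read a plot table from CSV
#'
#' Reads an RFC-4180 CSV with a header naming every plot-record field (the
#' monthly normals as 12 suffixed columns each). Rows that violate the
#' record invariants are dropped with a warning naming the row numbers and
#' the violated rule; schema-level problems (missing columns, unparseable
#' numbers, an empty file) are errors. An empty `TREELOSS` field denotes a
#' missing value, which is required when `FIRE = 0` and rejected when
#' `FIRE = 1`.
#'
#' @param path CSV file path.
#' @param config an [run_config()] object (reserved for schema options).
#' @return a `data.frame` of validated plot records, with an attribute
#'   `rejected` holding the dropped row numbers and reasons. Extra columns
#'   beyond the core schema are passed through untouched.
#' @export
read_plot_table <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("plot table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("plot table is empty: ", path)
  for (cc in intersect(.fc_id_cols, names(df))) {
    df[[cc]] <- as.character(df[[cc]])
  }
  missing <- setdiff(.fc_required_cols(), names(df))
  if (length(missing)) {
    stop("plot table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  numcols <- setdiff(.fc_required_cols(), .fc_id_cols)
  for (cc in numcols) {
    if (!is.numeric(df[[cc]])) {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(!is.na(df[[cc]]) & df[[cc]] != "" & is.na(v))
      if (length(bad)) {
        stop(sprintf("unparseable numeric in column '%s' at row(s) %s",
                     cc, paste(utils::head(bad, 5), collapse = ", ")))
      }
      df[[cc]] <- v
    }
  }
  chk <- validate_plot_records(df)
  rejected <- data.frame(row = which(!chk$ok),
                         reason = chk$reasons[!chk$ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf(
      "rejected %d row(s): %s", nrow(rejected),
      paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
            collapse = "; ")), call. = FALSE)
  }
  out <- df[chk$ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a plot table to CSV
#'
#' Emits a table that [read_plot_table()] reads back identically. Missing
#' `TREELOSS` values (unburned plots) are written as empty fields.
#'
#' @param records nonempty data frame of plot records.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_plot_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a nonempty data frame")
  }
  missing <- setdiff(.fc_required_cols(), names(records))
  if (length(missing)) {
    stop("records are missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  ok <- tryCatch(
    utils::write.csv(records, path, row.names = FALSE, na = "",
                     quote = FALSE),
    error = function(e) stop("cannot write plot table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}
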