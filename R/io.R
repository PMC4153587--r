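# Tabular text readers and writers for all pipeline inputs and outputs.

# read.csv wrapper that reports the offending data line on parse failures.
.read_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
}

.numeric_column <- function(x, name, path) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0L)
    stop(sprintf("%s: cannot parse %s value '%s' at line %d",
                 path, name, x[bad[1L]], bad[1L] + 1L))
  out
}

#' Read a daily temperature table
#'
#' Expects a delimited text file with columns `date` (ISO 8601) and
#' `temperature` (degC). Duplicate dates, unparseable values and
#' temperatures outside the instrument range are errors naming the
#' offending line or date.
#'
#' @param path File path.
#' @param sep Field delimiter (default `","`; no auto-detection).
#' @return A [temperature_series()].
#' @export
read_temperature <- function(path, sep = ",") {
  df <- .read_table(path, sep)
  miss <- setdiff(c("date", "temperature"), names(df))
  if (length(miss) > 0L)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  day <- as.Date(df$date)
  if (anyNA(day))
    stop(sprintf("%s: cannot parse date '%s' at line %d", path,
                 df$date[which(is.na(day))[1L]], which(is.na(day))[1L] + 1L))
  temperature_series(day, .numeric_column(df$temperature, "temperature", path))
}

#' Read sub-daily temperature records and aggregate to daily means
#'
#' Expects columns `timestamp` and `temperature`; rows are averaged per
#' calendar day via [aggregate_daily_means()].
#'
#' @inheritParams read_temperature
#' @param min_records Minimum records per retained day.
#' @return A [temperature_series()].
#' @export
read_subdaily_temperature <- function(path, sep = ",", min_records = 1L) {
  df <- .read_table(path, sep)
  miss <- setdiff(c("timestamp", "temperature"), names(df))
  if (length(miss) > 0L)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  aggregate_daily_means(df$timestamp,
                        .numeric_column(df$temperature, "temperature", path),
                        min_records = min_records)
}

#' Read an aphid count panel
#'
#' Expects columns `year`, `plot`, `date`, `aphids`, `tillers`. Zero-tiller
#' rows, negative counts and duplicate (year, plot, date) keys are errors.
#'
#' @inheritParams read_temperature
#' @return A validated count panel data frame.
#' @export
read_counts <- function(path, sep = ",") {
  df <- .read_table(path, sep)
  miss <- setdiff(c("year", "plot", "date", "aphids", "tillers"), names(df))
  if (length(miss) > 0L)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df$aphids <- .numeric_column(df$aphids, "aphids", path)
  df$tillers <- .numeric_column(df$tillers, "tillers", path)
  .validate_panel(df)
}

#' Write pipeline tables as CSV
#'
#' Plain-delimited writers for every table the package emits, so that all
#' outputs round-trip losslessly through the matching readers:
#' `write_temperature()` / `write_counts()` mirror [read_temperature()] /
#' [read_counts()]; `write_fit_table()` writes the coefficient table of a
#' fit (Coefficient, Estimate, Standard error, p-value);
#' `write_lag_profile()` writes the (L, AIC) profile; `write_lag_curve()`
#' writes the (lag, estimate, lower, upper) band table.
#'
#' @param series,panel,fit,profile,curve The object to write.
#' @param path Output file path.
#' @param intercept Keep the intercept row in the fit table (default
#'   `FALSE`).
#' @return `path`, invisibly.
#' @export
write_temperature <- function(series, path) {
  utils::write.csv(data.frame(date = format(series$day),
                              temperature = series$t_mean),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature
#' @export
write_counts <- function(panel, path) {
  utils::write.csv(data.frame(year = panel$year, plot = panel$plot,
                              date = format(as.Date(panel$date)),
                              aphids = panel$aphids, tillers = panel$tillers),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature
#' @export
write_fit_table <- function(fit, path, intercept = FALSE) {
  utils::write.csv(coef_table(fit, intercept = intercept), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature
#' @export
write_lag_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature
#' @export
write_lag_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `temperature.csv` and `counts.csv` in the formats the readers
#' consume, plus `truth.csv` with the generator's ground-truth table.
#'
#' @param dataset A [simulate_panel()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_temperature(dataset$temperature, file.path(dir, "temperature.csv"))
  if (!is.null(dataset$panel))
    write_counts(dataset$panel, file.path(dir, "counts.csv"))
  truth <- dataset$truth
  truth$start_day <- format(as.Date(truth$start_day))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
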