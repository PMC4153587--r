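# Daily temperature series and degree-day covariates.

#' Construct a validated daily temperature series
#'
#' A temperature series is a data frame with one row per calendar day and a
#' daily mean air temperature in degrees Celsius. Construction sorts the rows
#' by date, rejects duplicate days and enforces the instrument plausibility
#' range of -50 to +110 degrees C. Days may be non-contiguous; gaps are never
#' interpolated and can be listed with [temperature_gaps()].
#'
#' @param day Dates (or anything `as.Date()` accepts, e.g. ISO 8601 strings).
#' @param t_mean Numeric daily mean temperatures, degrees C.
#' @return A data frame of class `temperature_series` with columns `day`
#'   (Date) and `t_mean` (numeric), sorted by day.
#' @seealso [aggregate_daily_means()] to build one from sub-daily records,
#'   [dd5()] and [dd05()] for degree-day sums over a [lag_window()].
#' @export
#' @examples
#' ts <- temperature_series(c("2001-01-01", "2001-01-02"), c(3.5, 6.2))
#' dd5(ts, lag_window("2001-01-03", 2))
temperature_series <- function(day, t_mean) {
  day <- as.Date(day)
  if (length(day) == 0L) stop("empty temperature series")
  if (length(day) != length(t_mean))
    stop("`day` and `t_mean` must have the same length")
  if (anyNA(day)) stop("unparseable or missing dates in temperature series")
  t_mean <- as.numeric(t_mean)
  if (any(!is.finite(t_mean)))
    stop("non-finite temperature at ", day[which(!is.finite(t_mean))[1L]])
  bad <- t_mean < -50 | t_mean > 110
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "temperature %.2f degC on %s outside the instrument range [-50, 110]",
      t_mean[i], format(day[i])))
  }
  if (anyDuplicated(day)) {
    d <- day[duplicated(day)][1L]
    stop("duplicate date in temperature series: ", format(d))
  }
  o <- order(day)
  structure(data.frame(day = day[o], t_mean = t_mean[o]),
            class = c("temperature_series", "data.frame"))
}

#' @export
print.temperature_series <- function(x, ...) {
  gaps <- temperature_gaps(x)
  cat(sprintf("<temperature_series> %d days, %s to %s (%d missing day%s)\n",
              nrow(x), format(x$day[1L]), format(x$day[nrow(x)]),
              length(gaps), if (length(gaps) == 1L) "" else "s"))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' List days missing from a temperature series
#'
#' Returns the calendar days strictly between the first and last day of the
#' series that have no record. Gaps are reported, never filled.
#'
#' @param series A [temperature_series()].
#' @return A Date vector (possibly empty).
#' @export
temperature_gaps <- function(series) {
  full <- seq(series$day[1L], series$day[nrow(series)], by = "day")
  full[!full %in% series$day]
}

#' Aggregate sub-daily temperature records to daily means
#'
#' Computes the arithmetic mean of all records falling on each calendar day,
#' the convention used for station records logged at sub-daily intervals
#' (e.g. every 15 minutes). Days with fewer than `min_records` records are
#' dropped and reported, so thin days surface as explicit gaps rather than
#' noisy means.
#'
#' @param timestamp Record timestamps (`POSIXct`, `Date`, or strings
#'   `as.POSIXct()` accepts).
#' @param temp Temperatures at each timestamp, degrees C.
#' @param min_records Minimum number of records a day needs to be retained.
#' @return A [temperature_series()]. Dropped days (if any) are attached as
#'   attribute `"dropped_days"` and announced via `message()`.
#' @export
aggregate_daily_means <- function(timestamp, temp, min_records = 1L) {
  if (length(timestamp) == 0L) stop("no temperature records to aggregate")
  if (length(timestamp) != length(temp))
    stop("`timestamp` and `temp` must have the same length")
  if (inherits(timestamp, "Date")) {
    day <- timestamp
  } else {
    tt <- as.POSIXct(timestamp, tz = "UTC")
    if (anyNA(tt)) stop("unparseable timestamp at record ",
                        which(is.na(tt))[1L])
    day <- as.Date(tt, tz = "UTC")
  }
  temp <- as.numeric(temp)
  bad <- !is.finite(temp) | temp < -50 | temp > 110
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("record %d (%s): temperature %s outside [-50, 110] degC",
                 i, format(day[i]), format(temp[i])))
  }
  f <- factor(day)
  n <- tabulate(f)
  m <- as.vector(tapply(temp, f, mean))
  keep <- n >= min_records
  dropped <- as.Date(levels(f)[!keep])
  if (length(dropped) > 0L)
    message(length(dropped), " day(s) dropped with fewer than ",
            min_records, " records: ", paste(format(dropped), collapse = ", "))
  if (!any(keep)) stop("no day meets `min_records`")
  out <- temperature_series(as.Date(levels(f)[keep]), m[keep])
  attr(out, "dropped_days") <- dropped
  out
}

#' Define a pre-season lag window
#'
#' The window covers exactly `depth_L` consecutive days strictly before the
#' anchor day: `anchor_day - depth_L, ..., anchor_day - 1`. The anchor (the
#' local aphid season start) is excluded, and lags are counted backwards from
#' it: lag 1 is the day immediately before the anchor, lag `depth_L` the most
#' distant day.
#'
#' @param anchor_day The local season start date.
#' @param depth_L Positive integer window depth L, days.
#' @return An object of class `lag_window`.
#' @export
lag_window <- function(anchor_day, depth_L) {
  anchor_day <- as.Date(anchor_day)
  if (length(anchor_day) != 1L || is.na(anchor_day))
    stop("`anchor_day` must be a single valid date")
  depth_L <- as.integer(depth_L)
  if (length(depth_L) != 1L || is.na(depth_L) || depth_L < 1L)
    stop("`depth_L` must be a positive integer")
  structure(list(anchor_day = anchor_day, depth_L = depth_L),
            class = "lag_window")
}

#' @export
print.lag_window <- function(x, ...) {
  cat(sprintf("<lag_window> L = %d days: %s ... %s (anchor %s excluded)\n",
              x$depth_L, format(x$anchor_day - x$depth_L),
              format(x$anchor_day - 1L), format(x$anchor_day)))
  invisible(x)
}

#' Days covered by a lag window
#'
#' @param window A [lag_window()].
#' @return Date vector `anchor_day - depth_L ... anchor_day - 1`, ascending.
#' @export
window_days <- function(window) {
  seq(window$anchor_day - window$depth_L, by = "day",
      length.out = window$depth_L)
}

# Day-indexed cache of per-day degree-day contributions with cumulative sums,
# shared by the public degree-day functions and the design-matrix builder.
# Positions are 1-based offsets from the first day of the series; missing
# days contribute 0 and are tracked in `present`.
.dd_cache <- function(series) {
  d0 <- series$day[1L]
  n <- as.integer(series$day[nrow(series)] - d0) + 1L
  pos <- as.integer(series$day - d0) + 1L
  t <- rep(0, n)
  t[pos] <- series$t_mean
  present <- logical(n)
  present[pos] <- TRUE
  v5 <- t * (present & t > 5)
  v5x <- (t - 5) * (present & t > 5)
  v05 <- t * (present & t >= 0 & t <= 5)
  list(d0 = d0, n = n, present = present,
       v5 = v5, v5x = v5x, v05 = v05,
       c5 = cumsum(v5), c5x = cumsum(v5x), c05 = cumsum(v05),
       cpres = cumsum(present))
}

# Cumulative sum over positions (a-L)..(a-1); cs has a leading implicit 0.
.cum_window <- function(cs, a, L) {
  hi <- cs[a - 1L]
  lo <- if (a - L - 1L >= 1L) cs[a - L - 1L] else 0
  hi - lo
}

# Window temperatures in lag order (element l = day anchor - l), validated
# against the missing-day policy. Direct per-day lookup, so the public
# degree-day functions sum exactly what a naive day-by-day loop would.
.window_lag_temps <- function(series, window,
                              missing_policy = c("error", "renormalize")) {
  missing_policy <- match.arg(missing_policy)
  L <- window$depth_L
  d0 <- series$day[1L]
  if (window$anchor_day - L < d0)
    stop(sprintf(paste0(
      "window of depth %d extends before the first available day %s; ",
      "the earliest feasible anchor is %s"),
      L, format(d0), format(d0 + L)))
  if (window$anchor_day - 1L > series$day[nrow(series)])
    stop("window extends past the last available day ",
         format(series$day[nrow(series)]))
  lag_days <- window$anchor_day - seq_len(L)
  t <- series$t_mean[match(lag_days, series$day)]
  n_miss <- sum(is.na(t))
  if (n_miss > 0L && missing_policy == "error")
    stop(sprintf("%d day(s) missing from the temperature series inside the %d-day window before %s",
                 n_miss, L, format(window$anchor_day)))
  if (n_miss == L)
    stop("no temperature data inside the window before ",
         format(window$anchor_day))
  list(t = t, L = L, n_present = L - n_miss)
}

#' Degree-day sum above the 5 degree aphid development threshold (DD5)
#'
#' Sums the daily mean temperatures over the lag window on days whose mean
#' exceeds 5 degrees C (strict inequality). The default mode `"sum-above"`
#' accumulates the temperature itself on qualifying days, treating DD5
#' symmetrically with [dd05()]; mode `"excess"` accumulates the classical
#' exceedance `t - 5` instead.
#'
#' @param series A [temperature_series()].
#' @param window A [lag_window()]; every window day must be present in
#'   `series` unless `missing = "renormalize"`.
#' @param mode `"sum-above"` (default) or `"excess"`; see Details.
#' @param missing `"error"` (default) rejects windows with missing days;
#'   `"renormalize"` rescales the sum by `L / (days present)` and warns.
#' @return Degree-day sum, degC day.
#' @export
dd5 <- function(series, window, mode = c("sum-above", "excess"),
                missing = c("error", "renormalize")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  wp <- .window_lag_temps(series, window, missing)
  t <- rev(wp$t)  # calendar order, matching a day-by-day accumulation
  t <- t[!is.na(t)]
  s <- if (mode == "sum-above") sum(t[t > 5]) else sum(t[t > 5] - 5)
  if (wp$n_present < wp$L) {
    warning(sprintf("DD5 renormalized by %d/%d for missing days before %s",
                    wp$L, wp$n_present, format(window$anchor_day)))
    s <- s * wp$L / wp$n_present
  }
  s
}

#' Degree-day sum within the [0, 5] degree wheat-development interval (DD05)
#'
#' Sums the daily mean temperatures over the lag window on days whose mean
#' lies in the closed interval \[0, 5\] degrees C (both endpoints included; a
#' day at exactly 0 qualifies but contributes 0 by value). Together with the
#' strict `> 5` rule of [dd5()] this makes the two covariates disjoint: a day
#' at exactly 5 degrees contributes to DD05 only.
#'
#' @inheritParams dd5
#' @return Degree-day sum, degC day.
#' @export
dd05 <- function(series, window, missing = c("error", "renormalize")) {
  missing <- match.arg(missing)
  wp <- .window_lag_temps(series, window, missing)
  t <- rev(wp$t)  # calendar order, matching a day-by-day accumulation
  t <- t[!is.na(t)]
  s <- sum(t[t >= 0 & t <= 5])
  if (wp$n_present < wp$L) {
    warning(sprintf("DD05 renormalized by %d/%d for missing days before %s",
                    wp$L, wp$n_present, format(window$anchor_day)))
    s <- s * wp$L / wp$n_present
  }
  s
}

#' Per-lag daily DD5 contributions
#'
#' Decomposes [dd5()] into one contribution per lag: element `l` is the
#' qualifying-temperature contribution of the day `l` days before the anchor
#' (lag 1 is the day immediately before the season start, lag `depth_L` the
#' most distant day). The vector sums exactly to `dd5()` on the same window
#' and mode. These are the regressors of the distributed-lag models, where a
#' lag-varying coefficient replaces the single pooled DD5 slope.
#'
#' @inheritParams dd5
#' @param standardize If `TRUE`, divide each contribution by `depth_L`,
#'   matching the standardized covariate DD5/L used in the regressions.
#' @return Numeric vector of length `depth_L`.
#' @export
lag_contributions <- function(series, window, mode = c("sum-above", "excess"),
                              standardize = FALSE,
                              missing = c("error", "renormalize")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  wp <- .window_lag_temps(series, window, missing)
  t <- ifelse(is.na(wp$t), 0, wp$t)
  x <- if (mode == "sum-above") t * (t > 5) else (t - 5) * (t > 5)
  if (wp$n_present < wp$L) {
    warning(sprintf("lag contributions renormalized by %d/%d for missing days before %s",
                    wp$L, wp$n_present, format(window$anchor_day)))
    x <- x * wp$L / wp$n_present
  }
  if (standardize) x <- x / wp$L
  x
}
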