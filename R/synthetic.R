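# Synthetic study generator: temperatures, plot-season panels, ground truth.

#' Configuration of the synthetic study generator
#'
#' Collects every parameter of the data-generating process that the analysis
#' assumes, so each pipeline stage can be validated by parameter recovery.
#' The defaults emulate the study conditions: 24 years of weekly counts on
#' 3-6 plots, 50-300 tillers per plot and date over 6-10 weeks of aphid
#' presence, left-skewed triangular density trajectories, season starts near
#' day-of-year 143, a Central-European seasonal temperature cycle, and TSM
#' generated from the linear model with variance inversely proportional to
#' the tiller total.
#'
#' @param n_years Number of study years (default 24).
#' @param plots_per_year Integer range `c(min, max)` of plots per year
#'   (default 3-6; each year draws uniformly from the range).
#' @param first_year Calendar year of the first season (default 1987).
#' @param temp_mean,temp_amplitude Annual mean and seasonal amplitude of the
#'   daily-mean temperature, degC (defaults 8.2 and 10, a lowland
#'   Central-European station).
#' @param temp_phase Phase shift in days of the seasonal sine (default 105,
#'   putting the warmest day near mid-July).
#' @param temp_noise_sd Stationary standard deviation of the day-to-day
#'   temperature deviation, degC (default 3).
#' @param temp_ar1 AR(1) coefficient of the daily deviation (default 0.7).
#' @param mu Intercept of the TSM model, days (default 135; with the default
#'   temperature climate and `true_L = 123` this centres TSM near 7 weeks
#'   while keeping the expected TSM positive across climate realizations).
#' @param beta1 Pooled DD5/L coefficient, days per degC (default -15).
#' @param beta1_lag Optional length-`true_L` vector of lag-specific
#'   coefficients `beta_1l`; when supplied it replaces the pooled `beta1`
#'   term by `sum_l beta_1l x_l / L` (see [bimodal_lag_curve()]).
#' @param delta DD05/L coefficient, days per degC (default -20).
#' @param gamma Previous-year coefficient (default 0).
#' @param gamma_term Which previous-year summary `gamma` multiplies:
#'   `"prev_max"` (default) or `"prev_tsm"`.
#' @param sigma2 Error variance scale; a plot-season with tiller total `n`
#'   has error variance `sigma2 / n` (default 35000, i.e. a residual SD of
#'   about 5 days at a typical total of 1400 tillers).
#' @param true_L Depth of the generating lag window, days (default 123).
#' @param start_mean,start_sd Mean and SD of the season-start day-of-year
#'   (defaults 143 and 7); draws are truncated below at `true_L + 1` so the
#'   window never leaves the calendar year.
#' @param tillers Range of tillers inspected per plot and date (default
#'   50-300).
#' @param sampling_interval Days between counts (default 7, weekly).
#' @param n_weeks Range of weeks of aphid presence per plot-season
#'   (default 6-10).
#' @param peak_density Range of the year-level median peak density,
#'   aphids/tiller (default 1-60; yearly medians are drawn log-normally and
#'   clamped to this range, with plot-level scatter around them).
#' @param rise_ratio,decline_ratio Weekly geometric growth factor of the
#'   density trajectory before the peak and decline factor after it
#'   (defaults 3 and 6; the decline must be at least as fast as the rise).
#' @param start_density Density floor at the season start, aphids/tiller
#'   (default 0.1). The geometric rise is floored at this value so the first
#'   non-zero date is detectable when counts are Poisson-sampled on 50-300
#'   tillers; without it, long seasons would start below one aphid per
#'   hundred tillers and the observed season start would drift late.
#' @param poisson_counts If `TRUE` (default) aphid counts are Poisson draws
#'   around density x tillers (a sampling-realism layer); if `FALSE`, counts
#'   are deterministic (ceiling, so a positive density is never lost).
#' @param round_to_grid Round generated TSM to the sampling interval
#'   (default `TRUE`), so the density peak falls on a sampling date and TSM
#'   is recoverable exactly from the emitted counts.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 24L, plots_per_year = c(3L, 6L),
                             first_year = 1987L,
                             temp_mean = 8.2, temp_amplitude = 10,
                             temp_phase = 105, temp_noise_sd = 3,
                             temp_ar1 = 0.7,
                             mu = 135, beta1 = -15, beta1_lag = NULL,
                             delta = -20, gamma = 0,
                             gamma_term = c("prev_max", "prev_tsm"),
                             sigma2 = 35000, true_L = 123L,
                             start_mean = 143, start_sd = 7,
                             tillers = c(50L, 300L),
                             sampling_interval = 7L, n_weeks = c(6L, 10L),
                             peak_density = c(1, 60),
                             rise_ratio = 3, decline_ratio = 6,
                             start_density = 0.1,
                             poisson_counts = TRUE, round_to_grid = TRUE) {
  gamma_term <- match.arg(gamma_term)
  cfg <- list(n_years = as.integer(n_years),
              plots_per_year = as.integer(plots_per_year),
              first_year = as.integer(first_year),
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_phase = temp_phase, temp_noise_sd = temp_noise_sd,
              temp_ar1 = temp_ar1, mu = mu, beta1 = beta1,
              beta1_lag = beta1_lag, delta = delta, gamma = gamma,
              gamma_term = gamma_term, sigma2 = sigma2,
              true_L = as.integer(true_L), start_mean = start_mean,
              start_sd = start_sd, tillers = as.integer(tillers),
              sampling_interval = as.integer(sampling_interval),
              n_weeks = as.integer(n_weeks), peak_density = peak_density,
              rise_ratio = rise_ratio, decline_ratio = decline_ratio,
              start_density = start_density,
              poisson_counts = isTRUE(poisson_counts),
              round_to_grid = isTRUE(round_to_grid))
  if (cfg$n_years < 1L) stop("`n_years` must be positive")
  if (length(cfg$plots_per_year) != 2L || any(cfg$plots_per_year < 1L) ||
      diff(cfg$plots_per_year) < 0L)
    stop("`plots_per_year` must be an increasing positive range")
  if (cfg$sigma2 < 0 || cfg$temp_noise_sd < 0) stop("variances must be non-negative")
  if (abs(cfg$temp_ar1) >= 1) stop("`temp_ar1` must lie in (-1, 1)")
  if (cfg$true_L < 1L) stop("`true_L` must be positive")
  if (cfg$start_mean - cfg$true_L < 1)
    stop("`start_mean` - `true_L` must leave temperature coverage from day 1 of the year")
  if (!is.null(cfg$beta1_lag) && length(cfg$beta1_lag) != cfg$true_L)
    stop("`beta1_lag` must have length `true_L`")
  if (cfg$decline_ratio < cfg$rise_ratio)
    stop("the post-peak decline must be at least as fast as the rise")
  if (cfg$start_density < 0) stop("`start_density` must be non-negative")
  if (cfg$sampling_interval < 1L) stop("`sampling_interval` must be positive")
  structure(cfg, class = "synthetic_config")
}

#' Lag-coefficient preset with two negative pre-season windows
#'
#' Builds a `beta1_lag` vector that is zero except in two windows of
#' distinctly negative coefficients, by default at lags 50-80 and 90-110
#' days before the season start -- the bimodal shape used for power and
#' shape-recovery experiments, mimicking sensitivity periods around the
#' termination of aphid egg dormancy and egg hatching.
#'
#' @param L Lag depth (default 123).
#' @param windows List of two `c(from, to)` lag windows.
#' @param depths Coefficient value inside each window (recycled; default
#'   -40).
#' @return Numeric vector of length `L`.
#' @export
bimodal_lag_curve <- function(L = 123L,
                              windows = list(c(50L, 80L), c(90L, 110L)),
                              depths = c(-40, -40)) {
  depths <- rep_len(depths, length(windows))
  b <- numeric(L)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (w[1L] < 1L || w[2L] > L || w[1L] > w[2L]) stop("window outside 1..L")
    b[w[1L]:w[2L]] <- depths[i]
  }
  b
}

#' Simulate a daily-mean temperature series
#'
#' Daily means follow a seasonal sine plus stationary AR(1) noise:
#' `T_t = m + A sin(2 pi (t - phase) / 365.25) + e_t`. The series is
#' continuous across years, from 1 January of the first study year through
#' 31 December of the last.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed (set once at entry; omit when calling
#'   from an outer seeded simulation).
#' @return A [temperature_series()].
#' @export
simulate_temperature <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d0 <- as.Date(sprintf("%d-01-01", config$first_year))
  d1 <- as.Date(sprintf("%d-12-31", config$first_year + config$n_years - 1L))
  days <- seq(d0, d1, by = "day")
  t_cont <- as.numeric(days - d0) + 1
  seasonal <- config$temp_mean +
    config$temp_amplitude * sin(2 * pi * (t_cont - config$temp_phase) / 365.25)
  n <- length(days)
  if (config$temp_noise_sd > 0) {
    innov_sd <- config$temp_noise_sd * sqrt(1 - config$temp_ar1^2)
    eps <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    config$temp_ar1, method = "recursive"))
  } else eps <- numeric(n)
  temperature_series(days, pmin(pmax(seasonal + eps, -50), 110))
}

#' Left-skewed triangular density trajectory
#'
#' Density rises geometrically from a small positive value at `start_day`
#' to `peak_density` exactly at `start_day + tsm`, then declines faster
#' than it rose; it is zero before the start. If the nominal peak does not
#' fall on a sampling date it is shifted to the nearest one (recorded in
#' attribute `"peak_shift"`), so the maximum over the emitted dates is
#' attained at the (possibly shifted) peak and nowhere earlier.
#'
#' @param start_day Date of the first non-zero density.
#' @param tsm Days from start to peak (>= 0).
#' @param peak_density Peak density, aphids/tiller (> 0).
#' @param sampling_dates Dates at which the trajectory is evaluated.
#' @param rise_ratio,decline_ratio Weekly geometric factors (see
#'   [synthetic_config()]).
#' @param floor_density Minimum pre-peak density, aphids/tiller (default 0,
#'   the pure geometric rise). A positive floor keeps the season start above
#'   the detection scale of tiller counts; it is capped at half the peak so
#'   the maximum is still attained at the peak and nowhere earlier.
#' @return Data frame with columns `date`, `density`, attribute
#'   `"peak_shift"` (days the peak was moved to reach the grid).
#' @export
triangular_trajectory <- function(start_day, tsm, peak_density,
                                  sampling_dates, rise_ratio = 3,
                                  decline_ratio = 6, floor_density = 0) {
  if (tsm < 0) stop("`tsm` must be non-negative")
  if (peak_density <= 0) stop("`peak_density` must be positive")
  if (decline_ratio < rise_ratio)
    stop("the post-peak decline must be at least as fast as the rise")
  start_day <- as.Date(start_day)
  dates <- sort(as.Date(sampling_dates))
  nominal_peak <- start_day + tsm
  on_or_after <- dates[dates >= start_day]
  if (length(on_or_after) == 0L)
    stop("no sampling date on or after `start_day`")
  peak_day <- on_or_after[which.min(abs(as.numeric(on_or_after - nominal_peak)))]
  shift <- as.numeric(peak_day - nominal_peak)
  dt <- as.numeric(dates - peak_day)  # days relative to the peak
  floor_eff <- min(floor_density, peak_density / 2)
  density <- ifelse(dates < start_day, 0,
                    ifelse(dt <= 0,
                           pmax(peak_density * rise_ratio^(dt / 7), floor_eff),
                           peak_density * decline_ratio^(-dt / 7)))
  structure(data.frame(date = dates, density = density),
            peak_shift = shift)
}

# Uniform integer draw on [lo, hi], safe for degenerate ranges.
.sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
}

#' Simulate a complete synthetic study dataset
#'
#' Generates the temperature record, then for every year and plot: a season
#' start near day-of-year `start_mean`; the degree-day covariates DD5 and
#' DD05 over the `true_L`-day pre-season window; a TSM drawn from the linear
#' model `mu + beta1 DD5/L + delta DD05/L + gamma prev + e`,
#' `e ~ N(0, sigma2 / n)` with `n` the tiller total of the plot-season
#' (for a lag-varying truth the DD5 term is `sum_l beta_1l x_l / L`); and a
#' weekly triangular count trajectory whose peak sits on the sampling grid.
#' Previous-year summaries are plot means of the generated peak densities
#' and TSM values; the first study year has none (its TSM is generated
#' without the `gamma` term, and fits drop it).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(config, seed)`.
#' @param counts If `FALSE`, skip the count trajectories and return only
#'   the temperature series and ground truth (faster for recovery loops).
#' @return A list of class `synthetic_dataset`: `temperature`
#'   ([temperature_series()]), `panel` (count observations, or `NULL`),
#'   `truth` (per plot-season ground truth laid out like [build_records()]
#'   output, with extra columns `dd5`, `dd05`, `linpred`, `peak_density`),
#'   and `config`.
#' @export
simulate_panel <- function(config, seed = NULL, counts = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$true_L
  # Validate the config against the noise-free climate: the expected TSM at
  # the mean season start must be non-negative, else the model is untenable.
  cfg0 <- config
  cfg0$temp_noise_sd <- 0
  cfg0$n_years <- 1L
  t0 <- simulate_temperature(cfg0)
  w0 <- lag_window(t0$day[1L] + round(config$start_mean) - 1, L)
  dd_term0 <- if (is.null(config$beta1_lag)) {
    config$beta1 * dd5(t0, w0) / L
  } else sum(config$beta1_lag * lag_contributions(t0, w0)) / L
  exp_tsm <- config$mu + dd_term0 + config$delta * dd05(t0, w0) / L
  if (exp_tsm < 0)
    stop(sprintf(paste0(
      "config implies a negative expected TSM (%.1f days) at the mean ",
      "season start under the noise-free seasonal climate; raise `mu` or ",
      "weaken the temperature coefficients"), exp_tsm))

  temps <- simulate_temperature(config)
  cache <- .dd_cache(temps)
  step <- config$sampling_interval
  lag_varying <- !is.null(config$beta1_lag)

  year_rows <- vector("list", config$n_years)
  panel_rows <- if (counts) list() else NULL
  prev_max <- NA_real_
  prev_tsm <- NA_real_
  for (i in seq_len(config$n_years)) {
    yr <- config$first_year + i - 1L
    jan1 <- as.Date(sprintf("%d-01-01", yr))
    m <- .sample_range(config$plots_per_year[1L], config$plots_per_year[2L], 1L)
    year_peak <- exp(stats::rnorm(1L, log(8), 0.8))
    year_peak <- min(max(year_peak, config$peak_density[1L]),
                     config$peak_density[2L])

    start_doy <- pmax(round(stats::rnorm(m, config$start_mean, config$start_sd)),
                      L + 1)
    anchors <- jan1 + start_doy - 1
    a <- as.integer(anchors - cache$d0) + 1L
    dd5_v <- cache$c5[a - 1L] - ifelse(a - L - 1L >= 1L, cache$c5[pmax(a - L - 1L, 1L)], 0)
    dd05_v <- cache$c05[a - 1L] - ifelse(a - L - 1L >= 1L, cache$c05[pmax(a - L - 1L, 1L)], 0)
    if (lag_varying) {
      Z <- matrix(cache$v5[outer(a, seq_len(L), `-`)], nrow = m)
      dd_term <- drop(Z %*% config$beta1_lag) / L
    } else {
      dd_term <- config$beta1 * dd5_v / L
    }
    prev_val <- if (config$gamma_term == "prev_max") prev_max else prev_tsm
    gamma_contrib <- if (i == 1L) 0 else config$gamma * prev_val
    # Rare climate extremes can push a realized linear predictor below zero;
    # the TSM draw is then truncated at 0 (peak at the season start).
    linpred <- config$mu + dd_term + config$delta * dd05_v / L + gamma_contrib

    n_weeks_i <- .sample_range(config$n_weeks[1L], config$n_weeks[2L], m)
    tiller_draws <- lapply(n_weeks_i, function(k)
      .sample_range(config$tillers[1L], config$tillers[2L], k))
    n_weight <- vapply(tiller_draws, sum, numeric(1L))
    e <- stats::rnorm(m, 0, sqrt(config$sigma2 / n_weight))
    tsm_raw <- linpred + e
    tsm <- if (config$round_to_grid) pmax(round(tsm_raw / step) * step, 0)
           else pmax(tsm_raw, 0)
    peak <- pmin(pmax(year_peak * exp(stats::rnorm(m, 0, 0.3)),
                      config$peak_density[1L]), config$peak_density[2L])

    year_rows[[i]] <- data.frame(
      year = yr, plot = sprintf("p%d", seq_len(m)), start_day = anchors,
      tsm = tsm, n_weight = n_weight, max_density = peak,
      prev_max = prev_max, prev_tsm = prev_tsm,
      dd5 = dd5_v, dd05 = dd05_v, linpred = linpred, peak_density = peak)

    if (counts) {
      for (j in seq_len(m)) {
        k <- tsm[j] %/% step           # rise steps to the peak
        n_rise <- k + 1L               # dates from start to peak inclusive
        n_decline <- max(n_weeks_i[j] - n_rise - 1L, 1L)
        n_dates <- 1L + n_rise + n_decline  # one leading zero date
        tl <- tiller_draws[[j]]
        if (length(tl) < n_dates)      # long TSM outgrew the planned season
          tl <- c(tl, .sample_range(config$tillers[1L], config$tillers[2L],
                                    n_dates - length(tl)))
        tl <- tl[seq_len(n_dates)]
        dates <- anchors[j] + step * (seq_len(n_dates) - 2L)
        traj <- triangular_trajectory(anchors[j], tsm[j], peak[j], dates,
                                      config$rise_ratio, config$decline_ratio,
                                      config$start_density)
        lambda <- traj$density * tl
        aphids <- if (config$poisson_counts) stats::rpois(n_dates, lambda)
                  else ceiling(lambda)
        panel_rows[[length(panel_rows) + 1L]] <- data.frame(
          year = yr, plot = sprintf("p%d", j), date = dates,
          aphids = aphids, tillers = tl)
      }
    }
    prev_max <- mean(peak)
    prev_tsm <- mean(tsm)
  }
  truth <- do.call(rbind, year_rows)
  rownames(truth) <- NULL
  panel <- if (counts) do.call(rbind, panel_rows) else NULL
  structure(list(temperature = temps, panel = panel, truth = truth,
                 config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d years, %d plot-seasons, %d temperature days%s\n",
              x$config$n_years, nrow(x$truth), nrow(x$temperature),
              if (is.null(x$panel)) "" else
                sprintf(", %d count observations", nrow(x$panel))))
  invisible(x)
}
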