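test_that("simulate_temperature is deterministic and follows its seasonal cycle", {
  cfg <- synthetic_config(n_years = 2)
  t1 <- simulate_temperature(cfg, seed = 5)
  t2 <- simulate_temperature(cfg, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_temperature(cfg, seed = 6)
  expect_false(identical(t1$t_mean, t3$t_mean))
  # amplitude 0, noise 0: constant series at the annual mean
  flat <- synthetic_config(n_years = 1, temp_amplitude = 0, temp_noise_sd = 0)
  tf <- simulate_temperature(flat, seed = 1)
  expect_equal(unique(tf$t_mean), flat$temp_mean)
  expect_equal(length(temperature_gaps(tf)), 0L)
})

test_that("winter windows are colder than summer windows across seeds", {
  cfg <- synthetic_config(n_years = 1)
  ok <- vapply(1:100, function(r) {
    ts <- simulate_temperature(cfg, seed = 900 + r)
    doy <- as.integer(format(ts$day, "%j"))
    mean(ts$t_mean[doy %in% 1:60]) < mean(ts$t_mean[doy %in% 182:243])
  }, logical(1))
  expect_true(all(ok))
})

test_that("triangular_trajectory rises to a grid-aligned peak and falls faster", {
  start <- as.Date("2000-05-22")
  grid <- start + 7 * (-1:8)
  tr <- triangular_trajectory(start, tsm = 21, peak_density = 12, grid)
  expect_equal(attr(tr, "peak_shift"), 0)
  on <- tr$density[tr$date >= start & tr$date <= start + 21]
  expect_equal(length(on), 4L)                  # 4 ascending values to the peak
  expect_true(all(diff(on) > 0))
  expect_equal(tr$date[which.max(tr$density)], start + 21)
  expect_equal(max(tr$density), 12)
  expect_equal(tr$density[tr$date < start], 0)
  # decline at least as fast as the rise: a week after the peak is no denser
  # than a week before it, and so on outwards
  before <- rev(on[-length(on)])
  after <- tr$density[tr$date > start + 21][seq_along(before)]
  expect_true(all(after <= before + 1e-12))
  expect_true(all(diff(tr$density[tr$date > start + 21]) < 0))
  # tsm = 0: spike at the start
  tr0 <- triangular_trajectory(start, 0, 5, grid)
  expect_equal(tr0$date[which.max(tr0$density)], start)
  # off-grid peak is shifted to the nearest sampling date and recorded
  tr2 <- triangular_trajectory(start, 10, 5, grid)
  expect_equal(abs(attr(tr2, "peak_shift")), 3)
  expect_true(tr2$date[which.max(tr2$density)] %in% grid)
})

test_that("tsm_from_series inverts triangular trajectories exactly", {
  set.seed(71)
  for (i in 1:50) {
    start <- as.Date("2000-04-01") + sample(0:60, 1)
    tsm <- 7 * sample(0:8, 1)
    grid <- start + 7 * (-1:(tsm / 7 + 3))
    tr <- triangular_trajectory(start, tsm, runif(1, 0.5, 60), grid)
    s <- tsm_from_series(tr)
    expect_identical(s$start_day, start)
    expect_identical(s$tsm, as.numeric(tsm))
  }
})

test_that("simulate_panel is deterministic and internally consistent", {
  cfg <- synthetic_config(n_years = 6, plots_per_year = c(3, 6))
  s1 <- simulate_panel(cfg, seed = 19)
  s2 <- simulate_panel(cfg, seed = 19)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$panel, s2$panel)
  expect_false(identical(s1$truth$tsm, simulate_panel(cfg, seed = 20)$truth$tsm))
  # plot counts within range, starts near the configured day-of-year
  per_year <- table(s1$truth$year)
  expect_true(all(per_year >= 3 & per_year <= 6))
  doy <- as.integer(format(as.Date(s1$truth$start_day), "%j"))
  expect_true(all(abs(doy - 143) < 40))
  # generated TSM sits on the weekly grid
  expect_true(all(s1$truth$tsm %% 7 == 0))
})

test_that("noiseless panels reproduce the generator's TSM exactly", {
  cfg <- synthetic_config(n_years = 8, plots_per_year = c(3, 6),
                          poisson_counts = FALSE)
  sim <- simulate_panel(cfg, seed = 73)
  rec <- quiet(build_records(sim$panel))
  m <- merge(rec, sim$truth, by = c("year", "plot"))
  expect_equal(nrow(m), nrow(sim$truth))
  expect_identical(m$tsm.x, m$tsm.y)
  expect_identical(m$start_day.x, m$start_day.y)
})

test_that("sigma2 = 0 with flat truth returns the grid-rounded linear predictor", {
  cfg <- synthetic_config(n_years = 5, plots_per_year = c(4, 4), sigma2 = 0,
                          gamma = 0, poisson_counts = FALSE)
  sim <- simulate_panel(cfg, seed = 79)
  expect_identical(sim$truth$tsm,
                   pmax(round(sim$truth$linpred / 7) * 7, 0))
})

test_that("density dependence induces year-to-year TSM autocorrelation", {
  lag1_cor <- function(gamma, seeds) {
    cfg <- synthetic_config(n_years = 24, plots_per_year = c(6, 6),
                            gamma = gamma, gamma_term = "prev_tsm",
                            sigma2 = 8000)
    vapply(seeds, function(r) {
      yr <- simulate_panel(cfg, seed = r, counts = FALSE)$truth
      m <- tapply(yr$tsm, yr$year, mean)
      cor(m[-1], m[-length(m)])
    }, numeric(1))
  }
  seeds <- 1:100
  expect_gt(mean(lag1_cor(0.45, seeds)), mean(lag1_cor(0, seeds)))
})

test_that("an untenable configuration is rejected with a diagnostic", {
  expect_error(
    simulate_panel(synthetic_config(mu = 20), seed = 1),
    "negative expected TSM")
  expect_error(synthetic_config(start_mean = 100, true_L = 123),
               "temperature coverage")
  expect_error(synthetic_config(rise_ratio = 5, decline_ratio = 2), "decline")
  expect_error(synthetic_config(beta1_lag = c(-1, -2), true_L = 123),
               "length")
})

test_that("the bimodal preset places its negative windows where asked", {
  b <- bimodal_lag_curve(123)
  expect_equal(length(b), 123L)
  expect_true(all(b[50:80] == -40) && all(b[90:110] == -40))
  expect_true(all(b[c(1:49, 81:89, 111:123)] == 0))
  expect_error(bimodal_lag_curve(60, windows = list(c(50, 80))), "outside")
})

test_that("a long generated panel recovers the generating coefficients", {
  cfg <- synthetic_config(n_years = 200, plots_per_year = c(6, 6),
                          sigma2 = 4000)
  sim <- simulate_panel(cfg, seed = 83, counts = FALSE)
  f <- quiet(fit_model(sim$truth, sim$temperature, design_spec(1, L = 123)))
  expect_lt(abs(f$coefficients["DD5.std"] / -15 - 1), 0.05)
  expect_lt(abs(f$coefficients["DD05.std"] / -20 - 1), 0.05)
})
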