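test_that("wls_fit equals the closed-form weighted normal equations", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n, X %*% rnorm(p), 1)
    w <- runif(n, 0.2, 5)
    f <- wls_fit(y, X, w)
    expect_equal(unname(f$coefficients), unname(oracle_wls(y, X, w)),
                 tolerance = 1e-10)
    # unit weights reduce to OLS
    f1 <- wls_fit(y, X, rep(1, n))
    expect_equal(unname(f1$coefficients), unname(oracle_wls(y, X, rep(1, n))),
                 tolerance = 1e-10)
  }
})

test_that("wls_fit handles exact fits, weight scaling and rank deficiency", {
  set.seed(7)
  X <- cbind(1, rnorm(30), runif(30))
  colnames(X) <- c("(Intercept)", "a", "b")
  beta <- c(2, -1, 0.5)
  w <- runif(30, 1, 4)
  # exact linear response
  fe <- wls_fit(drop(X %*% beta), X, w)
  expect_equal(max(abs(fe$residuals)), 0, tolerance = 1e-10)
  expect_equal(fe$r2_adj, 1, tolerance = 1e-10)
  # rescaling all weights changes nothing but the variance scale
  y <- rnorm(30, X %*% beta)
  f1 <- wls_fit(y, X, w)
  f2 <- wls_fit(y, X, 2 * w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
  # collinear column named in the error
  Xr <- cbind(X, dup = X[, "a"])
  expect_error(wls_fit(y, Xr, w), "collinear column\\(s\\): dup")
})

test_that("the AIC uses the full Gaussian likelihood with p + 1 parameters", {
  set.seed(11)
  X <- cbind(1, rnorm(40))
  y <- rnorm(40, X %*% c(1, 2))
  w <- runif(40, 0.5, 2)
  f <- wls_fit(y, X, w)
  s2_ml <- sum(w * f$residuals^2) / 40
  ll <- sum(dnorm(y, f$fitted, sqrt(s2_ml / w), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-10)
  expect_equal(f$aic, -2 * ll + 2 * 3, tolerance = 1e-10)
  expect_equal(as.numeric(logLik(f)), f$loglik)
})

test_that("fit_model recovers generating parameters on a large panel", {
  cfg <- synthetic_config(n_years = 150, plots_per_year = c(6, 6), sigma2 = 8000)
  sim <- simulate_panel(cfg, seed = 17, counts = FALSE)
  f <- quiet(fit_model(sim$truth, sim$temperature, design_spec(1, L = 123)))
  expect_equal(names(f$coefficients),
               c("(Intercept)", "DD5.std", "DD05.std", "prev_max"))
  expect_lt(abs(f$coefficients["DD5.std"] - (-15)) / 15, 0.05)
  expect_lt(abs(f$coefficients["DD05.std"] - (-20)) / 20, 0.05)
  expect_lt(abs(f$coefficients["prev_max"]), 3 * f$se["prev_max"])
})

test_that("gamma p-values are uniform when the generator has no density dependence", {
  cfg <- synthetic_config(plots_per_year = c(6, 6), round_to_grid = FALSE)
  spec <- design_spec(1, L = 123)
  pv <- vapply(1:150, function(r) {
    sim <- simulate_panel(cfg, seed = 4000 + r, counts = FALSE)
    quiet(fit_model(sim$truth, sim$temperature, spec))$p_value["prev_max"]
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("profile_L returns a comparable profile and breaks ties to smaller L", {
  sim <- simulate_panel(synthetic_config(n_years = 8, plots_per_year = c(4, 4)),
                        seed = 23, counts = FALSE)
  spec <- design_spec(1, L = 60)
  pr <- quiet(profile_L(sim$truth, sim$temperature, spec, c(40, 60, 80)))
  expect_s3_class(pr, "lag_profile")
  expect_equal(length(pr$aic), 3L)
  expect_equal(pr$best_L, pr$L[which.min(pr$aic)])
  # every candidate refitted on the same records
  expect_equal(as.data.frame(pr)$aic[2],
               quiet(fit_model(sim$truth, sim$temperature, spec))$aic)
  # single-candidate grid
  pr1 <- quiet(profile_L(sim$truth, sim$temperature, spec, 45))
  expect_equal(pr1$best_L, 45L)
})

test_that("infeasible candidate depths are dropped with a log entry", {
  cfg <- synthetic_config(n_years = 4, plots_per_year = c(3, 3))
  sim <- simulate_panel(cfg, seed = 29, counts = FALSE)
  msgs <- capture_messages(
    pr <- profile_L(sim$truth, sim$temperature, design_spec(1, L = 60),
                    c(60, 90, 2000)))
  expect_true(any(grepl("dropped as infeasible", msgs)))
  expect_equal(pr$L, c(60L, 90L))
})

test_that("lag_curve maps theta through the basis with a pointwise band", {
  sim <- simulate_panel(synthetic_config(n_years = 10, plots_per_year = c(5, 5)),
                        seed = 31, counts = FALSE)
  f3 <- quiet(fit_model(sim$truth, sim$temperature, design_spec(3, L = 123)))
  cv <- lag_curve(f3)
  expect_equal(nrow(cv), 123L)
  expect_true(all(cv$lower <= cv$estimate & cv$estimate <= cv$upper))
  # oracle recomputation of the spline combination at integer lags
  B <- oracle_bspline(f3$basis$knots, seq_len(123), 3)
  theta <- f3$coefficients[f3$theta_idx]
  expect_equal(cv$estimate, drop(B %*% theta), tolerance = 1e-10)
  V <- f3$vcov[f3$theta_idx, f3$theta_idx]
  expect_equal(cv$se[17], sqrt(drop(t(B[17, ]) %*% V %*% B[17, ])),
               tolerance = 1e-10)
  expect_equal(cv$upper, cv$estimate + qnorm(0.975) * cv$se, tolerance = 1e-12)
  # degenerate cases
  fz <- f3
  fz$vcov[] <- 0
  cvz <- lag_curve(fz)
  expect_equal(cvz$lower, cvz$estimate)
  fbad <- f3
  fbad$theta_idx <- 2:4
  expect_error(lag_curve(fbad), "dimension")
  f1 <- quiet(fit_model(sim$truth, sim$temperature, design_spec(1, L = 123)))
  expect_error(lag_curve(f1), "models 3 and 4")
})

test_that("the constant-basis lag curve equals the pooled model-1 slope", {
  sim <- simulate_panel(synthetic_config(n_years = 10, plots_per_year = c(5, 5)),
                        seed = 37, counts = FALSE)
  f1 <- quiet(fit_model(sim$truth, sim$temperature, design_spec(1, L = 123)))
  f30 <- quiet(fit_model(sim$truth, sim$temperature,
                         design_spec(3, L = 123, K = 0, degree = 0)))
  cv <- lag_curve(f30)
  expect_equal(unique(round(cv$estimate, 10)),
               round(unname(f1$coefficients["DD5.std"]), 10))
})

test_that("joint_dd5_test degenerates and errors as required", {
  sim <- simulate_panel(synthetic_config(n_years = 10, plots_per_year = c(5, 5)),
                        seed = 41, counts = FALSE)
  f3 <- quiet(fit_model(sim$truth, sim$temperature, design_spec(3, L = 123)))
  ht <- joint_dd5_test(f3)
  expect_s3_class(ht, "htest")
  # chi-squared statistic is (K+1) times the F statistic
  hc <- joint_dd5_test(f3, type = "chisq")
  expect_equal(unname(hc$statistic), unname(ht$statistic) * 10, tolerance = 1e-10)
  # theta = 0 exactly gives statistic 0 and p-value 1
  fz <- f3
  fz$coefficients[fz$theta_idx] <- 0
  htz <- joint_dd5_test(fz)
  expect_equal(unname(htz$statistic), 0)
  expect_equal(htz$p.value, 1)
  fs <- f3
  fs$vcov[fs$theta_idx, fs$theta_idx] <- 0
  expect_error(joint_dd5_test(fs), "singular")
})

test_that("random-year GLS reduces to WLS without correlation", {
  cfg <- synthetic_config(n_years = 12, plots_per_year = c(4, 4))
  sim <- simulate_panel(cfg, seed = 43, counts = FALSE)
  spec <- design_spec(1, L = 123)
  f <- quiet(fit_model(sim$truth, sim$temperature, spec))
  g0 <- quiet(fit_random_year_gls(sim$truth, sim$temperature, spec, rho = 0))
  expect_equal(g0$coefficients, f$coefficients, tolerance = 1e-10)
  expect_equal(g0$se, f$se, tolerance = 1e-10)
  expect_equal(g0$rho, 0)
  # single plot per year: moment estimator has no pairs, reduces to WLS
  cfg1 <- synthetic_config(n_years = 12, plots_per_year = c(1, 1))
  sim1 <- simulate_panel(cfg1, seed = 47, counts = FALSE)
  f1 <- quiet(fit_model(sim1$truth, sim1$temperature, spec))
  g1 <- quiet(fit_random_year_gls(sim1$truth, sim1$temperature, spec))
  expect_equal(g1$rho, 0)
  expect_equal(g1$coefficients, f1$coefficients, tolerance = 1e-10)
  # a supplied rho outside [0, 1) is clipped with a warning
  expect_warning(
    suppressMessages(fit_random_year_gls(sim$truth, sim$temperature, spec,
                                         rho = 1.2)),
    "clipped")
})

test_that("random-year GLS matches nlme::gls at a fixed correlation", {
  cfg <- synthetic_config(n_years = 15, plots_per_year = c(5, 5))
  sim <- simulate_panel(cfg, seed = 53, counts = FALSE)
  # inject genuine within-year correlation on top of the generator draw
  tr <- sim$truth
  set.seed(54)
  yr_eff <- rnorm(length(unique(tr$year)), 0, 5)
  tr$tsm <- tr$tsm + yr_eff[match(tr$year, unique(tr$year))]
  spec <- design_spec(1, L = 123)
  g <- quiet(fit_random_year_gls(tr, sim$temperature, spec))
  expect_gt(g$rho, 0.05)
  d <- quiet(build_design(tr, sim$temperature, spec))
  dat <- data.frame(tsm = d$y, DD5.std = d$X[, "DD5.std"],
                    DD05.std = d$X[, "DD05.std"], prev_max = d$X[, "prev_max"],
                    year = d$records$year, inv_n = 1 / d$w)
  ref <- nlme::gls(tsm ~ DD5.std + DD05.std + prev_max, data = dat,
                   correlation = nlme::corCompSymm(value = g$rho, form = ~ 1 | year,
                                                   fixed = TRUE),
                   weights = nlme::varFixed(~ inv_n))
  expect_equal(unname(g$coefficients), unname(coef(ref)), tolerance = 1e-6)
})

test_that("correlated years keep the temperature signs of the WLS fit", {
  cfg <- synthetic_config(n_years = 24, plots_per_year = c(6, 6))
  spec <- design_spec(1, L = 123)
  ok <- vapply(1:40, function(r) {
    sim <- simulate_panel(cfg, seed = 6000 + r, counts = FALSE)
    tr <- sim$truth
    # exchangeable within-year correlation ~0.5 on the standardized scale
    sd_y <- sqrt(cfg$sigma2 / mean(tr$n_weight))
    yr_eff <- rnorm(length(unique(tr$year)), 0, sd_y)
    tr$tsm <- tr$tsm + yr_eff[match(tr$year, unique(tr$year))]
    f <- quiet(fit_model(tr, sim$temperature, spec))
    g <- quiet(fit_random_year_gls(tr, sim$temperature, spec))
    all(sign(g$coefficients[2:3]) == sign(f$coefficients[2:3])) &&
      (g$p_value[2] < 0.05) == (f$p_value[2] < 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("compare_models ranks by AIC and rejects mismatched record sets", {
  sim <- simulate_panel(synthetic_config(n_years = 12, plots_per_year = c(5, 5)),
                        seed = 59, counts = FALSE)
  f1 <- quiet(fit_model(sim$truth, sim$temperature, design_spec(1, L = 123)))
  f2 <- quiet(fit_model(sim$truth, sim$temperature, design_spec(2, L = 123)))
  tab <- compare_models(f1, f2)
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  expect_equal(compare_models(f1, f1)$delta_aic, c(0, 0))
  sim2 <- simulate_panel(synthetic_config(n_years = 8, plots_per_year = c(5, 5)),
                         seed = 61, counts = FALSE)
  f3 <- quiet(fit_model(sim2$truth, sim2$temperature, design_spec(1, L = 123)))
  expect_error(compare_models(f1, f3), "not comparable")
})

test_that("adding a pure-noise column does not reduce the AIC on average", {
  set.seed(67)
  daic <- vapply(1:60, function(r) {
    n <- 60
    X <- cbind(1, rnorm(n))
    y <- rnorm(n, X %*% c(3, 1))
    w <- runif(n, 0.5, 2)
    f0 <- wls_fit(y, X, w)
    f1 <- wls_fit(y, cbind(X, junk = rnorm(n)), w)
    f1$aic - f0$aic
  }, numeric(1))
  expect_gt(mean(daic), 0)
})
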