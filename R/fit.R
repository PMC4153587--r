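# Weighted least squares, AIC, lag profiling, lag curve, Wald test, GLS.

# Gaussian log-likelihood of a weighted fit: Var(e_i) = sigma2 / w_i, with
# the ML variance estimate (weighted RSS / n) plugged in. Constants (2*pi,
# sum(log w)) are kept so AIC differences are basis- and weight-independent.
.wls_loglik <- function(rss_w, w, n) {
  s2_ml <- rss_w / n
  -n / 2 * (log(2 * pi * s2_ml) + 1) + sum(log(w)) / 2
}

#' Weighted least-squares fit by iteratively reweighted least squares
#'
#' Minimizes `sum(w_i (y_i - x_i' beta)^2)`. Estimation runs as an IRWLS
#' loop (the general path for this model family); with fixed known weights
#' the loop converges at the first re-solve, its fixed point being the
#' one-shot weighted least-squares solution. Standard errors use
#' `sigma2 = weighted RSS / (n - p)`; the AIC uses the full Gaussian
#' log-likelihood with the ML variance estimate and counts `p + 1`
#' parameters (the residual variance included). The adjusted R-squared is
#' computed on the weighted scale by default (the unweighted version is also
#' reported).
#'
#' @param y Numeric response vector.
#' @param X Design matrix with full column rank.
#' @param w Positive weights, proportional to inverse error variances.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-10).
#' @param max_iter Maximum IRWLS iterations (default 50).
#' @return An object of class `aphid_fit`: coefficients, `vcov`, `se`,
#'   `t_value`, `p_value` (two-sided, t with `n - p` df), `sigma2`, `aic`,
#'   `loglik`, `r2_adj`, `r2_adj_unweighted`, `n_obs`, `n_params`,
#'   `df_residual`, `fitted`, `residuals`, `weights`, plus `y` and `X`.
#' @export
wls_fit <- function(y, X, w, tol = 1e-10, max_iter = 50L) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("`y` and `X` dimensions disagree")
  if (length(w) != n) stop("`w` must have one weight per observation")
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive and finite")
  if (n <= p) stop("need more observations than parameters")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  sw <- sqrt(w)
  qx <- qr(X * sw)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- rep(Inf, p)
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    if (max(abs(fit$coefficients - beta)) < tol) break
    beta <- fit$coefficients
  }
  beta <- fit$coefficients
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss_w <- sum(w * res^2)
  sigma2 <- rss_w / (n - p)
  XtWX_inv <- chol2inv(qr.R(qx))
  vcov <- sigma2 * XtWX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)

  ybar_w <- sum(w * y) / sum(w)
  tss_w <- sum(w * (y - ybar_w)^2)
  r2_adj_w <- 1 - (rss_w / (n - p)) / (tss_w / (n - 1))
  rss_u <- sum(res^2)
  tss_u <- sum((y - mean(y))^2)
  r2_adj_u <- 1 - (rss_u / (n - p)) / (tss_u / (n - 1))

  ll <- .wls_loglik(rss_w, w, n)
  structure(list(
    coefficients = beta, vcov = vcov, se = se, t_value = tval,
    p_value = pval, sigma2 = sigma2, loglik = ll,
    aic = -2 * ll + 2 * (p + 1), r2_adj = r2_adj_w,
    r2_adj_unweighted = r2_adj_u, n_obs = n, n_params = p,
    df_residual = n - p, fitted = fitted, residuals = res,
    weights = w, y = y, X = X, iterations = it),
    class = "aphid_fit")
}

#' @export
print.aphid_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("<%s>%s n = %d, params = %d (+ sigma2)\n",
              class(x)[1L],
              if (!is.null(x$spec)) sprintf(" model %d,", x$spec$model) else "",
              x$n_obs, x$n_params))
  print(coef_table(x, intercept = TRUE), digits = digits)
  cat(sprintf("sigma2 = %.4g,  AIC = %.2f,  adj. R2 (weighted) = %.3f\n",
              x$sigma2, x$aic, x$r2_adj))
  if (!is.null(x$rho)) cat(sprintf("within-year correlation rho = %.3f\n", x$rho))
  invisible(x)
}

#' @export
coef.aphid_fit <- function(object, ...) object$coefficients

#' @export
vcov.aphid_fit <- function(object, ...) object$vcov

#' @export
logLik.aphid_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params + 1L, class = "logLik")
}

#' Coefficient table in the reporting layout
#'
#' Estimates, standard errors and two-sided p-values, one row per
#' coefficient in model order (DD5 block, DD05, previous-year term).
#'
#' @param fit An [wls_fit()] / [fit_model()] result.
#' @param intercept Keep the intercept row? Default `FALSE`, matching the
#'   usual reporting layout.
#' @return Data frame with columns `Coefficient`, `Estimate`,
#'   `Standard.error`, `p.value`.
#' @export
coef_table <- function(fit, intercept = FALSE) {
  out <- data.frame(Coefficient = names(fit$coefficients),
                    Estimate = unname(fit$coefficients),
                    Standard.error = unname(fit$se),
                    p.value = unname(fit$p_value))
  if (!intercept) out <- out[out$Coefficient != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit one of the four TSM regression models
#'
#' Composes [build_design()] and [wls_fit()]: builds the degree-day
#' covariates over each record's pre-season window and estimates the model
#' by weighted least squares with weights proportional to the tiller counts.
#'
#' @inheritParams build_design
#' @return An `aphid_fit` (see [wls_fit()]) with the `spec`, the `lag_basis`
#'   (models 3-4) and the index of the DD5 coefficient block attached.
#' @export
fit_model <- function(records, temps, spec) {
  d <- build_design(records, temps, spec)
  f <- wls_fit(d$y, d$X, d$w)
  f$spec <- spec
  f$basis <- d$basis
  f$records <- d$records
  f$theta_idx <- if (spec$lag_varying) 1L + seq_len(spec$K + 1L) else 2L
  f
}

#' Profile the AIC over candidate lag depths L
#'
#' Refits the model at every window depth in `L_grid` on one common record
#' set and returns the AIC profile and its argmin. So that the AICs are
#' comparable, all depths are fitted on the records whose windows are
#' covered by the temperature series at the deepest candidate; candidates
#' deeper than any feasible window are dropped with a log entry. Ties in the
#' minimum are broken toward the smallest L (the most parsimonious history
#' depth).
#'
#' @inheritParams build_design
#' @param spec Template [design_spec()]; its `L` is replaced by each
#'   candidate.
#' @param L_grid Positive integer candidate depths.
#' @return An object of class `lag_profile`: `L` (the feasible grid), `aic`,
#'   `best_L`, `n_obs`, `r2_adj` per candidate.
#' @export
profile_L <- function(records, temps, spec, L_grid) {
  L_grid <- sort(unique(as.integer(L_grid)))
  if (length(L_grid) == 0L || any(is.na(L_grid) | L_grid < 1L))
    stop("`L_grid` must be positive integers")
  prev <- records[[spec$density_term]]
  usable <- records[!is.na(prev) & !is.na(records$tsm), , drop = FALSE]
  if (nrow(usable) == 0L) stop("no usable records")
  # max feasible depth per record given temperature coverage
  cache <- .dd_cache(temps)
  a <- as.integer(as.Date(usable$start_day) - cache$d0) + 1L
  max_feas <- a - 1L
  feasible <- L_grid[L_grid <= max(max_feas)]
  if (length(feasible) == 0L)
    stop("no candidate L is feasible for any record (earliest window exceeds temperature coverage)")
  if (length(feasible) < length(L_grid))
    message(length(L_grid) - length(feasible),
            " candidate L value(s) dropped as infeasible: ",
            paste(setdiff(L_grid, feasible), collapse = ", "))
  Lmax <- max(feasible)
  common <- usable[max_feas >= Lmax, , drop = FALSE]
  if (nrow(common) < nrow(usable))
    message(nrow(usable) - nrow(common),
            " record(s) dropped so every candidate L uses the same record set")
  if (nrow(common) == 0L) stop("no record supports the deepest candidate L")

  aic <- r2 <- numeric(length(feasible))
  for (i in seq_along(feasible)) {
    spec_i <- spec
    spec_i$L <- feasible[i]
    f <- fit_model(common, temps, spec_i)
    aic[i] <- f$aic
    r2[i] <- f$r2_adj
  }
  best <- feasible[which.min(aic)]  # which.min returns the first (smallest L)
  structure(list(L = feasible, aic = aic, r2_adj = r2, best_L = best,
                 n_obs = nrow(common), spec = spec),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("<lag_profile> model %d, %d candidate depths on n = %d records\n",
              x$spec$model, length(x$L), x$n_obs))
  cat(sprintf("best L = %d (AIC %.2f)\n", x$best_L, min(x$aic)))
  invisible(x)
}

#' @export
as.data.frame.lag_profile <- function(x, ...) {
  data.frame(L = x$L, aic = x$aic, r2_adj = x$r2_adj)
}

#' @export
plot.lag_profile <- function(x, ...) {
  plot(x$L, x$aic, type = "b", pch = 16, xlab = "L (days)", ylab = "AIC", ...)
  graphics::abline(v = x$best_L, lty = 2)
  invisible(x)
}

#' Lag-coefficient curve with pointwise confidence band
#'
#' Maps the fitted spline coefficients theta back to the per-lag DD5
#' coefficients `beta_1l = sum_k theta_k b_k(l)` and attaches the pointwise
#' asymptotic band `estimate +/- z * sqrt(b(l)' Cov(theta) b(l))`.
#'
#' @param fit A model-3 or model-4 [fit_model()] result.
#' @param level Confidence level (default 0.95; the band uses the normal
#'   quantile, i.e. 1.96 at the default).
#' @return Data frame of class `lag_curve` with columns `lag`, `estimate`,
#'   `se`, `lower`, `upper`.
#' @export
lag_curve <- function(fit, level = 0.95) {
  if (is.null(fit$basis)) stop("`fit` has no lag basis (models 3 and 4 only)")
  B <- fit$basis$B
  idx <- fit$theta_idx
  if (length(idx) != ncol(B))
    stop("basis dimension does not match the fitted theta block")
  theta <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  est <- drop(B %*% theta)
  se <- sqrt(pmax(rowSums((B %*% V) * B), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(data.frame(lag = seq_len(nrow(B)), estimate = est, se = se,
                       lower = est - z * se, upper = est + z * se),
            class = c("lag_curve", "data.frame"), level = level)
}

#' @export
plot.lag_curve <- function(x, ...) {
  plot(x$lag, x$estimate, type = "l", ylim = range(x$lower, x$upper),
       xlab = "lag l (days before season start)",
       ylab = expression(beta[1 * l]), ...)
  graphics::lines(x$lag, x$lower, lty = 2)
  graphics::lines(x$lag, x$upper, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Joint Wald test of the DD5 lag-coefficient block
#'
#' Tests the null hypothesis that the whole DD5 effect vanishes
#' (`beta_1l = 0` at every lag, i.e. all theta = 0) with the Wald statistic
#' `theta' Cov(theta)^-1 theta`. The small-sample default refers
#' `statistic / (K+1)` to an F distribution with `(K+1, n-p)` degrees of
#' freedom; `type = "chisq"` gives the asymptotic chi-squared version.
#'
#' @param fit A model-3 or model-4 [fit_model()] result.
#' @param type `"F"` (default) or `"chisq"`.
#' @return An object of class `htest`.
#' @export
joint_dd5_test <- function(fit, type = c("F", "chisq")) {
  type <- match.arg(type)
  idx <- fit$theta_idx
  if (is.null(fit$basis)) stop("`fit` has no lag-coefficient block (models 3 and 4 only)")
  theta <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  if (rcond(V) < .Machine$double.eps)
    stop("singular covariance of the theta block")
  wald <- drop(crossprod(theta, solve(V, theta)))
  q <- length(theta)
  if (type == "F") {
    stat <- wald / q
    p <- stats::pf(stat, q, fit$df_residual, lower.tail = FALSE)
    structure(list(statistic = c(F = stat),
                   parameter = c(df1 = q, df2 = fit$df_residual),
                   p.value = p,
                   method = "Wald F test of the joint DD5 lag effect (all beta_1l = 0)",
                   data.name = deparse(substitute(fit))),
              class = "htest")
  } else {
    p <- stats::pchisq(wald, q, lower.tail = FALSE)
    structure(list(statistic = c("X-squared" = wald),
                   parameter = c(df = q),
                   p.value = p,
                   method = "Wald chi-squared test of the joint DD5 lag effect",
                   data.name = deparse(substitute(fit))),
              class = "htest")
  }
}

#' Random-year sensitivity fit by feasible generalized least squares
#'
#' Refits the model allowing exchangeable (compound-symmetric) correlation
#' `rho` among the plots investigated in the same year, while retaining the
#' `sigma^2 / n` tiller-count variance weights: on the weight-standardized
#' scale the error correlation matrix is block compound-symmetric in years.
#' `rho` is estimated by the method of moments on the standardized WLS
#' residuals (average cross-product of within-year pairs over the residual
#' variance) and the coefficients are then re-estimated by one feasible GLS
#' solve. With `rho = 0`, or with a single plot per year, the fit reduces
#' exactly to [wls_fit()].
#'
#' @inheritParams build_design
#' @param rho Within-year correlation. `NULL` (default) estimates it;
#'   a supplied value outside `[0, 1)` is clipped with a warning.
#' @return An object of class `c("aphid_gls", "aphid_fit")` with the extra
#'   element `rho`. Its AIC counts `p + 2` parameters (`sigma^2` and `rho`).
#' @export
fit_random_year_gls <- function(records, temps, spec, rho = NULL) {
  d <- build_design(records, temps, spec)
  base <- wls_fit(d$y, d$X, d$w)
  year <- d$records$year
  n <- base$n_obs
  p <- base$n_params
  u <- base$residuals * sqrt(d$w)  # standardized: Var = sigma2, Corr = CS(rho)
  s2 <- sum(u^2) / (n - p)

  if (is.null(rho)) {
    cross <- npairs <- 0
    for (g in split(u, year)) {
      m <- length(g)
      if (m >= 2L) {
        cross <- cross + (sum(g)^2 - sum(g^2)) / 2
        npairs <- npairs + m * (m - 1) / 2
      }
    }
    if (npairs == 0) {
      rho <- 0
    } else {
      rho <- cross / npairs / s2
      if (rho < 0 || rho >= 1) {
        warning(sprintf("estimated rho = %.3f outside [0, 1); clipped", rho))
        rho <- min(max(rho, 0), 0.99)
      }
    }
  } else {
    if (rho < 0 || rho >= 1) {
      warning(sprintf("rho = %.3f outside [0, 1); clipped", rho))
      rho <- min(max(rho, 0), 0.99)
    }
  }

  # Whitened normal equations, block by block: for a CS(rho) block of size m,
  # R^-1 = a I + b J with a = 1/(1-rho), b = -rho / ((1-rho)(1+(m-1)rho)).
  sw <- sqrt(d$w)
  Xs <- d$X * sw
  ys <- d$y * sw
  A <- matrix(0, p, p)
  cvec <- numeric(p)
  yy <- 0
  logdetR <- 0
  for (g in split(seq_len(n), year)) {
    m <- length(g)
    aa <- 1 / (1 - rho)
    bb <- if (m > 1L) -rho / ((1 - rho) * (1 + (m - 1) * rho)) else 0
    if (rho == 0) { aa <- 1; bb <- 0 }
    Xg <- Xs[g, , drop = FALSE]
    yg <- ys[g]
    cs <- colSums(Xg)
    A <- A + aa * crossprod(Xg) + bb * tcrossprod(cs)
    cvec <- cvec + aa * crossprod(Xg, yg) + bb * cs * sum(yg)
    yy <- yy + aa * sum(yg^2) + bb * sum(yg)^2
    logdetR <- logdetR + (m - 1) * log(1 - rho) + log(1 + (m - 1) * rho)
  }
  beta <- drop(solve(A, cvec))
  quad <- yy - 2 * sum(beta * cvec) + drop(crossprod(beta, A %*% beta))
  sigma2 <- quad / (n - p)
  vcov <- sigma2 * solve(A)
  dimnames(vcov) <- dimnames(base$vcov)
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  s2_ml <- quad / n
  ll <- -n / 2 * (log(2 * pi * s2_ml) + 1) - logdetR / 2 + sum(log(d$w)) / 2
  fitted <- drop(d$X %*% beta)
  names(beta) <- colnames(d$X)
  structure(list(
    coefficients = beta, vcov = vcov, se = se, t_value = tval,
    p_value = pval, sigma2 = sigma2, rho = rho, loglik = ll,
    aic = -2 * ll + 2 * (p + 2), r2_adj = base$r2_adj, n_obs = n,
    n_params = p, df_residual = n - p, fitted = fitted,
    residuals = d$y - fitted, weights = d$w, y = d$y, X = d$X,
    spec = spec, basis = d$basis, records = d$records,
    theta_idx = if (spec$lag_varying) 1L + seq_len(spec$K + 1L) else 2L),
    class = c("aphid_gls", "aphid_fit"))
}

#' Rank fitted models by AIC
#'
#' All fits must be computed on the identical record set (checked via
#' `n_obs`); otherwise their AICs are not comparable.
#'
#' @param ... `aphid_fit` objects, optionally named.
#' @return Data frame with columns `model`, `n_params`, `aic`, `delta_aic`
#'   and `r2_adj`, sorted by AIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "aphid_fit")) fits <- fits[[1L]]
  if (length(fits) < 2L) stop("need at least two fits to compare")
  nm <- names(fits)
  if (is.null(nm) || any(nm == "")) {
    auto <- vapply(fits, function(f)
      if (!is.null(f$spec)) paste0("model", f$spec$model) else "fit",
      character(1L))
    if (is.null(nm)) nm <- auto else nm[nm == ""] <- auto[nm == ""]
    nm <- make.unique(nm)
  }
  ns <- vapply(fits, function(f) f$n_obs, numeric(1L))
  if (length(unique(ns)) != 1L)
    stop("fits use different numbers of observations (",
         paste(ns, collapse = ", "), "); AICs are not comparable")
  out <- data.frame(
    model = nm,
    n_params = vapply(fits, function(f) f$n_params, numeric(1L)),
    aic = vapply(fits, function(f) f$aic, numeric(1L)),
    r2_adj = vapply(fits, function(f) f$r2_adj, numeric(1L)))
  out$delta_aic <- out$aic - min(out$aic)
  out <- out[order(out$aic), c("model", "n_params", "aic", "delta_aic", "r2_adj")]
  rownames(out) <- NULL
  out
}
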