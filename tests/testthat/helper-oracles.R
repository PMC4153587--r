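# Independent oracles used across the suite. Each re-derives a quantity by
# the most literal route available so the fast package paths are checked
# against something they share no code with.

# Naive day-by-day degree-day sums over a window: per-day lookup via match().
oracle_dd <- function(series, window, mode = "sum-above") {
  days <- window_days(window)
  t <- series$t_mean[match(days, series$day)]
  stopifnot(!anyNA(t))
  dd5 <- if (mode == "sum-above") sum(t[t > 5]) else sum(t[t > 5] - 5)
  dd05 <- sum(t[t >= 0 & t <= 5])
  # lag l counts backwards: lag 1 is the last window day
  contrib <- rev(if (mode == "sum-above") t * (t > 5) else (t - 5) * (t > 5))
  list(dd5 = dd5, dd05 = dd05, contrib = contrib)
}

# Literal Cox-de Boor recursion for a B-spline basis on an explicit knot
# vector, with the final interval closed on the right.
oracle_bspline <- function(knots, x, degree) {
  tmax <- max(knots)
  N0 <- function(i, u) {
    if (u < knots[i]) return(0)
    if (u < knots[i + 1L]) return(1)
    if (u == tmax && knots[i + 1L] == tmax && knots[i] < tmax) return(1)
    0
  }
  Nrec <- function(i, d, u) {
    if (d == 0L) return(N0(i, u))
    a <- 0
    if (knots[i + d] > knots[i])
      a <- (u - knots[i]) / (knots[i + d] - knots[i]) * Nrec(i, d - 1L, u)
    b <- 0
    if (knots[i + d + 1L] > knots[i + 1L])
      b <- (knots[i + d + 1L] - u) / (knots[i + d + 1L] - knots[i + 1L]) *
        Nrec(i + 1L, d - 1L, u)
    a + b
  }
  n_basis <- length(knots) - degree - 1L
  out <- matrix(0, length(x), n_basis)
  for (j in seq_along(x))
    for (i in seq_len(n_basis))
      out[j, i] <- Nrec(i, degree, x[j])
  out
}

# Closed-form weighted normal equations.
oracle_wls <- function(y, X, w) {
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1L]
}

# Interior local minima (strictly below both neighbours) of a lag curve.
interior_minima <- function(est) {
  n <- length(est)
  which(est[2:(n - 1)] < est[1:(n - 2)] & est[2:(n - 1)] < est[3:n]) + 1L
}

# A small contiguous temperature series with reproducible values.
toy_series <- function(n = 400, seed = 1, first = "2000-01-01") {
  set.seed(seed)
  temperature_series(as.Date(first) + 0:(n - 1),
                     round(stats::runif(n, -10, 25), 1))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
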