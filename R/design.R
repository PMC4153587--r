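# Regression design: model specification, B-spline lag basis, design matrix.

#' B-spline basis constraining the lag-coefficient curve
#'
#' Builds the Almon-type restriction matrix of the distributed-lag models:
#' the L lag-specific coefficients `beta_1l` are constrained to lie in the
#' span of `K + 1` B-spline basis functions evaluated at the integer lags
#' `1 ... L`, so `beta_1l = sum_k theta_k b_k(l)`. The basis is a B-spline
#' family of the given degree (cubic by default) with full-multiplicity
#' boundary knots at 1 and L and `K - degree` equally spaced interior knots,
#' giving exactly `K + 1` columns that form a partition of unity (every row
#' of the matrix sums to 1).
#'
#' @param L Window depth (number of lags); must exceed `K`.
#' @param K Basis dimension minus one (default 9, i.e. 10 basis functions).
#' @param degree Spline degree (default 3, cubic). `K = 0, degree = 0`
#'   degenerates to a single constant column, under which the distributed-lag
#'   model collapses algebraically to the pooled-DD5 model.
#' @return An object of class `lag_basis`: list with `depth_L`, `K`,
#'   `degree`, `knots` and the `L x (K+1)` matrix `B`.
#' @export
bspline_lag_basis <- function(L, K = 9L, degree = 3L) {
  L <- as.integer(L); K <- as.integer(K); degree <- as.integer(degree)
  if (is.na(L) || L < 2L) stop("`L` must be an integer >= 2")
  if (is.na(K) || K < 0L) stop("`K` must be a non-negative integer")
  if (is.na(degree) || degree < 0L || degree > K)
    stop("`degree` must satisfy 0 <= degree <= K")
  if (L <= K)
    stop(sprintf("L = %d <= K = %d: the lag curve is unidentifiable (need L > K)",
                 L, K))
  n_interior <- K - degree
  interior <- if (n_interior > 0L) {
    seq(1, L, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else numeric(0L)
  knots <- c(rep(1, degree + 1L), interior, rep(L, degree + 1L))
  B <- splines::splineDesign(knots, x = seq_len(L), ord = degree + 1L)
  colnames(B) <- paste0("theta", 0:K)
  structure(list(depth_L = L, K = K, degree = degree, knots = knots, B = B),
            class = "lag_basis")
}

#' @export
print.lag_basis <- function(x, ...) {
  cat(sprintf("<lag_basis> degree-%d B-splines, %d x %d (lags x basis), %d interior knots\n",
              x$degree, x$depth_L, x$K + 1L, length(x$knots) - 2L * (x$degree + 1L)))
  invisible(x)
}

#' Specify one of the four TSM regression models
#'
#' Models 1 and 2 regress TSM on the pooled standardized degree-day
#' covariates DD5/L and DD05/L; models 3 and 4 replace the single DD5 slope
#' by a lag-varying coefficient curve constrained to a B-spline basis
#' ([bspline_lag_basis()]). Odd-numbered models correct for the previous
#' year's maximum density, even-numbered ones for the previous year's TSM.
#' All models are heteroscedastic: the error variance is `sigma^2 /
#' n_weight^weight_exponent`, so plot-seasons inspected on more tillers get
#' proportionally more weight.
#'
#' @param model Model id, 1 to 4.
#' @param L Lag window depth, days.
#' @param K,degree Lag-basis dimension parameters (models 3 and 4 only);
#'   see [bspline_lag_basis()].
#' @param dd_mode DD5 accumulation mode, `"sum-above"` (default) or
#'   `"excess"`; see [dd5()].
#' @param weight_rule Tiller-weight rule, see [build_records()]. Recorded so
#'   a spec round-trips through its config file; [build_design()] itself uses
#'   the `n_weight` already present in the records.
#' @param weight_exponent Exponent `nu` in the variance function
#'   `sigma^2 / n^nu` (default 1).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(model, L, K = 9L, degree = 3L,
                        dd_mode = c("sum-above", "excess"),
                        weight_rule = c("total", "mean-per-date",
                                        "tillers-at-peak"),
                        weight_exponent = 1) {
  model <- as.integer(model)
  if (!model %in% 1:4) stop("`model` must be 1, 2, 3 or 4")
  dd_mode <- match.arg(dd_mode)
  weight_rule <- match.arg(weight_rule)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("`L` must be a positive integer")
  spec <- structure(list(
    model = model, L = L, K = as.integer(K), degree = as.integer(degree),
    dd_mode = dd_mode, weight_rule = weight_rule,
    weight_exponent = weight_exponent,
    density_term = if (model %in% c(1L, 3L)) "prev_max" else "prev_tsm",
    lag_varying = model %in% c(3L, 4L)), class = "design_spec")
  if (spec$lag_varying && L <= spec$K)
    stop("models 3 and 4 need L > K")
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> model %d: TSM ~ %s + DD05/L + %s, L = %d%s, weights n^%g (%s)\n",
              x$model,
              if (x$lag_varying)
                sprintf("B-spline lag curve (K = %d, degree %d)", x$K, x$degree)
              else "DD5/L",
              x$density_term, x$L,
              if (x$dd_mode == "excess") ", excess DD5" else "",
              x$weight_exponent, x$weight_rule))
  invisible(x)
}

#' Write / read a design specification as plain-text YAML
#'
#' @param spec A [design_spec()].
#' @param path File path.
#' @return `read_design_spec()` returns a [design_spec()];
#'   `write_design_spec()` returns `path` invisibly.
#' @export
write_design_spec <- function(spec, path) {
  yaml::write_yaml(list(model = spec$model, L = spec$L, K = spec$K,
                        degree = spec$degree, dd_mode = spec$dd_mode,
                        weight_rule = spec$weight_rule,
                        weight_exponent = spec$weight_exponent), path)
  invisible(path)
}

#' @rdname write_design_spec
#' @export
read_design_spec <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("model", "L")
  miss <- setdiff(need, names(y))
  if (length(miss) > 0L)
    stop("design spec file is missing field(s): ", paste(miss, collapse = ", "))
  design_spec(model = y$model, L = y$L,
              K = if (is.null(y$K)) 9L else y$K,
              degree = if (is.null(y$degree)) 3L else y$degree,
              dd_mode = if (is.null(y$dd_mode)) "sum-above" else y$dd_mode,
              weight_rule = if (is.null(y$weight_rule)) "total" else y$weight_rule,
              weight_exponent = if (is.null(y$weight_exponent)) 1 else y$weight_exponent)
}

#' Build the response, design matrix and weights for a TSM regression
#'
#' Assembles `y` (TSM), `X` and the weight vector `w` for the model in
#' `spec`. Columns are, in order: intercept; the DD5 block (one pooled
#' `DD5.std = DD5/L` column for models 1-2, or `K + 1` basis-projected
#' lag columns `theta0 ... thetaK` for models 3-4, computed as `(Z/L) B`
#' where `Z[i, l]` is the per-lag DD5 contribution of record `i`);
#' `DD05.std = DD05/L`; and the previous-year density-dependence term.
#' Standardization is by `1/L` only (no centering or rescaling), so
#' coefficients are directly comparable across models and window depths.
#' Records whose previous-year term is missing are excluded with a logged
#' count; a record whose lag window is not fully covered by the temperature
#' series is an error.
#'
#' @param records Plot-season records from [build_records()] (or the
#'   generator's ground-truth table).
#' @param temps A [temperature_series()] covering every record's window.
#' @param spec A [design_spec()].
#' @return List of class `aphid_design`: `y`, `X`, `w`, `records` (the rows
#'   used), `basis` (models 3-4, else `NULL`), `spec`, `n_dropped`.
#' @export
build_design <- function(records, temps, spec) {
  if (!inherits(spec, "design_spec")) stop("`spec` must be a design_spec")
  prev <- records[[spec$density_term]]
  if (is.null(prev)) stop("records lack column ", spec$density_term)
  keep <- !is.na(prev) & !is.na(records$tsm)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " record(s) without a ", spec$density_term,
            " value excluded from the design")
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("no usable records")

  cache <- .dd_cache(temps)
  L <- spec$L
  a <- as.integer(as.Date(records$start_day) - cache$d0) + 1L
  if (any(a - L < 1L)) {
    i <- which(a - L < 1L)[1L]
    stop(sprintf(paste0(
      "record %d/%s: %d-day window before %s extends before the first ",
      "temperature day %s (earliest feasible anchor %s)"),
      records$year[i], records$plot[i], L,
      format(as.Date(records$start_day[i])),
      format(cache$d0), format(cache$d0 + L)))
  }
  if (any(a - 1L > cache$n))
    stop("a record's window extends past the last temperature day")
  np <- cache$cpres[a - 1L] - ifelse(a - L - 1L >= 1L, cache$cpres[pmax(a - L - 1L, 1L)], 0)
  if (any(np < L)) {
    i <- which(np < L)[1L]
    stop(sprintf("record %d/%s: %d day(s) missing from the temperature series in its window",
                 records$year[i], records$plot[i], L - np[i]))
  }

  v5 <- if (spec$dd_mode == "sum-above") cache$v5 else cache$v5x
  c5 <- if (spec$dd_mode == "sum-above") cache$c5 else cache$c5x
  dd5_v <- c5[a - 1L] - ifelse(a - L - 1L >= 1L, c5[pmax(a - L - 1L, 1L)], 0)
  dd05_v <- cache$c05[a - 1L] - ifelse(a - L - 1L >= 1L, cache$c05[pmax(a - L - 1L, 1L)], 0)

  n <- nrow(records)
  basis <- NULL
  if (spec$lag_varying) {
    basis <- bspline_lag_basis(L, spec$K, spec$degree)
    # Z[i, l] = per-lag contribution of day (anchor_i - l), standardized by L
    Z <- matrix(v5[outer(a, seq_len(L), `-`)], nrow = n) / L
    Xdd <- Z %*% basis$B
  } else {
    Xdd <- matrix(dd5_v / L, ncol = 1L, dimnames = list(NULL, "DD5.std"))
  }
  X <- cbind("(Intercept)" = 1, Xdd, DD05.std = dd05_v / L,
             records[[spec$density_term]])
  colnames(X)[ncol(X)] <- spec$density_term
  w <- as.numeric(records$n_weight)^spec$weight_exponent
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive and finite")
  structure(list(y = as.numeric(records$tsm), X = X, w = w,
                 records = records, basis = basis, spec = spec,
                 dd5 = dd5_v, dd05 = dd05_v, n_dropped = n_dropped),
            class = "aphid_design")
}
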