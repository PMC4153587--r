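---
title: "Degree-day distributed-lag regression for the aphid growth period"
author: "aphidlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day distributed-lag regression for the aphid growth period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidlag)
```

## The question and the response variable

Cereal aphids (*Metopolophium dirhodum*, *Sitobion avenae*, *Rhopalosiphum
padi*) colonise winter wheat in spring, grow quickly, peak, and collapse
with crop senescence, so their abundance trajectory is a left-skewed
triangle. How large the peak gets is largely set by how long the population
can grow. This package models that growth period — **TSM**, the
time-from-start-to-maximum: for each year $i$ and plot $j$, the number of
days between the first sampling date with non-zero aphid density and the
date the observed density reaches its maximum. Densities are total aphids
found divided by total tillers inspected on a date
(`density_series()`); `tsm_from_series()` resolves the start and the peak
on the weekly sampling grid, breaking peak ties toward the earliest date,
so TSM is the shortest defensible value. No interpolation between sampling
dates is attempted: with weekly counts, both quantities are only known to
the grid.

The explanatory variables are thermal histories before the *local* season
start. Two degree-day covariates are accumulated over an $L$-day window
that ends the day before the season start (anchor-exclusive, lags counted
backwards from the anchor):

* **DD5** — the sum of daily mean temperatures on days above 5 °C, the
  development threshold for cereal aphids;
* **DD05** — the sum of daily mean temperatures on days inside the closed
  interval [0, 5] °C, where winter wheat develops but aphids do not.

Both are standardized by $1/L$ in the regressions so that coefficients are
comparable across window depths. Two boundary conventions matter and are
fixed as follows: DD5 uses the strict inequality $> 5$ and DD05 the closed
interval $[0, 5]$, so the covariates are disjoint (a day at exactly 5 °C
counts in DD05 only). And because "the sum of daily temperatures above
5 °C" can be read two ways, `dd5()` has two modes: the default
`"sum-above"` accumulates the temperature itself on qualifying days —
chosen because DD05, a sum over a bounded interval, only makes sense as a
sum of temperatures, and the two covariates should be treated symmetrically
— while `"excess"` gives the classical exceedance $\sum (T - 5)^+$ for
users who want the textbook degree-day.

## The four regression models

With $x_{ij}$ the standardized degree-day pair and $n_{ij}$ the tillers
inspected on plot $j$ in year $i$, model (1) is

$$\mathrm{TSM}_{ij} = \mu + \beta_1\,\frac{DD5_{ij}}{L}
 + \delta\,\frac{DD05_{ij}}{L} + \gamma\,\bar M_{i-1} + \varepsilon_{ij},
 \qquad \varepsilon_{ij} \sim N\!\left(0,\ \sigma^2 / n_{ij}\right),$$

where $\bar M_{i-1}$ is the previous year's maximum density averaged over
the plots investigated that year. Model (2) replaces $\bar M_{i-1}$ by the
previous year's mean TSM. The heteroscedastic variance $\sigma^2/n_{ij}$
encodes that a plot-season counted on more tillers carries more
information; the exponent $\nu$ in $\sigma^2/n^\nu$ is configurable
(`weight_exponent`), with $\nu = 1$ the default. Because TSM is one number
per plot-season while tillers vary by date, the default weight is the
*total* tillers inspected over the plot-season (the total information in
the trajectory); `"mean-per-date"` and `"tillers-at-peak"` are selectable
alternatives.

Models (3) and (4) relax the assumption that a degree-day is worth the same
whether it falls one day or four months before the season start. Each lag
$l$ gets its own coefficient on the per-day DD5 contribution $x_{ij,l}$:

$$\mathrm{TSM}_{ij} = \mu + \sum_{l=1}^{L} \beta_{1l}\,\frac{x_{ij,l}}{L}
 + \delta\,\frac{DD05_{ij}}{L} + \gamma\,(\cdot)_{i-1} + \varepsilon_{ij}.$$

Unrestricted, the $\beta_{1l}$ are unidentifiable; in the Almon tradition
they are constrained to the span of $K+1$ B-spline basis functions,
$\beta_{1l} = \sum_k \theta_k b_k(l)$, with $K = 9$ by default. The basis
(`bspline_lag_basis()`) is cubic with full-multiplicity boundary knots at
lags 1 and $L$ and $K - 3$ equally spaced interior knots, giving exactly
$K+1$ columns that form a partition of unity. The degree and knot layout
are package defaults exposed in the spec — only the family and $K$ are
scientifically fixed — and sensitivity to them should be checked rather
than assumed away. The basis-dimension restriction *is* the
regularization; no penalized smoothness selection is performed. With
$K = 0$ and degree 0 the basis is a single constant column and model (3)
collapses algebraically onto model (1); this degeneracy is verified to
1e-10 in the tests and is a useful end-to-end check of the design builder.

One indexing note: the lag coefficients are sometimes written
$\beta_{10}, \ldots, \beta_{1L}$ ($L+1$ values) although the window spans
$L$ days; this package uses exactly $L$ lags, $l = 1$ (the day before the
anchor) through $l = L$, and one coefficient per lag.

## Estimation, AIC, and the selection of L

`wls_fit()` estimates all models by iteratively reweighted least squares;
with fixed, known weights the loop's fixed point is the one-shot weighted
least-squares solution (it converges at the first re-solve; the loop is
kept as the general path, tolerance 1e-10 on coefficient change, at most
50 iterations). Standard errors use $\hat\sigma^2 = $ weighted RSS
$/(n-p)$ and p-values are two-sided $t$ with $n - p$ degrees of freedom —
a small-sample choice that can move third decimals relative to
normal-based output. The AIC uses the full Gaussian log-likelihood —
constants $2\pi$ and $\sum \log w_i$ included, ML variance inside — with
$k = p + 1$ parameters ($\sigma^2$ counted). This makes AICs comparable
across models 1–4 on identical records, but absolute AIC values are
software-convention dependent and are not comparable across programs; only
AIC *differences* on the same data are meaningful, and `compare_models()`
refuses fits with differing record counts.

The window depth $L$ is not set a priori: `profile_L()` refits the model at
every candidate depth and minimizes the AIC over non-negative integers
(profiled optimization). Two details the profiling fixes by design: all
candidates are fitted on the single record subset whose windows are covered
at the *deepest* candidate, so the AICs are comparable; and exact ties
resolve to the smallest $L$ (the most parsimonious history depth).
Candidates deeper than any feasible window are dropped with a log entry.

For the distributed-lag fits, `lag_curve()` maps
$\hat\beta_{1l} = \sum_k \hat\theta_k b_k(l)$ with the pointwise asymptotic
band $\pm 1.96\sqrt{b(l)^\top \widehat{\mathrm{Cov}}(\hat\theta)\, b(l)}$,
and `joint_dd5_test()` tests $\theta = 0$ (equivalently all
$\beta_{1l} = 0$) with a Wald statistic referred to $F(K+1,\ n-p)$ by
default (a $\chi^2$ version is available). Estimates at the deep-lag
boundary deserve skepticism: in mid-winter almost no day exceeds 5 °C, the
per-lag regressors are mostly zero there, and the band balloons — curve
features near lag $L$ are typically artifacts, which is why shape summaries
in the tests use interior turning points only.

Because plots sampled in the same year share weather and management,
`fit_random_year_gls()` refits any model allowing exchangeable
(compound-symmetric) correlation $\rho$ among same-year plots on the
weight-standardized scale, retaining the $\sigma^2/n$ weights. $\rho$ is
estimated by the method of moments on the standardized WLS residuals,
clipped to $[0, 1)$, followed by one feasible GLS solve; with $\rho = 0$ or
a single plot per year the fit reduces exactly to WLS. The GLS AIC counts
$p + 2$ parameters. An independent check against `nlme::gls()` with the
correlation fixed at the same $\rho$ agrees to 1e-6 in the test suite.

## What the synthetic generator emulates

`synthetic_config()` + `simulate_panel()` generate complete study-shaped
datasets: 24 years (default) of 3–6 plots, weekly counts on 50–300 tillers
per plot-date over 6–10 weeks of presence, season starts drawn around
day-of-year 143, left-skewed triangular density trajectories, and TSM drawn
from the linear model above with variance $\sigma^2/n_{ij}$. Temperatures
follow a seasonal sine (annual mean 8.2 °C, amplitude 10 °C, warmest near
mid-July) plus stationary AR(1) day-to-day noise (sd 3 °C, coefficient
0.7) — a Central-European lowland climate. Defaults for the truth are
$(\beta_1, \delta, \gamma) = (-15, -20, 0)$ and $L = 123$;
$\sigma^2 = 35000$ gives a residual SD near 5 days at a typical 1400-tiller
total, and $\mu = 135$ centres TSM near seven weeks while keeping the
expected TSM positive across climate realizations (an untenable
configuration — negative expected TSM under the noise-free seasonal
climate — is rejected at generation time; rare realized negatives from
climate extremes truncate at zero, i.e. the density peaks at the season
start). Generated TSM is rounded to the weekly sampling grid so that the
trajectory peak falls on a sampling date and `tsm_from_series()` recovers
it exactly; counts are Poisson around density × tillers (switchable off for
noiseless checks). The geometric rise is floored at a detection-scale
density of 0.1 aphids/tiller at the start, without which long seasons would
begin below one aphid per count and the observed start would drift late.
A bimodal lag-curve preset (`bimodal_lag_curve()`: coefficient −40 at lags
50–80 and 90–110, zero elsewhere) provides a lag-varying truth for power
and shape-recovery experiments, mimicking sensitivity periods around egg
dormancy termination and hatching.

Deliberate simplifications, and hence what passing tests do *not* show
about field data: season starts are drawn independently of temperature (a
temperature-triggered start would confound the covariates with the anchor;
matching the generator to the fitted model is the point of the recovery
tests), there is no mechanistic aphid biology (generations, enemies,
senescence), no spatial structure among plots, and no within-year error
correlation unless injected. When a long TSM outgrows the planned season
length the trajectory is extended with extra sampling dates, so the
panel's total tiller count can exceed the generative weight for those rare
plot-seasons. Grid rounding adds a homoscedastic noise component (variance
$\approx 49/12$) outside the $\sigma^2/n$ model; at the default noise
scale this is a ~14 % variance misstatement that leaves recovery unbiased
and coverage within its Monte-Carlo band, but it mildly inflates the joint
Wald test's size (to ~0.07 at 500 replicates). Type-I calibration
experiments therefore generate with `round_to_grid = FALSE`, drawing
errors from the assumed model — a test of the statistic, not of the
rounding artifact, which is documented here instead.

## Problem sizes and numerical choices

The validation experiments run at study scale: 500 generate-and-fit
replicates for coverage (24 × 6 plot-seasons each), 50 replicates × 21
candidate depths for $L$ recovery, 500 null and 100 alternative replicates
for the Wald test, and 100 replicates for lag-curve shape recovery; the
whole suite completes in a couple of minutes on one core because designs
are built from cumulative day-indexed sums. The public degree-day
functions instead sum window days directly in calendar order, so they
agree bit-for-bit with a naive day-by-day loop; the cumulative-sum design
path is checked against them to 1e-12. Other numerical conventions: rank
deficiency in the design is an error naming the collinear columns;
weights must be strictly positive; the weighted adjusted $R^2$ is reported
on the weighted scale by default with the unweighted version alongside,
since which scale published values use is often unstated.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(plots_per_year = c(6, 6))
sim <- simulate_panel(cfg, seed = 42)
records <- build_records(sim$panel)

prof <- profile_L(records, sim$temperature, design_spec(1, L = 123),
                  seq(60, 160, by = 5))
prof$best_L

f1 <- fit_model(records, sim$temperature, design_spec(1, L = prof$best_L))
coef_table(f1)

f3 <- fit_model(records, sim$temperature, design_spec(3, L = prof$best_L))
joint_dd5_test(f3)
plot(lag_curve(f3))
compare_models(f1, f3)
```

## Known limitations

Absolute AIC values depend on likelihood constants and will not match
numbers computed under other software conventions; only within-run
differences are interpretable. The profiled $L$ is treated as fixed in all
downstream inference — quantifying the extra variability induced by
estimating $L$ would need far more data than a 24-year panel. The
moment-based $\rho$ is attenuated when year-level covariates absorb part
of the between-year variance. The legacy wide-spreadsheet ingest layout is
not supported; data enter as plain CSV (`read_temperature()`,
`read_counts()`), and sub-daily station records can be aggregated with
`read_subdaily_temperature()`. Temperature series are never interpolated:
windows with missing days error by default, with an explicit
`"renormalize"` policy (rescale by $L/\text{days present}$, with a
warning) as the only alternative.
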