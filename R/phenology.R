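# Aphid count panels, densities, TSM and regression records.

# Validate a count panel: year, plot, date, aphids, tillers.
.validate_panel <- function(panel) {
  need <- c("year", "plot", "date", "aphids", "tillers")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0L)
    stop("count panel is missing column(s): ", paste(miss, collapse = ", "))
  panel$date <- as.Date(panel$date)
  if (anyNA(panel$date)) stop("unparseable date in count panel")
  panel$year <- as.integer(panel$year)
  if (anyNA(panel$year)) stop("non-integer year in count panel")
  if (any(!is.finite(panel$aphids) | panel$aphids < 0))
    stop("aphid counts must be non-negative")
  if (any(!is.finite(panel$tillers) | panel$tillers < 1))
    stop("tiller counts must be >= 1 (zero-tiller observations carry no information)")
  key <- paste(panel$year, panel$plot, panel$date)
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1L]
    stop("duplicate (year, plot, date) observation: ", k)
  }
  panel
}

#' Aphid density series for one plot-season
#'
#' Converts the counts of one plot-year into densities, defined as the total
#' number of aphids found (all species summed) divided by the total number of
#' tillers inspected on that date.
#'
#' @param obs Data frame with columns `date`, `aphids`, `tillers` for a
#'   single plot and year.
#' @return Data frame with columns `date` and `density` (aphids per tiller),
#'   in date order.
#' @export
density_series <- function(obs) {
  if (NROW(obs) == 0L) stop("no observations")
  if (any(!is.finite(obs$tillers) | obs$tillers < 1))
    stop("tiller counts must be >= 1")
  if (any(!is.finite(obs$aphids) | obs$aphids < 0))
    stop("aphid counts must be non-negative")
  date <- as.Date(obs$date)
  o <- order(date)
  data.frame(date = date[o], density = (obs$aphids / obs$tillers)[o])
}

#' Season start and time-from-start-to-maximum (TSM)
#'
#' The season start is the earliest sampled date with a non-zero density;
#' TSM is the number of days from that start to the date on which the
#' observed density reaches its maximum. Ties in the maximum are broken by
#' the earliest date attaining it, so TSM is the shortest defensible value.
#' Because sampling is weekly, both quantities are resolved only to the
#' sampling grid; no interpolation between sampling dates is attempted.
#'
#' @param densities Data frame with columns `date` and `density`, as from
#'   [density_series()] (any non-negative density series works).
#' @return List with elements `start_day` (Date) and `tsm` (days, >= 0).
#' @export
#' @examples
#' d <- data.frame(date = as.Date("2001-01-01") + c(120, 127, 141, 148),
#'                 density = c(0, 0.2, 1.0, 0.5))
#' tsm_from_series(d)  # start at day 127 offset, tsm 14
tsm_from_series <- function(densities) {
  date <- as.Date(densities$date)
  dens <- densities$density
  if (any(!is.finite(dens) | dens < 0)) stop("densities must be non-negative")
  o <- order(date)
  date <- date[o]; dens <- dens[o]
  if (all(dens == 0)) stop("no season detected: all densities are zero")
  start <- date[which(dens > 0)[1L]]
  peak <- date[which.max(dens)]  # which.max takes the earliest tie
  list(start_day = start, tsm = as.numeric(peak - start))
}

#' Build per-plot-season regression records from a count panel
#'
#' Assembles, for every (year, plot) with a detected season, the row the
#' regressions consume: season start, TSM, the sampling-effort weight and
#' the previous-year summaries used as density-dependence corrections.
#' `prev_max` is the previous year's maximum density averaged over the plots
#' investigated that year (plot-level maxima, then the mean over plots);
#' `prev_tsm` is the previous year's TSM averaged the same way. Both are `NA`
#' for the first panel year and for years whose calendar predecessor is
#' absent; fits requiring them drop such records with a logged count.
#'
#' @param panel Data frame with columns `year`, `plot`, `date`, `aphids`,
#'   `tillers`; one row per (year, plot, date).
#' @param weight_rule How the tiller weight `n_weight` of a plot-season is
#'   computed: `"total"` (default; total tillers inspected over the
#'   plot-season, the total information in the trajectory),
#'   `"mean-per-date"`, or `"tillers-at-peak"`.
#' @return Data frame with one row per plot-season: `year`, `plot`,
#'   `start_day`, `tsm`, `n_weight`, `max_density`, `prev_max`, `prev_tsm`.
#'   Plot-years with no non-zero count are skipped (count in attribute
#'   `"n_skipped"`, announced via `message()`).
#' @export
build_records <- function(panel,
                          weight_rule = c("total", "mean-per-date",
                                          "tillers-at-peak")) {
  weight_rule <- match.arg(weight_rule)
  panel <- .validate_panel(panel)
  keys <- unique(panel[, c("year", "plot")])
  keys <- keys[order(keys$year, keys$plot), , drop = FALSE]
  rows <- vector("list", nrow(keys))
  n_skipped <- 0L
  for (r in seq_len(nrow(keys))) {
    obs <- panel[panel$year == keys$year[r] & panel$plot == keys$plot[r], ]
    ds <- density_series(obs)
    if (all(ds$density == 0)) {
      n_skipped <- n_skipped + 1L
      next
    }
    s <- tsm_from_series(ds)
    obs <- obs[order(as.Date(obs$date)), ]
    nw <- switch(weight_rule,
      "total" = sum(obs$tillers),
      "mean-per-date" = mean(obs$tillers),
      "tillers-at-peak" = obs$tillers[which.max(ds$density)])
    rows[[r]] <- data.frame(
      year = keys$year[r], plot = keys$plot[r],
      start_day = s$start_day, tsm = s$tsm, n_weight = nw,
      max_density = max(ds$density))
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no plot-season with a detected season")
  if (n_skipped > 0L)
    message(n_skipped, " plot-year(s) without a detected season skipped")
  rec <- do.call(rbind, rows)
  yr_max <- tapply(rec$max_density, rec$year, mean)
  yr_tsm <- tapply(rec$tsm, rec$year, mean)
  prev <- as.character(rec$year - 1L)
  rec$prev_max <- as.vector(yr_max[prev])
  rec$prev_tsm <- as.vector(yr_tsm[prev])
  rownames(rec) <- NULL
  attr(rec, "n_skipped") <- n_skipped
  rec
}
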