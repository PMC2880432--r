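#' Population doublings from subculture counts
#'
#' The standard bookkeeping of serial culture: `PD = log(A/B)/log(2)` with
#' `A` the number of cells collected at harvest and `B` the number plated.
#'
#' @param collected Harvested cell count (> 0).
#' @param plated Plated cell count (> 0).
#' @return Doublings (may be negative if the population shrank).
#' @export
population_doublings <- function(collected, plated) {
  if (any(collected <= 0) || any(plated <= 0))
    stop("counts must be positive", call. = FALSE)
  log(collected / plated) / log(2)
}

.dedupe_curve <- function(t, pd) {
  keep <- !duplicated(t)
  list(t = t[keep], pd = pd[keep])
}

#' Detect the growth plateau of a population-doubling curve
#'
#' A plateau is the period during which the population-doubling rate departs
#' from the culture's own exponential rate. The baseline rate is measured on
#' the first passage (the unambiguous exponential phase); the smoothed rate
#' (centered difference over `window_days`) is then compared against
#' `rate_threshold * baseline`, and the longest contiguous sub-threshold
#' interval is the plateau. The reported width corrects for the smoothing
#' window's edge bias (`+ window_days * (1 - 2 * rate_threshold)`, exact for
#' a piecewise-linear curve); an interval running into the end of the record
#' is extended by the half-window instead.
#'
#' @param record A `growth_record` for a single replicate.
#' @param rate_threshold Fraction of the baseline rate below which growth
#'   counts as stalled (default 0.25).
#' @param window_days Smoothing window for the rate estimate (default 2).
#' @return An object of class `plateau_estimate`: `start_day`, `width_days`
#'   (0 if no plateau), `start_pd` (cumulative doublings at onset),
#'   `baseline_rate` (doublings/day), `threshold_used`, `window_days`.
#' @export
detect_plateau <- function(record, rate_threshold = 0.25, window_days = 2) {
  stopifnot(is.data.frame(record))
  if (length(unique(record$passage)) < 2)
    stop("record must span at least 2 passages", call. = FALSE)
  cur <- .dedupe_curve(record$time_days, record$cumulative_pd)
  t <- cur$t
  pd <- cur$pd
  p1 <- record$passage == min(record$passage)
  t1 <- record$time_days[p1]
  pd1 <- record$cumulative_pd[p1]
  span1 <- max(t1) - min(t1)
  if (span1 <= 0) stop("first passage has no duration", call. = FALSE)
  baseline <- (max(pd1) - min(pd1)) / span1
  if (baseline <= 0) stop("no growth in the first passage", call. = FALSE)

  f <- stats::approxfun(t, pd, rule = 2)
  h <- window_days / 2
  step <- 1 / 24
  if (max(t) - min(t) <= window_days)
    stop("record shorter than the smoothing window", call. = FALSE)
  tt <- seq(min(t) + h, max(t) - h, by = step)
  rate <- (f(tt + h) - f(tt - h)) / window_days
  low <- rate < rate_threshold * baseline

  est <- list(start_day = NA_real_, width_days = 0, start_pd = NA_real_,
              baseline_rate = baseline, threshold_used = rate_threshold,
              window_days = window_days)
  if (any(low)) {
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    i0 <- starts[best]
    i1 <- ends[best]
    width <- tt[i1] - tt[i0]
    # edge-bias correction, per interior edge; record-boundary edges get the
    # half-window instead (the plateau plausibly extends past the data)
    corr_edge <- window_days * (0.5 - rate_threshold)
    width <- width + (if (i0 > 1) corr_edge else h) +
      (if (i1 < length(tt)) corr_edge else h)
    start <- tt[i0] - (if (i0 > 1) corr_edge else h)
    est$start_day <- start
    est$width_days <- width
    est$start_pd <- f(start)
  }
  class(est) <- "plateau_estimate"
  est
}

#' @export
print.plateau_estimate <- function(x, ...) {
  if (x$width_days == 0) {
    cat("<plateau_estimate> no plateau detected\n")
  } else {
    cat(sprintf(
      "<plateau_estimate> start day %.1f (%.2f PD), width %.1f days\n",
      x$start_day, x$start_pd, x$width_days))
  }
  cat(sprintf("  baseline %.3f PD/day, threshold %.2f, window %.1f days\n",
              x$baseline_rate, x$threshold_used, x$window_days))
  invisible(x)
}

#' Fit the plateau-width vs initial-fraction power law
#'
#' Ordinary least squares of `log W = log a - b log f`, i.e. the inverse
#' power function `W = a * f^(-b)` linking plateau width to the initial
#' variant fraction.
#'
#' @param fraction Initial variant fractions (> 0), at least 3 distinct.
#' @param width Plateau widths in days (> 0).
#' @return An object of class `power_law_fit`: `a` (days), `b` (> 0 for an
#'   inverse dependence), `r_squared`, `sigma_log` (residual SD on the log
#'   scale) and the fitted range of `fraction`.
#' @export
fit_plateau_power_law <- function(fraction, width) {
  if (is.data.frame(fraction)) {
    width <- fraction$width
    fraction <- fraction$fraction
  }
  ok <- is.finite(fraction) & is.finite(width)
  fraction <- fraction[ok]
  width <- width[ok]
  if (length(unique(fraction)) < 3)
    stop("need at least 3 distinct fractions", call. = FALSE)
  if (any(fraction <= 0) || any(width <= 0))
    stop("fractions and widths must be positive", call. = FALSE)
  fit <- stats::lm(log(width) ~ log(fraction))
  b <- -unname(coef(fit)[2])
  a <- exp(unname(coef(fit)[1]))
  if (b <= 0)
    warning("fitted exponent is not positive: width does not decrease with ",
            "the initial fraction", call. = FALSE)
  res <- stats::residuals(fit)
  sst <- sum((log(width) - mean(log(width)))^2)
  structure(list(a = a, b = b,
                 r_squared = if (sst > 0) 1 - sum(res^2) / sst else 1,
                 sigma_log = sqrt(sum(res^2) / max(1, length(width) - 2)),
                 fraction_range = range(fraction),
                 n = length(fraction)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> W = %.3f * f^(-%.3f) days (R^2 = %.3f, n = %d)\n",
    x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Infer the initial variant fraction from a plateau width
#'
#' Inverts the fitted power law: `f = (a / W)^(1 / b)`. Extrapolating beyond
#' the fitted fraction range triggers a warning (the relation is routinely
#' extrapolated to interpret specimens, but with less support).
#'
#' @param fit A [fit_plateau_power_law()] result.
#' @param width Observed plateau width in days (> 0).
#' @return The inferred initial variant fraction.
#' @export
infer_initial_fraction <- function(fit, width) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(width <= 0)) stop("width must be positive", call. = FALSE)
  f <- (fit$a / width)^(1 / fit$b)
  out_of_range <- f < fit$fraction_range[1] | f > fit$fraction_range[2]
  if (any(out_of_range))
    warning("inferred fraction extrapolates beyond the fitted range",
            call. = FALSE)
  f
}

#' Per-timepoint dispersion of replicate growth curves
#'
#' Cumulative-doubling curves are interpolated onto a shared time grid; at
#' each timepoint the standard error across replicates and the relative
#' standard error (SE/mean) are computed. Timepoints before the population's
#' first doubling (mean PD < 1) are excluded from the maximum: SE/mean
#' diverges trivially as the mean approaches 0.
#'
#' @param records List of `growth_record`s (>= 2 for a defined RSE).
#' @param min_pd Mean-PD floor for inclusion in the reported maximum.
#' @return A list of class `rse_summary`: `time_days`, `mean_pd`, `se`,
#'   `rse`, `max_rse` (NA with a single replicate), `n`.
#' @export
relative_standard_error <- function(records, min_pd = 1) {
  if (inherits(records, "growth_record")) records <- list(records)
  n <- length(records)
  stopifnot(n >= 1)
  t_end <- min(vapply(records, function(r) max(r$time_days), numeric(1)))
  tt <- seq(0, t_end, by = 1 / 24)
  curves <- vapply(records, function(r) {
    cur <- .dedupe_curve(r$time_days, r$cumulative_pd)
    stats::approxfun(cur$t, cur$pd, rule = 2)(tt)
  }, numeric(length(tt)))
  curves <- matrix(curves, nrow = length(tt))
  mean_pd <- rowMeans(curves)
  if (n >= 2) {
    se <- apply(curves, 1, stats::sd) / sqrt(n)
    rse <- ifelse(mean_pd > 0, se / mean_pd, NA_real_)
    eligible <- mean_pd >= min_pd
    max_rse <- if (any(eligible)) max(rse[eligible]) else NA_real_
  } else {
    se <- rep(NA_real_, length(tt))
    rse <- rep(NA_real_, length(tt))
    max_rse <- NA_real_
  }
  structure(list(time_days = tt, mean_pd = mean_pd, se = se, rse = rse,
                 max_rse = max_rse, n = n),
            class = "rse_summary")
}

#' Sweep the initial variant fraction and measure plateau widths
#'
#' Runs replicate serial cultures at each initial fraction, detects the
#' plateau of each record, and averages widths per fraction. Replicates in
#' which the variant lineage went extinct (no variant agents at the end,
#' possible for very small initial fractions via subculture sampling) show no
#' resumed growth and are censored with a warning.
#'
#' @param fractions Initial variant fractions to simulate.
#' @param replicates Replicates per fraction; recycled along `fractions`, so
#'   extinction-prone fractions (a single seeded variant) can be given more
#'   runs than the rest.
#' @param base_seed Seed root; run (i, j) uses `base_seed + 1000 * i + j`.
#' @param dynamics,passaging,grid Passed to [run_serial_culture()].
#' @param n_agents Seeded agents per culture.
#' @param rate_threshold,window_days Passed to [detect_plateau()].
#' @return A data frame of class `plateau_sweep` with columns `fraction`,
#'   `width` (mean days across usable replicates) and `n_used`; per-run
#'   detail in `attr(, "detail")`.
#' @export
run_fraction_sweep <- function(fractions, replicates = 3, base_seed = 1,
                               dynamics = dynamics_params(),
                               passaging = passage_config(),
                               grid = create_grid(), n_agents = 1200,
                               rate_threshold = 0.25, window_days = 2) {
  replicates <- rep_len(replicates, length(fractions))
  detail <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    for (j in seq_len(replicates[i])) {
      rec <- run_serial_culture(
        dynamics, passaging, seeding_spec(n_agents, f), grid,
        seed = base_seed + 1000 * i + j, replicate = j)
      last <- rec[nrow(rec), ]
      extinct <- (last$n_variant_proliferative +
                    last$n_variant_senescent) == 0
      width <- if (extinct) NA_real_ else {
        detect_plateau(rec, rate_threshold, window_days)$width_days
      }
      detail[[length(detail) + 1L]] <-
        data.frame(fraction = f, replicate = j, width = width,
                   extinct = extinct)
    }
  }
  detail <- do.call(rbind, detail)
  if (any(detail$extinct))
    warning(sum(detail$extinct),
            " run(s) lost the variant lineage and were censored",
            call. = FALSE)
  agg <- do.call(rbind, lapply(split(detail, detail$fraction), function(d) {
    data.frame(fraction = d$fraction[1],
               width = mean(d$width, na.rm = TRUE),
               n_used = sum(!is.na(d$width)))
  }))
  agg <- agg[order(agg$fraction), ]
  rownames(agg) <- NULL
  agg <- agg[agg$n_used > 0, ]
  class(agg) <- c("plateau_sweep", "data.frame")
  attr(agg, "detail") <- detail
  agg
}
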