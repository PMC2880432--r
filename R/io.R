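#' Write growth records to CSV
#'
#' One or several replicate records are concatenated. Metadata (master seed
#' and a compact configuration fingerprint, when available) is embedded as
#' `#`-prefixed comment lines so re-runs are traceable to their inputs.
#'
#' @param records A `growth_record` or a list of them.
#' @param path Output CSV path.
#' @param seed Master seed to embed (defaults to the record attribute).
#' @param config Optional `experiment_config` to fingerprint.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(records, path, seed = NULL, config = NULL) {
  if (inherits(records, "growth_record")) records <- list(records)
  all <- do.call(rbind, lapply(records, as.data.frame))
  if (is.null(seed)) seed <- attr(records[[1]], "seed")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", if (is.null(seed)) "NA" else seed), con)
  if (!is.null(config)) {
    fp <- jsonlite::toJSON(list(
      name = config$name,
      n_agents = config$seeding$n_agents,
      variant_fraction = config$seeding$variant_fraction,
      limits = c(config$dynamics$division_limit_normal,
                 config$dynamics$division_limit_variant),
      trigger = config$passaging$trigger_saturation,
      dose_gy = if (is.null(config$radiation)) 0 else
        config$radiation$dose_gy), auto_unbox = TRUE)
    writeLines(sprintf("# config: %s", fp), con)
  }
  utils::write.csv(all, con, row.names = FALSE)
  invisible(path)
}

#' Read a growth-record CSV written by [write_growth_csv()]
#'
#' @param path CSV path.
#' @return A `growth_record` data frame (possibly multiple replicates).
#' @export
read_growth_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  class(d) <- c("growth_record", "data.frame")
  d
}

#' Class/state label image of a culture
#'
#' Collapses the occupancy grid into display codes: 0 free, 1 proliferative
#' normal, 2 proliferative variant, 3 senescent (either class).
#'
#' @param state A `sim_state`.
#' @return An integer matrix of display codes.
#' @export
snapshot_matrix <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  lab <- state$grid$label
  a <- state$agents
  code <- integer(nrow(a) + 1L)  # index 1 = free
  code[-1L] <- ifelse(a$state == "senescent", 3L,
                      ifelse(a$class == "variant", 2L, 1L))
  matrix(code[lab + 1L], nrow(lab), ncol(lab))
}

#' Write a culture snapshot
#'
#' Renders the label image with the conventional palette — proliferating
#' normal cells red, variants green, senescent cells blue, free space white —
#' as PNG (requires the `png` package) and/or as a plain-text label matrix.
#'
#' @param state A `sim_state`.
#' @param png_path,text_path Output paths (either may be `NULL`).
#' @return Invisibly, the display-code matrix.
#' @export
render_snapshot <- function(state, png_path = NULL, text_path = NULL) {
  m <- snapshot_matrix(state)
  if (!is.null(text_path)) {
    utils::write.table(m, text_path, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(png_path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG rendering requires the 'png' package", call. = FALSE)
    pal <- rbind(c(1, 1, 1),      # free
                 c(0.85, 0.1, 0.1),  # normal proliferative
                 c(0.1, 0.65, 0.1),  # variant proliferative
                 c(0.15, 0.25, 0.8)) # senescent
    img <- array(0, dim = c(nrow(m), ncol(m), 3))
    for (k in 1:3) img[, , k] <- matrix(pal[m + 1L, k], nrow(m), ncol(m))
    png::writePNG(img, png_path)
  }
  invisible(m)
}

#' Write a fit result as JSON
#'
#' @param fit A `dose_response_fit`, `power_law_fit` or `plateau_estimate`.
#' @param path Output path.
#' @param seed Optional master seed recorded alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  x <- unclass(fit)
  x$type <- class(fit)[1]
  if (!is.null(seed)) x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a population-doubling curve
#'
#' Cumulative population doublings against days in culture, with passage
#' boundaries marked.
#'
#' @param x A `growth_record` (one or several replicates).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.growth_record <- function(x, ...) {
  reps <- unique(x$replicate)
  graphics::plot(NA, xlim = range(x$time_days), ylim = range(x$cumulative_pd),
                 xlab = "days in culture",
                 ylab = "cumulative population doublings", ...)
  for (r in reps) {
    d <- x[x$replicate == r, ]
    graphics::lines(d$time_days, d$cumulative_pd,
                    col = grDevices::grey(0.2 + 0.6 * (match(r, reps) - 1) /
                                            max(1, length(reps) - 1)))
    bounds <- d$time_days[c(FALSE, diff(d$passage) > 0)]
    graphics::abline(v = bounds, col = "grey85", lty = 3)
  }
  invisible(x)
}

#' Plot a plateau-width sweep on log-log axes
#'
#' Plateau width against initial variant fraction, with the fitted inverse
#' power law overlaid.
#'
#' @param x A `plateau_sweep` from [run_fraction_sweep()].
#' @param fit Optional [fit_plateau_power_law()] result to overlay (fitted
#'   from `x` when omitted).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.plateau_sweep <- function(x, fit = NULL, ...) {
  graphics::plot(x$fraction, x$width, log = "xy", pch = 19,
                 xlab = "initial variant fraction",
                 ylab = "plateau width (days)", ...)
  detail <- attr(x, "detail")
  if (!is.null(detail))
    graphics::points(detail$fraction, detail$width, pch = 1, col = "grey50")
  if (is.null(fit) && nrow(x) >= 3) fit <- fit_plateau_power_law(x)
  if (!is.null(fit)) {
    f <- exp(seq(log(min(x$fraction)), log(max(x$fraction)), length.out = 50))
    graphics::lines(f, fit$a * f^(-fit$b), col = "firebrick")
  }
  invisible(x)
}
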