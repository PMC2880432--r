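#' Build or validate a senescence assay table
#'
#' A small dose-response table of the fraction of cells remaining
#' SA-beta-gal negative (i.e. non-senescent) after a single acute dose,
#' normalized to the unirradiated population.
#'
#' @param dose_gy Doses in Gy (>= 0).
#' @param sa_bgal_negative_fraction Non-senescent fraction at each dose.
#'   Normalized values may slightly exceed 1 through assay noise.
#' @param cell_class `"normal"` or `"variant"`.
#' @param normalized Whether fractions are already normalized to the
#'   unirradiated control; if `FALSE` the table must contain dose 0 and is
#'   normalized by the mean control fraction.
#' @return A data frame of class `senescence_assay`.
#' @export
senescence_assay <- function(dose_gy, sa_bgal_negative_fraction,
                             cell_class = "normal", normalized = TRUE) {
  stopifnot(length(dose_gy) == length(sa_bgal_negative_fraction))
  if (any(dose_gy < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(sa_bgal_negative_fraction < 0))
    stop("fractions must be >= 0", call. = FALSE)
  cell_class <- match.arg(cell_class, .cls_chr)
  if (!normalized) {
    if (!any(dose_gy == 0))
      stop("unnormalized assay must contain dose 0", call. = FALSE)
    ctrl <- mean(sa_bgal_negative_fraction[dose_gy == 0])
    if (ctrl <= 0) stop("control fraction must be positive", call. = FALSE)
    sa_bgal_negative_fraction <- sa_bgal_negative_fraction / ctrl
  }
  out <- data.frame(cell_class = cell_class, dose_gy = dose_gy,
                    sa_bgal_negative_fraction = sa_bgal_negative_fraction)
  class(out) <- c("senescence_assay", "data.frame")
  out
}

#' Read a senescence assay CSV
#'
#' Expects columns `cell_class`, `dose_gy`, `sa_bgal_negative_fraction`.
#'
#' @param path CSV file path.
#' @param normalized Passed to [senescence_assay()].
#' @return A `senescence_assay` (possibly covering both classes).
#' @export
read_assay_csv <- function(path, normalized = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_class", "dose_gy", "sa_bgal_negative_fraction")
  if (!all(need %in% names(d)))
    stop("assay CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  parts <- lapply(split(d, d$cell_class), function(p) {
    senescence_assay(p$dose_gy, p$sa_bgal_negative_fraction,
                     p$cell_class[1], normalized = normalized)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("senescence_assay", "data.frame")
  out
}

#' Fit the exponential senescence dose-response
#'
#' Fits the single-parameter survival-of-proliferation model
#' \eqn{y = e^{-\alpha D}} to normalized SA-beta-gal(-) fractions by
#' nonlinear least squares on the natural scale (log-linearization would
#' overweight fractions near zero). A negative unconstrained optimum is
#' clipped to 0 with a warning. R^2 is computed on the natural scale.
#'
#' @param assay A [senescence_assay()] for a single cell class.
#' @return An object of class `dose_response_fit` with elements `alpha`
#'   (per Gy), `r_squared`, `cell_class` and `n`.
#' @export
fit_alpha <- function(assay) {
  stopifnot(inherits(assay, "senescence_assay"))
  if (length(unique(assay$cell_class)) != 1)
    stop("fit one cell class at a time", call. = FALSE)
  D <- assay$dose_gy
  y <- assay$sa_bgal_negative_fraction
  if (length(unique(D)) < 2)
    stop("need at least 2 distinct doses", call. = FALSE)
  if (all(D == 0)) stop("all doses are zero; alpha is unidentifiable",
                        call. = FALSE)
  sse <- function(a) sum((y - exp(-a * D))^2)
  # start from the through-origin log-linear estimate
  pos <- D > 0 & y > 0
  a0 <- if (any(pos)) -sum(D[pos] * log(y[pos])) / sum(D[pos]^2) else 0
  fit <- stats::nlminb(a0, sse)
  alpha <- fit$par
  if (alpha < 0) {
    if (alpha < -1e-8)
      warning("best-fit alpha was negative; clipped to 0", call. = FALSE)
    alpha <- 0
  }
  res <- sse(alpha)
  tot <- sum((y - mean(y))^2)
  r2 <- if (tot > 0) 1 - res / tot else if (res < 1e-12) 1 else NA_real_
  structure(list(alpha = alpha, r_squared = r2,
                 cell_class = assay$cell_class[1], n = length(D)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> %s: alpha = %.4f /Gy (R^2 = %.4f, n = %d)\n",
    x$cell_class, x$alpha, x$r_squared, x$n))
  invisible(x)
}

#' Expected senescent fraction induced by a dose
#'
#' The complement of the exponential survival curve: `1 - exp(-alpha * D)`.
#'
#' @param fit A `dose_response_fit`, or a bare numeric alpha (per Gy).
#' @param dose Dose(s) in Gy, >= 0.
#' @return Induced senescent fraction(s) in `[0, 1)`.
#' @export
induced_senescent_fraction <- function(fit, dose) {
  alpha <- if (inherits(fit, "dose_response_fit")) fit$alpha else fit
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  1 - exp(-alpha * dose)
}

#' Define a radiation exposure event
#'
#' @param dose Dose magnitude; interpreted in `dose_unit`.
#' @param alpha_normal,alpha_variant Per-class dose-response coefficients
#'   (per Gy); either bare numerics or `dose_response_fit` objects.
#' @param time_hours Simulation time at which the exposure occurs.
#' @param dose_unit `"Gy"` (default) or `"cGy"`.
#' @return An object of class `radiation_event` (dose stored in Gy).
#' @export
radiation_event <- function(dose, alpha_normal, alpha_variant,
                            time_hours = 0, dose_unit = c("Gy", "cGy")) {
  dose_unit <- match.arg(dose_unit)
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (dose_unit == "cGy") dose <- dose / 100
  pick <- function(a) if (inherits(a, "dose_response_fit")) a$alpha else a
  structure(list(dose_gy = dose, time_hours = time_hours,
                 alpha_normal = pick(alpha_normal),
                 alpha_variant = pick(alpha_variant)),
            class = "radiation_event")
}

#' Apply radiation-induced senescence to a culture
#'
#' Each proliferative agent converts permanently to the senescent state with
#' class-specific probability `1 - exp(-alpha_class * D)`, independently.
#' Already-senescent agents, footprints, and counts are untouched.
#'
#' @param state A `sim_state`.
#' @param event A [radiation_event()].
#' @return The updated `sim_state`.
#' @export
irradiate <- function(state, event) {
  stopifnot(inherits(state, "sim_state"), inherits(event, "radiation_event"))
  a <- state$agents
  if (nrow(a) == 0 || event$dose_gy == 0) return(state)
  missing_fit <- (any(a$class == "normal") && is.null(event$alpha_normal)) ||
    (any(a$class == "variant") && is.null(event$alpha_variant))
  if (missing_fit)
    stop("radiation event lacks a dose-response fit for a present class",
         call. = FALSE)
  p <- ifelse(a$class == "normal",
              induced_senescent_fraction(event$alpha_normal, event$dose_gy),
              induced_senescent_fraction(event$alpha_variant, event$dose_gy))
  hit <- a$state == "proliferative" & stats::runif(nrow(a)) < p
  state$agents$state[hit] <- "senescent"
  state
}

#' Pre-existing-senescence-corrected induction index
#'
#' Quantifies radiation-induced senescence corrected for cells already
#' senescent before exposure: `(Ps(D) - Ps(0)) / (1 - Ps(0))`, where `Ps` is
#' the senescent (SA-beta-gal positive) fraction before (`ps0`) and after
#' (`psd`) a dose. May be negative if `psd < ps0`; it is reported, not
#' clipped.
#'
#' @param ps0 Pre-exposure senescent fraction, in `[0, 1)`.
#' @param psd Post-exposure senescent fraction, in `[0, 1]`.
#' @return The induction index.
#' @export
senescence_induction_index <- function(ps0, psd) {
  if (any(ps0 < 0) || any(ps0 >= 1))
    stop("ps0 must be in [0, 1)", call. = FALSE)
  if (any(psd < 0) || any(psd > 1))
    stop("psd must be in [0, 1]", call. = FALSE)
  (psd - ps0) / (1 - ps0)
}
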