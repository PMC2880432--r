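#' Generate synthetic fixtures with known ground truth
#'
#' Pure, seeded generators used by the test-suite and available for
#' benchmarking the analysis layer against planted truths:
#' \describe{
#'   \item{`"dose_response"`}{A senescence assay drawn from
#'     `y = exp(-alpha * D)` with multiplicative lognormal noise of log-scale
#'     SD `sigma`. Noiseless data are recovered exactly by [fit_alpha()].}
#'   \item{`"growth_curve"`}{A piecewise-linear cumulative-doubling curve:
#'     exponential phase at `baseline_rate`, a planted plateau of
#'     `plateau_width` days at `plateau_rate`, then resumed exponential
#'     growth; optional additive Gaussian noise on PD. [detect_plateau()]
#'     recovers the planted width.}
#'   \item{`"lattice_state"`}{A `sim_state` with `n_agents` random
#'     non-overlapping blobs of `area` pixels, for engine tests with
#'     arithmetic occupancy oracles.}
#' }
#'
#' @param type Generator name.
#' @param ... Generator parameters, see Details above. Common defaults:
#'   dose_response: `alpha = 0.4`, `doses = c(0, 1, 2, 4, 6)`, `sigma = 0`,
#'   `cell_class = "normal"`; growth_curve: `baseline_rate = 0.9` PD/day,
#'   `plateau_start_day = 8`, `plateau_width = 20`, `plateau_rate = 0.02`,
#'   `total_days = 45`, `step_days = 1/24`, `sigma = 0`; lattice_state:
#'   `n_agents = 100`, `area = 21`, `width = 400`, `height = 400`,
#'   `variant_fraction = 0`.
#' @param seed RNG seed; the generator is a pure function of its arguments
#'   and the seed.
#' @return The fixture object (see Details).
#' @export
generate_fixture <- function(type = c("dose_response", "growth_curve",
                                      "lattice_state"),
                             ..., seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  args <- list(...)
  switch(type,
         dose_response = do.call(.fixture_dose_response, args),
         growth_curve = do.call(.fixture_growth_curve, args),
         lattice_state = do.call(.fixture_lattice_state, args))
}

.fixture_dose_response <- function(alpha = 0.4, doses = c(0, 1, 2, 4, 6),
                                   sigma = 0, cell_class = "normal") {
  y <- exp(-alpha * doses)
  if (sigma > 0) y <- y * exp(stats::rnorm(length(doses), 0, sigma))
  senescence_assay(doses, y, cell_class = cell_class, normalized = TRUE)
}

.fixture_growth_curve <- function(baseline_rate = 0.9, plateau_start_day = 8,
                                  plateau_width = 20, plateau_rate = 0.02,
                                  total_days = 45, step_days = 1 / 24,
                                  sigma = 0) {
  t <- seq(0, total_days, by = step_days)
  t1 <- plateau_start_day
  t2 <- plateau_start_day + plateau_width
  pd <- ifelse(t < t1, baseline_rate * t,
        ifelse(t < t2, baseline_rate * t1 + plateau_rate * (t - t1),
               baseline_rate * t1 + plateau_rate * plateau_width +
                 baseline_rate * (t - t2)))
  if (sigma > 0) pd <- pd + stats::rnorm(length(t), 0, sigma)
  # passage bookkeeping: the pre-plateau segment is the first passage
  passage <- 1L + findInterval(t, c(t1, t2))
  out <- data.frame(replicate = 1L, passage = passage, time_days = t,
                    cumulative_pd = pd)
  class(out) <- c("growth_record", "data.frame")
  attr(out, "truth") <- list(baseline_rate = baseline_rate,
                             plateau_start_day = plateau_start_day,
                             plateau_width = plateau_width,
                             plateau_rate = plateau_rate)
  out
}

.fixture_lattice_state <- function(n_agents = 100, area = 21, width = 400,
                                   height = 400, variant_fraction = 0) {
  params <- dynamics_params(max_area = area, min_area = min(6, area))
  seed_agents(create_grid(width, height),
              seeding_spec(n_agents, variant_fraction), params)
}
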