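#' Bundled experiment presets
#'
#' Named configurations reproducing the package's reference simulation
#' scenarios:
#' \describe{
#'   \item{validation}{Co-culture validation: normal agents limited to 3
#'     divisions (they cease proliferating by day 4), variant agents
#'     unbounded, low seeding density so space stays ample, 7-day horizon,
#'     no subculture.}
#'   \item{serial}{Standard serial passage: 1,200 agents at 0.25%
#'     variant on the 400 x 400 grid, division limits 7 (normal) / 40
#'     (variant), replate at 80% saturation, 5 replicates.}
#'   \item{irradiated}{The serial preset plus a 2 Gy exposure at plating
#'     of the first passage, with per-class dose-response coefficients
#'     alpha_normal = 0.39 /Gy and alpha_variant = 0.022 /Gy (chosen so that
#'     2 Gy senesces over 40% of normal but under 5% of variant
#'     proliferative agents, and 6 Gy senesces over 90% of normal cells).}
#' }
#' The shorthand aliases `fig5b`, `fig6a` and `fig7` name the same three
#' presets and are accepted anywhere a preset name is.
#'
#' @param name Preset name.
#' @return An object of class `experiment_config`: a list with elements
#'   `name`, `dynamics`, `passaging`, `seeding`, `grid` (width, height,
#'   pixel_area) and `radiation` (or `NULL`).
#' @export
preset_config <- function(name = c("serial", "validation", "irradiated",
                                   "fig6a", "fig5b", "fig7")) {
  name <- match.arg(name)
  name <- switch(name, fig6a = "serial", fig5b = "validation",
                 fig7 = "irradiated", name)
  grid <- list(width = 400, height = 400, pixel_area = 175 / 21)
  cfg <- switch(
    name,
    validation = list(
      dynamics = dynamics_params(division_limit_normal = 3,
                                 division_limit_variant = NA),
      passaging = passage_config(trigger_saturation = 1, max_passages = 1,
                                 max_sim_days = 7, max_passage_days = 7,
                                 replicates = 4),
      seeding = seeding_spec(n_agents = 300, variant_fraction = 0.5),
      radiation = NULL),
    serial = list(
      dynamics = dynamics_params(division_limit_normal = 7,
                                 division_limit_variant = 40),
      passaging = passage_config(),
      seeding = seeding_spec(n_agents = 1200, variant_fraction = 0.0025),
      radiation = NULL),
    irradiated = list(
      dynamics = dynamics_params(division_limit_normal = 7,
                                 division_limit_variant = 40),
      passaging = passage_config(),
      seeding = seeding_spec(n_agents = 1200, variant_fraction = 0.0025),
      radiation = radiation_event(dose = 2, alpha_normal = 0.39,
                                  alpha_variant = 0.022, time_hours = 0)))
  structure(c(list(name = name, grid = grid), cfg),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> '%s'\n", x$name))
  cat(sprintf("  grid %d x %d px, seed %d agents (%.2f%% variant)\n",
              x$grid$width, x$grid$height, x$seeding$n_agents,
              100 * x$seeding$variant_fraction))
  cat(sprintf("  limits %s/%s divisions, replate at %.0f%% saturation\n",
              format(x$dynamics$division_limit_normal),
              format(x$dynamics$division_limit_variant),
              100 * x$passaging$trigger_saturation))
  if (!is.null(x$radiation))
    cat(sprintf("  radiation: %g Gy at t = %g h (alpha %g / %g per Gy)\n",
                x$radiation$dose_gy, x$radiation$time_hours,
                x$radiation$alpha_normal, x$radiation$alpha_variant))
  invisible(x)
}

.take_fields <- function(given, allowed, where) {
  if (is.null(given)) return(list())
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop(sprintf("unknown field '%s' in config section '%s'", bad[1], where),
         call. = FALSE)
  given
}

#' Load an experiment configuration from a YAML (or JSON) file
#'
#' The file may name a `preset` to start from; any of the sections
#' `dynamics`, `passaging`, `seeding`, `grid` and `radiation` then override
#' individual fields. An empty file yields the default serial-passage
#' configuration. Unknown fields raise an error naming the field.
#'
#' @param path Path to a YAML file (JSON is valid YAML).
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("preset", "dynamics", "passaging", "seeding", "grid",
             "radiation", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("unknown config section '%s'", bad[1]), call. = FALSE)
  cfg <- preset_config(if (is.null(raw$preset)) "serial" else raw$preset)

  dyn <- .take_fields(raw$dynamics, names(formals(dynamics_params)),
                      "dynamics")
  cfg$dynamics <- do.call(dynamics_params,
                          utils::modifyList(unclass(cfg$dynamics), dyn))
  pas <- .take_fields(raw$passaging, names(formals(passage_config)),
                      "passaging")
  cfg$passaging <- do.call(passage_config,
                           utils::modifyList(unclass(cfg$passaging), pas))
  sd_allowed <- c("n_agents", "variant_fraction", "exact")
  sds <- .take_fields(raw$seeding, sd_allowed, "seeding")
  cfg$seeding <- do.call(seeding_spec,
                         utils::modifyList(unclass(cfg$seeding)[sd_allowed],
                                           sds))
  grd <- .take_fields(raw$grid, c("width", "height", "pixel_area"), "grid")
  cfg$grid <- utils::modifyList(cfg$grid, grd)
  if (!is.null(raw$radiation)) {
    rad <- .take_fields(raw$radiation,
                        c("dose", "dose_unit", "time_hours",
                          "alpha_normal", "alpha_variant"), "radiation")
    base <- if (is.null(cfg$radiation)) {
      list(dose = 0, alpha_normal = 0, alpha_variant = 0, time_hours = 0)
    } else {
      list(dose = cfg$radiation$dose_gy,
           alpha_normal = cfg$radiation$alpha_normal,
           alpha_variant = cfg$radiation$alpha_variant,
           time_hours = cfg$radiation$time_hours)
    }
    cfg$radiation <- do.call(radiation_event, utils::modifyList(base, rad))
  }
  if (!is.null(raw$seed)) cfg$seed <- raw$seed
  cfg
}

#' Run an experiment configuration
#'
#' Convenience wrapper running [run_replicates()] from an
#' `experiment_config`.
#'
#' @param config An `experiment_config` from [preset_config()] or
#'   [load_config()].
#' @param n Number of replicates (default from the config).
#' @param base_seed Master seed.
#' @return A `replicate_set`.
#' @export
run_experiment <- function(config, n = config$passaging$replicates,
                           base_seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  run_replicates(config$dynamics, config$passaging, config$seeding,
                 create_grid(config$grid$width, config$grid$height,
                             config$grid$pixel_area),
                 radiation = config$radiation, n = n, base_seed = base_seed)
}
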