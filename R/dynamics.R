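#' Dynamics parameters
#'
#' Defaults follow the calibrated culture model: a 26-hour cell cycle for both
#' classes, footprints between 21 pixels (175 um^2, uncrowded) and 6 pixels
#' (50 um^2, fully compressed), and division limits of 7 for normal HMEC and
#' 40 for variant agents in the serial-passage scenario.
#'
#' @param cycle_hours Cell-cycle duration in hours (both classes).
#' @param max_area,min_area Footprint bounds in pixels.
#' @param division_limit_normal,division_limit_variant Maximum divisions per
#'   class; `NA` or `Inf` means unbounded.
#' @param dt Time step in hours.
#' @param search_radius Free-space search radius (pixels) for the division
#'   rule.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(cycle_hours = 26, max_area = 21, min_area = 6,
                            division_limit_normal = 7,
                            division_limit_variant = 40,
                            dt = 1, search_radius = 5) {
  if (min_area <= 0 || min_area > max_area)
    stop("need 0 < min_area <= max_area", call. = FALSE)
  if (cycle_hours <= 0 || dt <= 0 || dt > cycle_hours)
    stop("need 0 < dt <= cycle_hours", call. = FALSE)
  if (search_radius < 1) stop("search_radius must be >= 1", call. = FALSE)
  structure(list(cycle_hours = cycle_hours,
                 max_area = as.integer(max_area),
                 min_area = as.integer(min_area),
                 division_limit_normal = division_limit_normal,
                 division_limit_variant = division_limit_variant,
                 dt = dt, search_radius = as.integer(search_radius)),
            class = "dynamics_params")
}

.cpp_agent_args <- function(state) {
  a <- state$agents
  list(grid = state$grid$label,
       cls = match(a$class, .cls_chr) - 1L,
       st = match(a$state, .st_chr) - 1L,
       divs = as.integer(a$divisions),
       limit = .limit_to_int(a$limit),
       phase = as.numeric(a$phase))
}

.apply_cpp_state <- function(state, res) {
  state$grid$label <- res$grid
  state$agents <- .agents_df(res)
  state
}

# Run the compiled within-passage loop for up to max_hours; returns the
# updated state plus the per-step series and the stop reason.
.run_engine <- function(state, params, trigger_frac, max_hours) {
  z <- .cpp_agent_args(state)
  res <- cpp_run_passage(z$grid, z$cls, z$st, z$divs, z$limit, z$phase,
                         params$cycle_hours, params$dt, params$min_area,
                         params$max_area, params$search_radius,
                         trigger_frac, max_hours, state$clock)
  state <- .apply_cpp_state(state, res)
  state$clock <- state$clock + res$elapsed_hours
  list(state = state, series = res$series, reason = res$reason)
}

#' Advance a culture by a fixed amount of time
#'
#' Steps the dynamics without any passaging trigger: proliferative agents
#' advance their cycle phase; agents whose cycle completes attempt division
#' (open division at full size, compressed division when crowded, permanent
#' senescent conversion at the division limit, or blocking when even two
#' minimal footprints do not fit). Update order is re-randomized every step.
#'
#' @param state A `sim_state`.
#' @param hours Hours to simulate.
#' @param params Dynamics parameters; defaults to those stored in the state.
#' @return The updated `sim_state`; the per-step count series is attached as
#'   `attr(, "series")`.
#' @export
step_culture <- function(state, hours, params = state$params) {
  stopifnot(inherits(state, "sim_state"), hours >= 0)
  out <- .run_engine(state, params, trigger_frac = 2, max_hours = hours)
  st <- out$state
  attr(st, "series") <- out$series
  attr(st, "reason") <- out$reason
  st
}

#' Attempt a single division
#'
#' Applies the division rules to one proliferative agent as if its cycle had
#' just completed. Outcomes: `"divided"` (daughter placed at full size),
#' `"compressed_divided"` (both daughters compressed to fit the local space),
#' `"blocked"` (held until space appears), or `"converted_senescent"`
#' (division limit reached; permanent).
#'
#' @param state A `sim_state`.
#' @param id Agent id; must be proliferative.
#' @param params Dynamics parameters; defaults to those stored in the state.
#' @return A list with the updated `state` and the `outcome` string.
#' @export
attempt_division <- function(state, id, params = state$params) {
  stopifnot(inherits(state, "sim_state"))
  if (state$agents$state[id] != "proliferative")
    stop("agent is not proliferative", call. = FALSE)
  z <- .cpp_agent_args(state)
  res <- cpp_attempt_division(z$grid, z$cls, z$st, z$divs, z$limit, z$phase,
                              as.integer(id), params$cycle_hours,
                              params$min_area, params$max_area,
                              params$search_radius)
  outcome <- c("divided", "compressed_divided", "blocked",
               "converted_senescent")[res$outcome + 1L]
  list(state = .apply_cpp_state(state, res), outcome = outcome)
}

#' Snapshot one growth-record row from a state
#'
#' Cumulative population doublings follow the subculture bookkeeping
#' PD = log(A/B)/log(2) with A the current cell count and B the count plated
#' into the current passage, offset by the doublings accumulated in earlier
#' passages.
#'
#' @param state A `sim_state`.
#' @param plated Count plated into the current passage.
#' @param pd_offset Cumulative doublings carried in from earlier passages.
#' @param replicate Replicate identifier stored in the row.
#' @return A one-row data frame in growth-record format.
#' @export
record_growth <- function(state, plated = nrow(state$agents), pd_offset = 0,
                          replicate = 1L) {
  a <- state$agents
  total <- nrow(a)
  data.frame(
    replicate = replicate,
    passage = state$passage,
    time_days = state$clock / 24,
    n_normal_proliferative = sum(a$class == "normal" & a$state == "proliferative"),
    n_normal_senescent = sum(a$class == "normal" & a$state == "senescent"),
    n_variant_proliferative = sum(a$class == "variant" & a$state == "proliferative"),
    n_variant_senescent = sum(a$class == "variant" & a$state == "senescent"),
    confluence = confluence(state),
    cumulative_pd = pd_offset + log2(total / plated))
}
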