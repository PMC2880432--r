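#' Serial-passaging configuration
#'
#' @param seed_count Agents replated at each subculture (default 1,200,
#'   about 20% of a 400 x 400 grid at maximal cell size).
#' @param trigger_saturation Confluence at which the culture is subcultured
#'   (default 0.80; about 6,000 maximal-size agents on the default grid).
#' @param max_passages Hard cap on passages.
#' @param max_sim_days Wall-clock horizon of the simulated experiment, days.
#' @param max_passage_days Force a subculture if a single passage exceeds
#'   this duration without reaching the trigger (routine subculture happens
#'   on a schedule even for near-static cultures).
#' @param max_total_pd Stop once cumulative population doublings reach this
#'   value; bounds the time spent simulating resumed exponential growth after
#'   the plateau of interest.
#' @param replicates Default replicate count for [run_replicates()].
#' @return An object of class `passage_config`.
#' @export
passage_config <- function(seed_count = 1200, trigger_saturation = 0.80,
                           max_passages = 60, max_sim_days = 120,
                           max_passage_days = 60, max_total_pd = 24,
                           replicates = 5) {
  if (trigger_saturation <= 0 || trigger_saturation > 1)
    stop("trigger_saturation must be in (0, 1]", call. = FALSE)
  if (seed_count < 0) stop("seed_count must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(seed_count = as.integer(seed_count),
                 trigger_saturation = trigger_saturation,
                 max_passages = as.integer(max_passages),
                 max_sim_days = max_sim_days,
                 max_passage_days = max_passage_days,
                 max_total_pd = max_total_pd,
                 replicates = as.integer(replicates)),
            class = "passage_config")
}

#' Is the culture due for subculture?
#'
#' @param state A `sim_state`.
#' @param config A [passage_config()].
#' @return `TRUE` iff confluence has reached the trigger saturation.
#' @export
should_passage <- function(state, config = passage_config()) {
  confluence(state) >= config$trigger_saturation
}

#' Subculture a population
#'
#' Implements the detachment/reattachment rule: senescent agents are
#' discarded (they do not reattach), proliferative agents are sampled
#' uniformly without replacement down to `seed_count` (all retained if
#' fewer), and survivors are re-dispersed randomly at maximal footprint size
#' on a fresh grid with their division counts and classes preserved. Cycle
#' phases are re-randomized to reflect dissociation and replating.
#'
#' @param state A `sim_state`.
#' @param config A [passage_config()].
#' @return A new `sim_state` at the incremented passage index. If no
#'   proliferative agent survives, an empty terminal state is returned with
#'   `attr(, "terminal") = TRUE`.
#' @export
passage <- function(state, config = passage_config()) {
  stopifnot(inherits(state, "sim_state"))
  params <- state$params
  a <- state$agents
  prolif <- which(a$state == "proliferative")
  fresh <- create_grid(ncol(state$grid$label), nrow(state$grid$label),
                       state$grid$pixel_area)
  if (length(prolif) == 0) {
    empty <- seed_agents(fresh, seeding_spec(0, 0), params)
    empty$clock <- state$clock
    empty$passage <- state$passage + 1L
    attr(empty, "terminal") <- TRUE
    return(empty)
  }
  keep <- if (length(prolif) > config$seed_count) {
    sort(sample(prolif, config$seed_count))
  } else prolif
  n <- length(keep)
  cls <- match(a$class[keep], .cls_chr) - 1L
  res <- cpp_seed_blobs(fresh$label, cls, integer(n),
                        as.integer(a$divisions[keep]),
                        .limit_to_int(a$limit[keep]),
                        stats::runif(n, 0, params$cycle_hours),
                        params$max_area, 2000L)
  if (res$placed < n)
    stop("replating failed: not enough space on the fresh grid", call. = FALSE)
  fresh$label <- res$grid
  out <- .new_state(fresh, .agents_df(res), params,
                    clock = state$clock, passage = state$passage + 1L)
  attr(out, "terminal") <- FALSE
  out
}

.series_to_rows <- function(series, passage, plated, pd_offset, replicate,
                            n_pixels) {
  if (nrow(series) == 0) return(NULL)
  total <- series$n_normal_proliferative + series$n_normal_senescent +
    series$n_variant_proliferative + series$n_variant_senescent
  data.frame(
    replicate = replicate,
    passage = passage,
    time_days = series$time_hours / 24,
    n_normal_proliferative = series$n_normal_proliferative,
    n_normal_senescent = series$n_normal_senescent,
    n_variant_proliferative = series$n_variant_proliferative,
    n_variant_senescent = series$n_variant_senescent,
    confluence = series$occupied_pixels / n_pixels,
    cumulative_pd = pd_offset + log2(total / plated))
}

#' Run a full serial-passage culture
#'
#' Seeds a culture, advances the lattice dynamics, subcultures whenever the
#' grid reaches the trigger saturation (or a passage stalls or exceeds its
#' maximum duration), and iterates until a stopping condition: the passage or
#' day caps, the cumulative-doubling cap, or loss of all proliferative agents.
#' An optional radiation event converts proliferative agents to senescence at
#' its scheduled time with class-specific probability `1 - exp(-alpha * D)`.
#'
#' @param dynamics A [dynamics_params()].
#' @param passaging A [passage_config()].
#' @param seeding A [seeding_spec()].
#' @param grid Grid template (default 400 x 400 at the 175/21 um^2 scale).
#' @param radiation Optional [radiation_event()].
#' @param seed Optional RNG seed (`set.seed`) making the trajectory
#'   reproducible.
#' @param replicate Replicate id recorded in the output rows.
#' @return A `growth_record` data frame with one row per simulated hour
#'   (plus a row at each plating): replicate, passage, time_days, counts by
#'   class and state, confluence, and cumulative population doublings.
#'   Attributes: `passage_log` (one row per passage with harvest counts and
#'   the stop reason) and `terminal` (`TRUE` if the culture ran out of
#'   proliferative agents).
#' @export
run_serial_culture <- function(dynamics = dynamics_params(),
                               passaging = passage_config(),
                               seeding = seeding_spec(),
                               grid = create_grid(),
                               radiation = NULL, seed = NULL,
                               replicate = 1L) {
  if (!is.null(seed)) set.seed(seed)
  state <- seed_agents(grid, seeding, dynamics)
  n_pixels <- length(grid$label)
  rad_pending <- !is.null(radiation)
  if (rad_pending) stopifnot(inherits(radiation, "radiation_event"))

  plated <- nrow(state$agents)
  pd_offset <- 0
  rows <- list(record_growth(state, plated, pd_offset, replicate))
  log_rows <- list()
  terminal <- FALSE
  global_end <- passaging$max_sim_days * 24

  repeat {
    if (rad_pending && radiation$time_hours <= state$clock + 1e-9) {
      state <- irradiate(state, radiation)
      rad_pending <- FALSE
    }
    run_to <- min(state$clock + passaging$max_passage_days * 24, global_end)
    hit_rad <- FALSE
    if (rad_pending && radiation$time_hours < run_to) {
      run_to <- radiation$time_hours
      hit_rad <- TRUE
    }
    out <- .run_engine(state, dynamics, passaging$trigger_saturation,
                       run_to - state$clock)
    state <- out$state
    rows[[length(rows) + 1L]] <-
      .series_to_rows(out$series, state$passage, plated, pd_offset,
                      replicate, n_pixels)
    if (out$reason == "timeout" && hit_rad) next
    if (out$reason == "exhausted") {
      terminal <- TRUE
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        passage = state$passage, end_day = state$clock / 24,
        harvest = nrow(state$agents), plated = plated,
        reason = out$reason,
        cumulative_pd = pd_offset + log2(nrow(state$agents) / plated))
      break
    }
    harvest <- nrow(state$agents)
    cur_pd <- pd_offset + log2(harvest / plated)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      passage = state$passage, end_day = state$clock / 24,
      harvest = harvest, plated = plated, reason = out$reason,
      cumulative_pd = cur_pd)
    if (out$reason == "timeout" && state$clock >= global_end - 1e-9) break
    if (cur_pd >= passaging$max_total_pd) break
    if (state$passage >= passaging$max_passages) break
    nxt <- passage(state, passaging)
    if (isTRUE(attr(nxt, "terminal"))) {
      terminal <- TRUE
      break
    }
    pd_offset <- cur_pd
    plated <- nrow(nxt$agents)
    state <- nxt
    rows[[length(rows) + 1L]] <- record_growth(state, plated, pd_offset,
                                               replicate)
  }

  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  class(rec) <- c("growth_record", "data.frame")
  attr(rec, "passage_log") <- do.call(rbind, log_rows)
  attr(rec, "terminal") <- terminal
  attr(rec, "seed") <- seed
  rec
}

#' Run independently seeded replicate simulations
#'
#' @param dynamics,passaging,seeding,grid,radiation As in
#'   [run_serial_culture()].
#' @param n Number of replicates.
#' @param base_seed Replicate `i` uses seed `base_seed + i - 1`.
#' @return A list of class `replicate_set`: `records` (list of
#'   `growth_record`s) and `summary`, the per-timepoint dispersion from
#'   [relative_standard_error()].
#' @export
run_replicates <- function(dynamics = dynamics_params(),
                           passaging = passage_config(),
                           seeding = seeding_spec(),
                           grid = create_grid(),
                           radiation = NULL,
                           n = passaging$replicates, base_seed = 1) {
  stopifnot(n >= 1)
  records <- lapply(seq_len(n), function(i) {
    run_serial_culture(dynamics, passaging, seeding, grid, radiation,
                       seed = base_seed + i - 1, replicate = i)
  })
  structure(list(records = records,
                 summary = relative_standard_error(records)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d replicates\n", length(x$records)))
  if (is.na(x$summary$max_rse)) {
    cat("max RSE of cumulative PD: not applicable (single replicate)\n")
  } else {
    cat(sprintf("max RSE of cumulative PD: %.3f%%\n", 100 * x$summary$max_rse))
  }
  invisible(x)
}

#' @export
print.growth_record <- function(x, ...) {
  cat(sprintf(
    "<growth_record> %d rows, %d passage(s), %.1f days, final PD %.2f%s\n",
    nrow(x), length(unique(x$passage)), max(x$time_days),
    x$cumulative_pd[nrow(x)],
    if (isTRUE(attr(x, "terminal"))) " (terminal)" else ""))
  invisible(x)
}
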