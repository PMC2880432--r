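#' Create an empty culture grid
#'
#' The grid is a lattice of pixels with exclusive occupancy: each pixel is
#' owned by at most one agent. The default pixel area follows the microscopy
#' calibration 21 pixels = 175 um^2, so a maximal 21-pixel cell covers
#' 175 um^2 and a minimal 6-pixel cell 50 um^2.
#'
#' @param width,height Grid dimensions in pixels.
#' @param pixel_area Physical area of one pixel in um^2.
#' @return An object of class `hmec_grid`: a list with the integer label
#'   matrix `label` (0 = free, otherwise the owning agent id) and
#'   `pixel_area`.
#' @examples
#' g <- create_grid(400, 400)
#' confluence(g)
#' @export
create_grid <- function(width = 400, height = 400, pixel_area = 175 / 21) {
  if (!is.numeric(width) || !is.numeric(height) || length(width) != 1 ||
      length(height) != 1 || width < 1 || height < 1)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.numeric(pixel_area) || length(pixel_area) != 1 || pixel_area <= 0)
    stop("pixel_area must be a positive scalar", call. = FALSE)
  structure(
    list(label = matrix(0L, nrow = as.integer(height), ncol = as.integer(width)),
         pixel_area = pixel_area),
    class = "hmec_grid")
}

#' @export
print.hmec_grid <- function(x, ...) {
  cat(sprintf("<hmec_grid> %d x %d pixels (%.3f um^2/pixel), confluence %.4f\n",
              ncol(x$label), nrow(x$label), x$pixel_area, confluence(x)))
  invisible(x)
}

#' Seeding specification
#'
#' @param n_agents Number of agents to plate.
#' @param variant_fraction Fraction of plated agents that are variant (vHMEC),
#'   in `[0, 1]`.
#' @param exact If `TRUE` (default) the variant count is the deterministic
#'   `round(n_agents * variant_fraction)` with randomized identity and
#'   placement; if `FALSE` each agent is variant with independent probability
#'   `variant_fraction`.
#' @return An object of class `seeding_spec`.
#' @export
seeding_spec <- function(n_agents = 1200, variant_fraction = 0.0025,
                         exact = TRUE) {
  if (n_agents < 0) stop("n_agents must be >= 0", call. = FALSE)
  if (variant_fraction < 0 || variant_fraction > 1)
    stop("variant_fraction must be in [0, 1]", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents),
                 variant_fraction = variant_fraction, exact = isTRUE(exact)),
            class = "seeding_spec")
}

.cls_chr <- c("normal", "variant")
.st_chr <- c("proliferative", "senescent")

.limit_to_int <- function(x) {
  x <- ifelse(is.na(x) | is.infinite(x), -1L, as.integer(x))
  as.integer(x)
}
.limit_from_int <- function(x) ifelse(x < 0, NA_integer_, x)

.agents_df <- function(res) {
  n <- length(res$class)
  data.frame(
    id = seq_len(n),
    class = .cls_chr[res$class + 1L],
    state = .st_chr[res$state + 1L],
    divisions = res$divisions,
    limit = .limit_from_int(res$limit),
    phase = res$phase,
    area = res$area,
    cx = res$cx,
    cy = res$cy,
    stringsAsFactors = FALSE)
}

.new_state <- function(grid, agents, params, clock = 0, passage = 1L) {
  structure(list(grid = grid, agents = agents, params = params,
                 clock = clock, passage = as.integer(passage)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  tab <- table(factor(x$agents$class, .cls_chr),
               factor(x$agents$state, .st_chr))
  cat(sprintf(
    "<sim_state> passage %d, day %.2f: %d agents, confluence %.4f\n",
    x$passage, x$clock / 24, nrow(x$agents), confluence(x)))
  print(tab)
  invisible(x)
}

#' Plate agents at random non-overlapping positions
#'
#' Disperses `spec$n_agents` agents uniformly at random on the grid, each with
#' a quasi-circular footprint of `params$max_area` pixels, mimicking plating
#' of a well-dissociated cell suspension. Cell-cycle phases are initialized
#' uniformly in `[0, cycle_hours)` so the population is desynchronized.
#'
#' @param grid An empty [create_grid()] object.
#' @param spec A [seeding_spec()].
#' @param params A [dynamics_params()]; supplies the footprint area, the
#'   per-class division limits and the cycle length used for phase
#'   initialization.
#' @param max_tries Placement attempts per agent before giving up.
#' @return A `sim_state` holding the grid and the agent table.
#' @export
seed_agents <- function(grid, spec, params = dynamics_params(),
                        max_tries = 2000) {
  stopifnot(inherits(grid, "hmec_grid"), inherits(spec, "seeding_spec"),
            inherits(params, "dynamics_params"))
  if (any(grid$label != 0L))
    stop("seed_agents requires an empty grid", call. = FALSE)
  n <- spec$n_agents
  if (n == 0) {
    agents <- .agents_df(list(class = integer(0), state = integer(0),
                              divisions = integer(0), limit = integer(0),
                              phase = numeric(0), area = integer(0),
                              cx = numeric(0), cy = numeric(0)))
    return(.new_state(grid, agents, params))
  }
  if (n * params$max_area > length(grid$label))
    stop(sprintf("seeding error: %d agents at %d px exceed the %d-pixel grid",
                 n, params$max_area, length(grid$label)), call. = FALSE)
  n_variant <- if (spec$exact) {
    as.integer(round(n * spec$variant_fraction))
  } else {
    sum(stats::rbinom(n, 1, spec$variant_fraction))
  }
  cls <- integer(n)
  if (n_variant > 0) cls[sample.int(n, n_variant)] <- 1L
  limit <- ifelse(cls == 1L,
                  .limit_to_int(params$division_limit_variant),
                  .limit_to_int(params$division_limit_normal))
  phase <- stats::runif(n, 0, params$cycle_hours)
  res <- cpp_seed_blobs(grid$label, cls, integer(n), integer(n),
                        as.integer(limit), phase,
                        params$max_area, as.integer(max_tries))
  if (res$placed < n)
    stop(sprintf("seeding error: placed only %d of %d agents without overlap",
                 res$placed, n), call. = FALSE)
  grid$label <- res$grid
  .new_state(grid, .agents_df(res), params)
}

#' Fraction of the grid covered by agent footprints
#'
#' @param x An `hmec_grid` or `sim_state`.
#' @return Occupied pixels divided by total pixels, in `[0, 1]`.
#' @export
confluence <- function(x) UseMethod("confluence")

#' @export
confluence.hmec_grid <- function(x) sum(x$label != 0L) / length(x$label)

#' @export
confluence.sim_state <- function(x) confluence(x$grid)

#' Free space reachable around an agent
#'
#' Counts unoccupied pixels reachable through free space within
#' `search_radius` 8-connected steps of the agent's footprint boundary. This
#' is the space-availability query behind the division rule: a daughter can
#' only be placed in locally reachable free space.
#'
#' @param state A `sim_state`.
#' @param id Agent id.
#' @param search_radius Number of BFS layers (pixels) to explore.
#' @return Number of free pixels (integer).
#' @export
free_adjacent_area <- function(state, id,
                               search_radius = state$params$search_radius) {
  stopifnot(inherits(state, "sim_state"))
  a <- state$agents
  cpp_free_area(state$grid$label, match(a$class, .cls_chr) - 1L,
                match(a$state, .st_chr) - 1L, a$divisions,
                .limit_to_int(a$limit), a$phase,
                as.integer(id), as.integer(search_radius))
}

#' Grow or shrink an agent footprint
#'
#' Growth accretes the nearest free pixels to the footprint centroid; if
#' fewer free pixels are reachable than requested, the achieved area is
#' returned. Shrinking releases the pixels farthest from the centroid while
#' keeping the footprint 8-connected. No other agent is affected.
#'
#' @param state A `sim_state`.
#' @param id Agent id.
#' @param target_area Desired footprint size in pixels, within
#'   `[min_area, max_area]` of the state's dynamics parameters.
#' @return The updated `sim_state`, with the achieved area in
#'   `attr(, "achieved")`.
#' @export
resize_footprint <- function(state, id, target_area) {
  stopifnot(inherits(state, "sim_state"))
  p <- state$params
  if (target_area < p$min_area || target_area > p$max_area)
    stop(sprintf("target_area must be within [%d, %d]", p$min_area,
                 p$max_area), call. = FALSE)
  a <- state$agents
  res <- cpp_resize(state$grid$label, match(a$class, .cls_chr) - 1L,
                    match(a$state, .st_chr) - 1L, a$divisions,
                    .limit_to_int(a$limit), a$phase,
                    as.integer(id), as.integer(target_area))
  state$grid$label <- res$grid
  state$agents <- .agents_df(res)
  attr(state, "achieved") <- res$achieved
  state
}

#' Assemble a simulation state from a label matrix and an agent table
#'
#' Intended for constructing prescribed lattice configurations in tests and
#' fixtures. The label matrix is authoritative for footprints; per-agent
#' areas and centroids are derived from it.
#'
#' @param label Integer matrix, 0 = free, otherwise agent id (ids must be
#'   `1..n` matching `agents` rows).
#' @param agents Data frame with columns `class`, `state`, `divisions`,
#'   `limit`, `phase` (missing columns get defaults: proliferative, 0
#'   divisions, unbounded limit, phase 0).
#' @param pixel_area Physical pixel area in um^2.
#' @param params A [dynamics_params()].
#' @param clock,passage Simulation clock (hours) and passage index.
#' @return A `sim_state`.
#' @export
as_sim_state <- function(label, agents = NULL, pixel_area = 175 / 21,
                         params = dynamics_params(), clock = 0, passage = 1L) {
  label <- matrix(as.integer(label), nrow(label), ncol(label))
  ids <- sort(unique(label[label > 0L]))
  n <- if (length(ids)) max(ids) else 0L
  if (length(ids) && !identical(ids, seq_len(n)))
    stop("label ids must be contiguous 1..n", call. = FALSE)
  if (is.null(agents)) agents <- data.frame(id = seq_len(n))
  if (nrow(agents) != n)
    stop("agent table rows must match the label ids", call. = FALSE)
  if (is.null(agents$class)) agents$class <- "normal"
  if (is.null(agents$state)) agents$state <- "proliferative"
  if (is.null(agents$divisions)) agents$divisions <- 0L
  if (is.null(agents$limit)) agents$limit <- NA_integer_
  if (is.null(agents$phase)) agents$phase <- 0
  cnt <- tabulate(label[label > 0L], nbins = n)
  if (any(cnt == 0))
    stop("every agent must own at least one pixel", call. = FALSE)
  xs <- col(label); ys <- row(label)
  agents$id <- seq_len(n)
  agents$area <- cnt
  agents$cx <- as.vector(tapply(xs[label > 0L] - 1L, label[label > 0L], mean))
  agents$cy <- as.vector(tapply(ys[label > 0L] - 1L, label[label > 0L], mean))
  grid <- structure(list(label = label, pixel_area = pixel_area),
                    class = "hmec_grid")
  cols <- c("id", "class", "state", "divisions", "limit", "phase", "area",
            "cx", "cy")
  .new_state(grid, agents[, cols], params, clock, passage)
}

#' Check structural invariants of a simulation state
#'
#' Verifies exclusive occupancy bookkeeping: footprint sizes recorded in the
#' agent table must equal the brute-force per-id pixel counts of the label
#' matrix, and every agent must be placed.
#'
#' @param state A `sim_state`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_sim_state <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  lab <- state$grid$label
  n <- nrow(state$agents)
  cnt <- tabulate(lab[lab > 0L], nbins = n)
  if (any(lab < 0L)) stop("negative labels in grid", call. = FALSE)
  if (n && max(lab) > n) stop("grid references unknown agent id", call. = FALSE)
  if (!identical(as.integer(cnt), as.integer(state$agents$area)))
    stop("agent areas disagree with grid pixel counts", call. = FALSE)
  if (any(cnt == 0)) stop("agent without pixels", call. = FALSE)
  if (sum(cnt) != sum(lab != 0L))
    stop("occupancy bookkeeping mismatch", call. = FALSE)
  invisible(TRUE)
}
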