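# Builders for prescribed lattice configurations used across test files.

# A single rectangular agent footprint of w x h pixels with top-left corner
# (row0, col0) on an otherwise empty grid.
rect_state <- function(grid_rows = 30, grid_cols = 30, row0 = 10, col0 = 10,
                       w = 7, h = 3, params = dynamics_params(),
                       class = "normal", state = "proliferative",
                       divisions = 0L, limit = NA_integer_) {
  lab <- matrix(0L, grid_rows, grid_cols)
  lab[row0:(row0 + h - 1), col0:(col0 + w - 1)] <- 1L
  as_sim_state(lab, data.frame(class = class, state = state,
                               divisions = divisions, limit = limit,
                               phase = 0),
               params = params)
}

# An agent of `core` pixels completely enclosed by a senescent ring agent of
# one-pixel thickness (plus optional extra rigid padding rings).
enclosed_state <- function(core_w = 4, core_h = 3, rings = 1,
                           params = dynamics_params(),
                           core_limit = NA_integer_) {
  pad <- rings + 2
  rows <- core_h + 2 * pad
  cols <- core_w + 2 * pad
  lab <- matrix(0L, rows, cols)
  r0 <- pad + 1
  c0 <- pad + 1
  lab[r0:(r0 + core_h - 1), c0:(c0 + core_w - 1)] <- 1L
  for (k in seq_len(rings)) {
    rr <- (r0 - k):(r0 + core_h - 1 + k)
    cc <- (c0 - k):(c0 + core_w - 1 + k)
    ring <- matrix(FALSE, rows, cols)
    ring[rr, cc] <- TRUE
    ring[lab > 0L] <- FALSE
    lab[ring] <- 1L + k
  }
  n <- max(lab)
  as_sim_state(lab, data.frame(
    class = "normal",
    state = c("proliferative", rep("senescent", n - 1L)),
    divisions = 0L,
    limit = c(core_limit, rep(0L, n - 1L)),
    phase = 0), params = params)
}

# Brute-force pixel-count oracle for confluence.
confluence_oracle <- function(state) {
  sum(state$grid$label != 0L) / length(state$grid$label)
}
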