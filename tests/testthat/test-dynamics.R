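test_that("an uncrowded agent divides once per cycle", {
  set.seed(1)
  st <- seed_agents(create_grid(60, 60), seeding_spec(1, 0),
                    dynamics_params(division_limit_normal = NA))
  st$agents$phase <- 0
  st <- step_culture(st, 26)
  expect_equal(nrow(st$agents), 2)
  expect_true(all(st$agents$area == 21))
  expect_true(all(st$agents$divisions == 1))
  validate_sim_state(st)
})

test_that("a lineage with limit L saturates at 2^L senescent agents", {
  for (L in 1:3) {
    set.seed(10 + L)
    st <- seed_agents(create_grid(120, 120), seeding_spec(1, 0),
                      dynamics_params(division_limit_normal = L))
    st$agents$phase <- 0
    st <- step_culture(st, 26 * (L + 1) + 2)
    expect_equal(nrow(st$agents), 2^L)
    expect_true(all(st$agents$divisions == L))
    expect_true(all(st$agents$state == "senescent"))
  }
})

test_that("normal agents with limit 3 stop proliferating by day 4", {
  set.seed(2)
  st <- seed_agents(create_grid(200, 200), seeding_spec(20, 0),
                    dynamics_params(division_limit_normal = 3))
  st <- step_culture(st, 96)
  expect_equal(nrow(st$agents), 20 * 8)
  expect_true(all(st$agents$divisions == 3))
  # one more cycle converts everyone (rule: permanent senescent type)
  st <- step_culture(st, 28)
  expect_true(all(st$agents$state == "senescent"))
  expect_equal(nrow(st$agents), 160)
})

test_that("a senescent-only population never changes", {
  st <- enclosed_state(4, 3, rings = 1)
  st$agents$state[] <- "senescent"
  out <- step_culture(st, 100)
  expect_identical(out$grid$label, st$grid$label)
  expect_identical(out$agents$divisions, st$agents$divisions)
  expect_identical(out$agents$state, st$agents$state)
})

test_that("attempt_division outcomes follow the space rules", {
  params <- dynamics_params()
  # at the division limit: permanent senescent conversion
  set.seed(3)
  st <- seed_agents(create_grid(50, 50), seeding_spec(1, 0),
                    dynamics_params(division_limit_normal = 2))
  st$agents$divisions <- 2L
  out <- attempt_division(st, 1)
  expect_equal(out$outcome, "converted_senescent")
  expect_equal(out$state$agents$state[1], "senescent")
  expect_equal(nrow(out$state$agents), 1)
  # the conversion is permanent: further steps change nothing
  after <- step_culture(out$state, 60)
  expect_equal(after$agents$state[1], "senescent")

  # open space: two full-size agents
  set.seed(4)
  st <- seed_agents(create_grid(50, 50), seeding_spec(1, 0), params)
  out <- attempt_division(st, 1)
  expect_equal(out$outcome, "divided")
  expect_equal(out$state$agents$area, c(21, 21))
  expect_equal(out$state$agents$divisions, c(1, 1))
  validate_sim_state(out$state)

  # a 12-pixel agent filling its whole world divides into two 6-pixel
  # daughters within the mother's own pixels
  lab <- matrix(1L, 3, 4)
  st <- as_sim_state(lab, data.frame(class = "normal",
                                     state = "proliferative",
                                     divisions = 0L, limit = NA_integer_,
                                     phase = 0), params = params)
  out <- attempt_division(st, 1)
  expect_equal(out$outcome, "compressed_divided")
  expect_equal(sort(out$state$agents$area), c(6, 6))
  expect_equal(sum(out$state$grid$label != 0L), 12)
  validate_sim_state(out$state)

  # a minimal agent with no space anywhere is blocked
  lab <- matrix(1L, 2, 3)
  st <- as_sim_state(lab, data.frame(class = "normal",
                                     state = "proliferative",
                                     divisions = 0L, limit = NA_integer_,
                                     phase = 0), params = params)
  out <- attempt_division(st, 1)
  expect_equal(out$outcome, "blocked")
  expect_equal(nrow(out$state$agents), 1)
})

test_that("crowded divisions may compress neighbors but respect area bounds", {
  set.seed(6)
  params <- dynamics_params(division_limit_normal = NA)
  st <- seed_agents(create_grid(40, 40), seeding_spec(20, 0), params)
  st <- step_culture(st, 26 * 8)  # grow to jamming
  expect_gt(confluence(st), 0.9)
  expect_true(all(st$agents$area >= params$min_area))
  expect_true(all(st$agents$area <= params$max_area))
  validate_sim_state(st)
})

test_that("stepping conserves agents and senescence is monotone", {
  set.seed(7)
  st <- seed_agents(create_grid(100, 100), seeding_spec(40, 0.5),
                    dynamics_params(division_limit_normal = 2,
                                    division_limit_variant = 4))
  n_prev <- nrow(st$agents)
  sen_prev <- character(0)
  for (k in 1:14) {
    st <- step_culture(st, 12)
    a <- st$agents
    expect_gte(nrow(a), n_prev)           # no agent disappears
    sen_now <- a$id[a$state == "senescent"]
    expect_true(all(sen_prev %in% sen_now))  # senescence never reverts
    expect_true(all(a$area >= 6 & a$area <= 21))
    expect_true(all(a$divisions <= ifelse(is.na(a$limit), Inf, a$limit)))
    n_prev <- nrow(a)
    sen_prev <- sen_now
  }
  expect_equal(confluence(st), confluence_oracle(st))
  validate_sim_state(st)
})

test_that("identical seeds give identical trajectories", {
  run <- function() {
    set.seed(123)
    st <- seed_agents(create_grid(80, 80), seeding_spec(30, 0.2),
                      dynamics_params(division_limit_normal = 3))
    st <- step_culture(st, 26 * 5)
    st
  }
  a <- run()
  b <- run()
  expect_identical(a$grid$label, b$grid$label)
  expect_identical(a$agents, b$agents)
})

test_that("record_growth implements the PD bookkeeping", {
  set.seed(8)
  st <- seed_agents(create_grid(60, 60), seeding_spec(4, 0))
  row <- record_growth(st, plated = 4)
  expect_equal(row$cumulative_pd, 0)
  expect_equal(row$n_normal_proliferative, 4)

  st$agents$phase <- 0
  st <- step_culture(st, 26)  # one synchronous doubling
  row <- record_growth(st, plated = 4)
  expect_equal(row$cumulative_pd, 1)

  row <- record_growth(st, plated = 4, pd_offset = 2.5)
  expect_equal(row$cumulative_pd, 3.5)
})
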