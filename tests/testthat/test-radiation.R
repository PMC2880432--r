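test_that("fit_alpha recovers a noiseless exponential exactly", {
  assay <- generate_fixture("dose_response", alpha = 0.4,
                            doses = c(0, 1, 2, 4, 6), sigma = 0)
  fit <- fit_alpha(assay)
  expect_equal(fit$alpha, 0.4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("fit_alpha handles flat and increasing dose responses", {
  flat <- senescence_assay(c(0, 2, 4, 6), rep(1, 4))
  fit <- fit_alpha(flat)
  expect_equal(fit$alpha, 0)

  rising <- senescence_assay(c(0, 1, 2), c(1, 1.2, 1.5))
  expect_warning(fit <- fit_alpha(rising), "clipped")
  expect_equal(fit$alpha, 0)

  expect_error(fit_alpha(senescence_assay(c(2, 2), c(0.5, 0.6))), "distinct")
  expect_error(fit_alpha(senescence_assay(c(0, 0), c(1, 1))),
               "unidentifiable|distinct")
})

test_that("alpha recovery is unbiased under multiplicative noise", {
  truth <- 0.4
  alphas <- vapply(1:100, function(s) {
    assay <- generate_fixture("dose_response", alpha = truth,
                              doses = c(0, 1, 2, 3, 4, 6), sigma = 0.05,
                              seed = 5000 + s)
    fit_alpha(assay)$alpha
  }, numeric(1))
  expect_true(all(abs(alphas - truth) / truth < 0.15))
  expect_lt(abs(mean(alphas) - truth), 0.01)
})

test_that("induced_senescent_fraction follows 1 - exp(-alpha D)", {
  expect_equal(induced_senescent_fraction(0.7, 0), 0)
  expect_equal(induced_senescent_fraction(0.5, 2), 1 - exp(-1))
  expect_error(induced_senescent_fraction(0.5, -1), ">= 0")
  # strictly increasing in dose for positive alpha
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(induced_senescent_fraction(0.3, d)) > 0))
  # >90% senescence at 6 Gy requires alpha >= ln(10)/6
  expect_equal(induced_senescent_fraction(log(10) / 6, 6), 0.9)
  expect_lt(induced_senescent_fraction(log(10) / 6 - 0.01, 6), 0.9)
})

test_that("irradiate converts proliferative agents binomially, nothing else", {
  # 1,000 single-pixel agents; alpha and dose chosen for p = 0.3
  lab <- matrix(seq_len(1000), 25, 40)
  st <- as_sim_state(lab,
                     params = dynamics_params(min_area = 1, max_area = 1))
  st$agents$state[1:100] <- "senescent"
  p <- 0.3
  ev <- radiation_event(dose = 2, alpha_normal = -log(1 - p) / 2,
                        alpha_variant = 0)

  # dose 0 leaves the state untouched
  ev0 <- radiation_event(0, 1, 1)
  expect_identical(irradiate(st, ev0)$agents, st$agents)

  set.seed(42)
  converted <- vapply(1:200, function(i) {
    out <- irradiate(st, ev)
    # footprints, counts and pre-existing senescence are untouched
    stopifnot(identical(out$grid$label, st$grid$label),
              nrow(out$agents) == nrow(st$agents),
              all(out$agents$state[1:100] == "senescent"))
    sum(out$agents$state == "senescent") - 100
  }, numeric(1))
  expect_equal(mean(converted), 900 * p,
               tolerance = 5 * sqrt(p * (1 - p) * 900) / sqrt(200) / (900 * p))
})

test_that("irradiate requires a fit for every present class", {
  set.seed(1)
  st <- seed_agents(create_grid(60, 60), seeding_spec(10, 0.5))
  ev <- radiation_event(2, alpha_normal = 0.39, alpha_variant = NULL)
  expect_error(irradiate(st, ev), "class")
})

test_that("senescence_induction_index corrects for pre-existing senescence", {
  expect_equal(senescence_induction_index(0, 0.4), 0.4)
  expect_equal(senescence_induction_index(0.3, 0.3), 0)
  expect_equal(senescence_induction_index(0.2, 0.6), 0.5)
  # may be negative, reported unclipped
  expect_lt(senescence_induction_index(0.4, 0.3), 0)
  expect_error(senescence_induction_index(1, 0.5), "ps0")
  # closed-form composition: with pre-existing fraction s0, the expected
  # post-irradiation senescent fraction is s0 + (1-s0)(1-e^(-aD)), and the
  # index recovers exactly the induced fraction
  for (s0 in c(0, 0.2, 0.7)) {
    for (aD in c(0.1, 0.8, 2)) {
      ind <- 1 - exp(-aD)
      psd <- s0 + (1 - s0) * ind
      expect_equal(senescence_induction_index(s0, psd), ind)
    }
  }
})

test_that("radiation_event converts centigray and accepts fits", {
  ev <- radiation_event(200, alpha_normal = 0.39, alpha_variant = 0.022,
                        dose_unit = "cGy")
  expect_equal(ev$dose_gy, 2)
  fit <- fit_alpha(generate_fixture("dose_response", alpha = 0.25, sigma = 0))
  ev <- radiation_event(2, alpha_normal = fit, alpha_variant = 0.022)
  expect_equal(ev$alpha_normal, 0.25, tolerance = 1e-6)
  expect_error(radiation_event(-1, 1, 1), "dose")
})

test_that("assay CSV round trip preserves the table", {
  assay <- rbind(
    generate_fixture("dose_response", alpha = 0.39, cell_class = "normal"),
    generate_fixture("dose_response", alpha = 0.022, cell_class = "variant"))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(assay), path, row.names = FALSE)
  back <- read_assay_csv(path)
  expect_s3_class(back, "senescence_assay")
  expect_equal(back$sa_bgal_negative_fraction,
               assay$sa_bgal_negative_fraction)
  fits <- lapply(split(back, back$cell_class), fit_alpha)
  expect_equal(fits$normal$alpha, 0.39, tolerance = 1e-6)
  expect_equal(fits$variant$alpha, 0.022, tolerance = 1e-6)
})
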