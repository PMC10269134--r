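test_that("deconvolution applies the published coefficients pointwise", {
  res <- deconvolute_wavelengths(
    tibble::tibble(time_s = 0, a520 = 1.0, a554 = 0.9, a563 = 0.5))
  expect_equal(res$cytc, 0.9 - 0.4 * 1.0 - 0.4 * 0.5)   # 0.3
  expect_equal(res$ecslin, 1.0 - 0.25 * 0.3)            # 0.925
  zero <- deconvolute_wavelengths(
    tibble::tibble(time_s = 0:2, a520 = 0, a554 = 0, a563 = 0))
  expect_equal(zero$cytc, rep(0, 3))
  expect_equal(zero$ecslin, rep(0, 3))
})

test_that("deconvolution is linear and nulls pure-ECS inputs", {
  set.seed(1)
  mk <- function() tibble::tibble(time_s = 1:50, a520 = rnorm(50),
                                  a554 = rnorm(50), a563 = rnorm(50))
  x <- mk(); y <- mk()
  comb <- tibble::tibble(time_s = x$time_s,
                         a520 = 2 * x$a520 + 3 * y$a520,
                         a554 = 2 * x$a554 + 3 * y$a554,
                         a563 = 2 * x$a563 + 3 * y$a563)
  dx <- deconvolute_wavelengths(x); dy <- deconvolute_wavelengths(y)
  dc <- deconvolute_wavelengths(comb)
  expect_equal(dc$cytc, 2 * dx$cytc + 3 * dy$cytc, tolerance = 1e-12)
  expect_equal(dc$ecslin, 2 * dx$ecslin + 3 * dy$ecslin, tolerance = 1e-12)
  # a554 = 0.4 (a520 + a563): no cytochrome component at all
  pure <- tibble::tibble(time_s = 1:20, a520 = sin(1:20), a563 = cos(1:20)) %>%
    dplyr::mutate(a554 = 0.4 * (a520 + a563))
  dp <- deconvolute_wavelengths(pure)
  expect_equal(dp$cytc, rep(0, 20), tolerance = 1e-12)
  expect_equal(dp$ecslin, pure$a520, tolerance = 1e-12)
})

test_that("long-format input requires aligned grids and all wavelengths", {
  long <- tidyr::expand_grid(time_s = 1:5, wavelength_nm = c(520, 554, 563)) %>%
    dplyr::mutate(delta_a = 0)
  expect_silent(deconvolute_wavelengths(long))
  expect_error(deconvolute_wavelengths(long[-1, ]), "aligned")
  expect_error(deconvolute_wavelengths(long[long$wavelength_nm != 554, ]),
               "554")
})

test_that("flash_amplitude reads steps exactly and inverts generated decays", {
  t <- seq(-0.05, 0.1, by = 5e-4)
  step <- tibble::tibble(time_s = t, ecslin = ifelse(t > 0, 0.01, 0))
  res <- flash_amplitude(step)
  expect_equal(res$amplitude, 0.01, tolerance = 1e-9)
  flat <- tibble::tibble(time_s = t, ecslin = 0.005)
  expect_equal(flash_amplitude(flat)$amplitude, 0, tolerance = 1e-9)
  # generated flash with decay: back-extrapolation recovers a1
  sc <- noise_free(study_scenario())
  tr <- gen_ecs_experiment(sc, seed = 1, line = "WT")
  decon <- deconvolute_wavelengths(tr)
  inh <- decon[decon$condition == "dcmu_ha" & decon$regime == "flash", ]
  amp <- flash_amplitude(inh)
  expect_equal(amp$amplitude, sc$ecs$a1, tolerance = 1e-3)
  expect_equal(amp$k_decay, sc$ecs$k_decay, tolerance = 0.05)
  expect_error(flash_amplitude(step, baseline_window_s = 0), "Baseline")
})

test_that("stoichiometry arithmetic and guard rails", {
  res <- psii_psi_stoichiometry(1.0, 0.4)
  expect_equal(res$psii_fraction, 0.6)
  expect_equal(res$psii_psi_ratio, 1.5)
  expect_equal(res$psii_amp, res$amp_total - res$amp_insensitive)
  expect_equal(psii_psi_stoichiometry(0.4, 0.4)$psii_psi_ratio, 0)
  expect_error(psii_psi_stoichiometry(0.3, 0.4), "negative PSII")
  expect_error(psii_psi_stoichiometry(1.0, 0), "positive")
})

test_that("electron_flow_rate is the normalized slope difference", {
  t <- seq(-0.25, 0.25, by = 5e-4)
  trace <- tibble::tibble(
    time_s = t,
    ecslin = ifelse(t <= 0, 0.05 * t, -1.95 * t))
  res <- electron_flow_rate(trace, t_off = 0, a_single_charge = 0.01)
  expect_equal(res$slope_light, 0.05, tolerance = 1e-9)
  expect_equal(res$slope_dark, -1.95, tolerance = 1e-9)
  expect_equal(res$flow, 200, tolerance = 1e-6)
  same <- tibble::tibble(time_s = t, ecslin = 0.02 * t)
  expect_equal(electron_flow_rate(same, 0, a_single_charge = 0.01)$flow, 0,
               tolerance = 1e-9)
  expect_error(electron_flow_rate(trace, 0, window_light_s = 5e-4,
                                  a_single_charge = 0.01), "3 samples")
  expect_error(electron_flow_rate(trace, 0, a_single_charge = 0), "positive")
})

test_that("generated light-off transitions return the configured flow", {
  sc <- noise_free(study_scenario())
  sc$ecs$lines$j_flow <- c(150, 75)
  tr <- gen_ecs_experiment(sc, seed = 1, line = "WT")
  res <- analyze_ecs_experiment(tr)
  expect_equal(res$flow, 150, tolerance = 1e-6)
})

test_that("noisy end-to-end analysis recovers the mutant/WT flow ratio", {
  sc <- study_scenario()
  ratios <- vapply(seq_len(60), function(s) {
    wt <- analyze_ecs_experiment(gen_ecs_experiment(sc, seed = s, line = "WT"))
    mut <- analyze_ecs_experiment(gen_ecs_experiment(sc, seed = 10000 + s,
                                                     line = "cpftsy"))
    mut$flow / wt$flow
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.03)
})
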