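test_that("generators are deterministic in (scenario, seed)", {
  sc <- study_scenario()
  expect_identical(gen_npq_trace(sc, seed = 42), gen_npq_trace(sc, seed = 42))
  expect_false(identical(gen_npq_trace(sc, seed = 42)$fm_prime,
                         gen_npq_trace(sc, seed = 43)$fm_prime))
  expect_identical(gen_count_series(sc, seed = 7), gen_count_series(sc, seed = 7))
  expect_identical(gen_abundance_matrix(sc, seed = 9)$abundance,
                   gen_abundance_matrix(sc, seed = 9)$abundance)
})

test_that("NPQ trace follows the induction model and no-quenching identity", {
  sc <- noise_free(study_scenario())
  # closed form: NPQ_max (1 - exp(-k t)) at the end of 6-min induction
  sc$fluor$npq_max <- 1.2
  sc$fluor$k_ind <- 0.01
  tr <- gen_npq_trace(sc, seed = 1)
  npq <- npq_timecourse(tr)
  s <- attr(npq, "summary")
  expect_equal(s$npq_end_induction, 1.2 * (1 - exp(-3.6)), tolerance = 1e-9)
  expect_equal(s$npq_end_induction, 1.1672, tolerance = 1e-4)
  # NPQ_max = 0: all pulses at the dark Fm, NPQ identically zero
  sc$fluor$npq_max <- 0
  tr0 <- gen_npq_trace(sc, seed = 1)
  expect_equal(unique(tr0$fm_prime), sc$fluor$fm)
  expect_equal(npq_timecourse(tr0)$npq, rep(0, nrow(tr0)))
  expect_error(sim_scenario(fluor = list(npq_max = -1)), "npq_max")
})

test_that("rapid light curve generator matches the Webb model", {
  sc <- noise_free(study_scenario())
  pts <- gen_rapid_light_curve(sc, seed = 1)
  expect_equal(nrow(pts), 13)
  expect_equal(range(pts$e), c(4, 1088))
  # low-irradiance series expansion: phi ~ alpha (1 - alpha E / (2 rETRmax))
  sc$rlc$alpha <- 0.3; sc$rlc$retr_max <- 60
  pts <- gen_rapid_light_curve(sc, seed = 1)
  e1 <- pts$e[1]
  approx <- min(sc$rlc$fv_fm, sc$rlc$alpha * (1 - sc$rlc$alpha * e1 / (2 * 60)))
  expect_equal(pts$phi_psii[1], approx, tolerance = 0.01)
  # noiseless inversion recovers the generating parameters
  fit <- fit_light_curve(pts)
  expect_equal(fit$alpha, 0.3, tolerance = 1e-6)
  expect_equal(fit$retr_max, 60, tolerance = 1e-6)
})

test_that("ECS mixing is the exact inverse of the deconvolution", {
  sc <- noise_free(study_scenario())
  tr <- gen_ecs_experiment(sc, seed = 1, line = "WT")
  truth <- sim_truth(tr)
  decon <- deconvolute_wavelengths(tr)
  for (case in list(c("control", "flash"), c("dcmu_ha", "flash"),
                    c("control", "light_off"))) {
    d <- decon[decon$condition == case[1] & decon$regime == case[2], ]
    tt <- truth[[paste(case[2], case[1], sep = "_")]]
    expect_equal(d$ecslin, tt$e, tolerance = 1e-12)
    expect_equal(d$cytc, tt$c, tolerance = 1e-12)
  }
})

test_that("ECS limiting cases: no PSII and zero flux", {
  sc <- noise_free(study_scenario())
  sc$ecs$lines <- tibble::tibble(line = "x", psii_psi_ratio = 0, j_flow = 0)
  tr <- gen_ecs_experiment(sc, seed = 1, line = "x")
  truth <- sim_truth(tr)
  expect_equal(truth$flash_control$amplitude, truth$flash_dcmu_ha$amplitude)
  decon <- deconvolute_wavelengths(tr)
  off <- decon[decon$condition == "control" & decon$regime == "light_off", ]
  flow <- electron_flow_rate(off, t_off = 0, a_single_charge = sc$ecs$a1)
  expect_equal(flow$flow, 0, tolerance = 1e-9)
})

test_that("pigment generator reproduces configured means and time grid", {
  sc <- noise_free(study_scenario())
  pg <- gen_pigment_timecourse(sc, seed = 1)
  expect_equal(sort(unique(pg$time_h)), c(0, 0.5, 6, 24, 168))
  expect_equal(max(table(pg$line, pg$time_h)), 3)  # three replicates per cell
  merged <- dplyr::inner_join(pg, sc$pigments$means,
                              by = c("line", "time_h"),
                              suffix = c("", "_true"))
  expect_equal(merged$chla, merged$chla_true)
  expect_equal(merged$dtx, merged$dtx_true)
  # configured Ddx = 3, Dtx = 1 gives DES = 0.25 downstream
  sc$pigments$means <- tibble::tibble(line = "x", time_h = 0, chla = 10,
                                      fx = 5, ddx = 3, dtx = 1)
  pg <- gen_pigment_timecourse(sc, seed = 1)
  expect_equal(unique(des_index(pg$ddx, pg$dtx)), 0.25)
  expect_error(
    sim_scenario(pigments = list(means = tibble::tibble(
      line = "x", time_h = 0, chla = -1, fx = 1, ddx = 1, dtx = 1))),
    "non-negative")
})

test_that("count series double daily at one division per day", {
  sc <- noise_free(study_scenario())
  expect_equal(sc$growth$n0, 1e5)
  sc$growth$rates <- tibble::tibble(line = "x", light = "LL", mu = 1)
  cs <- gen_count_series(sc, seed = 1)
  one <- cs[cs$replicate == 1, ]
  expect_equal(one$cells_per_ml, 1e5 * 2^one$time_d)
  # pure exponential inverts exactly
  res <- division_rates(cs)
  expect_equal(res$summary$mu_max, 1, tolerance = 1e-12)
})

test_that("HL±LINC generator obeys its closed forms", {
  sc <- noise_free(study_scenario())
  # +LINC arm: pure first-order loss, rel(60) = exp(-60 k)
  sc$photoinhibition$lines <- tibble::tibble(
    line = "x", n_rep = 1L, k_damage = 0.02007, k_repair = 0.065,
    k_qrelax = 0.15, q_hl = 0.3, q_res = 0)
  tc <- gen_hl_linc_timecourse(sc, seed = 1)
  linc60 <- tc$fv_fm[tc$arm == "HL_LINC" & tc$time_min == 60] /
    tc$fv_fm[tc$arm == "HL_LINC" & tc$time_min == 0]
  expect_equal(linc60, exp(-1.2042), tolerance = 1e-9)
  expect_equal(linc60, 0.2999, tolerance = 2e-4)
  # no damage, no quenching: flat at 100%
  sc$photoinhibition$lines$k_damage <- 0
  sc$photoinhibition$lines$q_hl <- 0
  tc0 <- gen_hl_linc_timecourse(sc, seed = 1)
  expect_equal(unique(tc0$fv_fm), sc$photoinhibition$fvfm0)
  # packaged WT -LINC arm ends recovery at the configured 96%
  tcw <- gen_hl_linc_timecourse(noise_free(study_scenario()), seed = 1)
  rel <- sim_truth(tcw)$rel
  expect_equal(100 * rel$rel[rel$line == "WT" & rel$arm == "HL" &
                             rel$time_min == 90], 96, tolerance = 1e-8)
  expect_equal(100 * rel$rel[rel$line == "cpftsy" & rel$arm == "HL" &
                             rel$time_min == 60], 40, tolerance = 1e-8)
})

test_that("abundance generator: design, noise-free effects and truth record", {
  sc <- study_scenario()
  expect_equal(sum(sc$proteomics$groups |> length()), 3)
  sc$proteomics$n_prot <- 50
  sc$proteomics$sigma_rep <- 0
  sc$proteomics$mcar_p <- 0
  sc$proteomics$mnar_slope <- 50          # sharp cutoff far below the data
  sc$proteomics$mnar_mid <- -100
  pq <- gen_abundance_matrix(sc, seed = 3)
  expect_equal(table(pq$samples$group)[["WT"]], 5)
  expect_false(anyNA(pq$abundance))
  truth <- sim_truth(pq)
  lr <- log2_group_ratio(pq, "cpftsy.1-25.7", "WT")
  merged <- dplyr::inner_join(lr, truth, by = "protein_id")
  expect_equal(merged$log2_ratio, merged$`effect_cpftsy.1-25.7`, tolerance = 1e-9)
  # anchored proteins carry their configured effects exactly
  expect_equal(merged$log2_ratio[merged$protein_id == "A0T0L2"], -1.35)
})

test_that("noise-free generation + analysis recovers truth across modules", {
  sc <- noise_free(study_scenario())
  # fluorescence: NPQ series equals the model series
  tr <- gen_npq_trace(sc, seed = 1)
  npq <- npq_timecourse(tr)
  expect_equal(npq$npq, sim_truth(tr)$npq_true$npq, tolerance = 1e-9)
  # growth
  res <- division_rates(gen_count_series(sc, seed = 1))
  truth_rates <- sc$growth$rates
  merged <- dplyr::inner_join(res$summary, truth_rates, by = c("line", "light"))
  expect_equal(merged$mu_max, merged$mu, tolerance = 1e-9)
  # photoinhibition damage rate
  norm <- normalize_to_initial(gen_hl_linc_timecourse(sc, seed = 1))
  linc <- norm[norm$line == "cpftsy" & norm$arm == "HL_LINC", ]
  expect_equal(photodamage_rate(linc)$k_damage, -log(0.30) / 60, tolerance = 1e-9)
  # ECS flow
  tr_e <- gen_ecs_experiment(sc, seed = 1, line = "WT")
  res_e <- analyze_ecs_experiment(tr_e)
  expect_equal(res_e$flow, 150, tolerance = 1e-6)
  expect_equal(res_e$psii_psi_ratio, 1.2, tolerance = 1e-3)
})
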