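# Synthetic-data generators. Every generator is deterministic given
# (scenario, seed), validates its parameter block, and attaches the exact
# noise-free truth as attr(x, "truth") so downstream estimators can be
# checked for parameter recovery.

#' Extract the ground-truth record attached to a generated dataset
#' @param x An object produced by one of the `gen_*()` generators.
#' @return The truth record (a list), or `NULL` if absent.
#' @export
sim_truth <- function(x) attr(x, "truth", exact = TRUE)

# ---------------------------------------------------------------------------
# Fluorescence

npq_model <- function(u, npq_max, k_ind) npq_max * (1 - exp(-k_ind * u))

npq_relax_model <- function(v, npq_end, f_fast, k_rel) {
  npq_end * (f_fast * exp(-k_rel * v) + (1 - f_fast))
}

#' Generate a saturating-pulse NPQ induction/relaxation trace
#'
#' Protocol: 3 min darkness, 6 min actinic induction (default 470
#' umol photons m^-2 s^-1 blue light), 6 min dim-light relaxation (default 8),
#' with a saturating pulse every 30 s. During induction
#' `NPQ(t) = NPQ_max (1 - exp(-k_ind t))`; during relaxation the quenching
#' decays biexponentially-with-plateau,
#' `NPQ(t) = NPQ_end (f_fast exp(-k_rel t) + 1 - f_fast)`, reflecting a fast
#' qE component on top of a sustained component. Maximal fluorescence under
#' each pulse is `Fm'(t) = Fm / (1 + NPQ(t))`; multiplicative Gaussian noise
#' with the configured CV is applied to both `F` and `Fm'`.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Integer seed; defaults to the scenario seed.
#' @return Tibble with columns `time_s`, `phase`, `actinic_e`, `f`,
#'   `fm_prime`, plus a truth attribute holding the noise-free series and
#'   model parameters.
#' @export
gen_npq_trace <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  fl <- scenario$fluor
  t_ind0 <- fl$dark_s
  t_rel0 <- fl$dark_s + fl$induction_s
  t_end <- t_rel0 + fl$relaxation_s
  time_s <- seq(0, t_end, by = fl$pulse_interval_s)
  phase <- ifelse(time_s < t_ind0, "dark",
                  ifelse(time_s <= t_rel0, "induction", "relaxation"))
  # first induction pulse sits at the moment the actinic light switches on
  npq_end <- npq_model(fl$induction_s, fl$npq_max, fl$k_ind)
  npq_true <- dplyr::case_when(
    phase == "dark" ~ 0,
    phase == "induction" ~ npq_model(time_s - t_ind0, fl$npq_max, fl$k_ind),
    TRUE ~ npq_relax_model(time_s - t_rel0, npq_end, fl$f_fast, fl$k_rel)
  )
  fm_prime_true <- fl$fm / (1 + npq_true)
  fvfm_dark <- (fl$fm - fl$f0) / fl$fm
  phi_true <- ifelse(phase == "dark", fvfm_dark, fvfm_dark * fm_prime_true / fl$fm)
  f_true <- ifelse(phase == "dark", fl$f0, fm_prime_true * (1 - phi_true))
  actinic_e <- dplyr::case_when(
    phase == "dark" ~ 0,
    phase == "induction" ~ fl$e_induction,
    TRUE ~ fl$e_relaxation
  )
  out <- with_seed(seed, {
    tibble::tibble(
      time_s = time_s, phase = phase, actinic_e = actinic_e,
      f = f_true * rnorm_cv(length(time_s), fl$noise_cv),
      fm_prime = fm_prime_true * rnorm_cv(length(time_s), fl$noise_cv)
    )
  })
  attr(out, "truth") <- list(
    f0 = fl$f0, fm = fl$fm, npq_max = fl$npq_max, k_ind = fl$k_ind,
    f_fast = fl$f_fast, k_rel = fl$k_rel, npq_end = npq_end,
    npq_true = tibble::tibble(time_s = time_s, phase = phase, npq = npq_true)
  )
  out
}

webb_retr <- function(e, alpha, retr_max) retr_max * (1 - exp(-alpha * e / retr_max))

#' Generate a rapid light curve
#'
#' Quantum yields follow the Webb saturating-exponential model,
#' `phi_PSII(E) = rETR(E) / E` with
#' `rETR(E) = rETRmax (1 - exp(-alpha E / rETRmax))`, capped at the
#' dark-adapted Fv/Fm, with multiplicative noise on the yields.
#'
#' @inheritParams gen_npq_trace
#' @return Tibble with columns `e` (umol photons m^-2 s^-1) and `phi_psii`.
#' @export
gen_rapid_light_curve <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  rl <- scenario$rlc
  e <- rl$e_steps
  phi_true <- pmin(rl$fv_fm, webb_retr(e, rl$alpha, rl$retr_max) / e)
  out <- with_seed(seed, {
    tibble::tibble(e = e, phi_psii = phi_true * rnorm_cv(length(e), rl$noise_cv))
  })
  attr(out, "truth") <- list(
    alpha = rl$alpha, retr_max = rl$retr_max, ek = rl$retr_max / rl$alpha,
    fv_fm = rl$fv_fm, phi_true = phi_true
  )
  out
}

# ---------------------------------------------------------------------------
# Electrochromic shift

# Forward spectral mixing, chosen as the exact inverse of the three-wavelength
# deconvolution: a563 = 0.1 E; a520 = E + 0.25 C; a554 = C + 0.4 a520 + 0.4 a563.
ecs_mix <- function(e_comp, c_comp, noise_sd, n) {
  a563 <- 0.1 * e_comp + rnorm(n, 0, noise_sd)
  a520 <- e_comp + 0.25 * c_comp + rnorm(n, 0, noise_sd)
  a554 <- c_comp + 0.4 * a520 + 0.4 * a563 + rnorm(n, 0, noise_sd)
  list(a520 = a520, a554 = a554, a563 = a563)
}

ecs_one_trace <- function(time_s, e_comp, c_comp, condition, regime,
                          event_time_s, line, noise_sd) {
  n <- length(time_s)
  mixed <- ecs_mix(e_comp, c_comp, noise_sd, n)
  tibble::tibble(
    line = line, condition = condition, regime = regime,
    event_time_s = event_time_s,
    time_s = rep(time_s, 3),
    wavelength_nm = rep(c(520, 554, 563), each = n),
    delta_a = c(mixed$a520, mixed$a554, mixed$a563)
  )
}

#' Generate a three-wavelength ECS experiment
#'
#' Produces absorbance-difference traces at 520, 554 and 563 nm for a single
#' line under two conditions (untreated control and DCMU + hydroxylamine,
#' which blocks PSII charge separation) and two regimes:
#'
#' * `flash`: at the event time the linear ECS component jumps by
#'   `a1 * (1 + psii_psi_ratio)` in the control (PSII and PSI each separate
#'   one charge) and by `a1` alone under DCMU + HA (one charge per chain,
#'   PSI only), then decays exponentially with rate `k_decay`.
#' * `light_off`: the linear ECS is piecewise linear with slope `drift`
#'   before the light-to-dark transition and `drift - J * a1` after it, so
#'   the slope difference normalized by the single-charge amplitude recovers
#'   the electron flow `J`.
#'
#' The true components are spectrally mixed so that the published
#' three-wavelength deconvolution is their exact inverse, then additive
#' Gaussian noise is applied per wavelength.
#'
#' @inheritParams gen_npq_trace
#' @param line Which line of `scenario$ecs$lines` to simulate.
#' @return Long-format tibble (`line`, `condition`, `regime`,
#'   `event_time_s`, `time_s`, `wavelength_nm`, `delta_a`).
#' @export
gen_ecs_experiment <- function(scenario, seed = scenario$seed, line = NULL) {
  validate_scenario(scenario)
  ec <- scenario$ecs
  ln <- if (is.null(line)) ec$lines$line[1] else line
  row <- ec$lines[ec$lines$line == ln, ]
  if (nrow(row) != 1) {
    abort(sprintf("Line '%s' not found in scenario$ecs$lines.", ln))
  }
  dt <- ec$dt_s
  # rounding keeps the grid identical through text serialization
  t_flash <- round(seq(-0.1, 0.3, by = dt), 12)
  t_off <- round(seq(-0.3, 0.3, by = dt), 12)
  cytc_flash <- function(t) ec$cytc_amp * ifelse(t > 0, 1 - exp(-t / 0.05), 0)
  cytc_off <- function(t) ec$cytc_amp * ifelse(t > 0, exp(-t / 0.1), 1)
  e_flash <- function(t, jump) ifelse(t > 0, jump * exp(-ec$k_decay * t), 0)
  e_level0 <- 3 * ec$a1   # steady-state ECS level under continuous light
  e_off <- function(t, j) {
    e_level0 + ec$drift * t + ifelse(t > 0, -j * ec$a1 * t, 0)
  }
  jump_ctrl <- ec$a1 * (1 + row$psii_psi_ratio)
  truths <- list(
    flash_control = list(e = e_flash(t_flash, jump_ctrl), c = cytc_flash(t_flash),
                         amplitude = jump_ctrl),
    flash_dcmu_ha = list(e = e_flash(t_flash, ec$a1), c = cytc_flash(t_flash),
                         amplitude = ec$a1),
    light_off_control = list(e = e_off(t_off, row$j_flow), c = cytc_off(t_off),
                             slope_light = ec$drift,
                             slope_dark = ec$drift - row$j_flow * ec$a1),
    light_off_dcmu_ha = list(e = e_off(t_off, 0), c = cytc_off(t_off),
                             slope_light = ec$drift, slope_dark = ec$drift)
  )
  out <- with_seed(seed, {
    dplyr::bind_rows(
      ecs_one_trace(t_flash, truths$flash_control$e, truths$flash_control$c,
                    "control", "flash", 0, ln, ec$noise_sd),
      ecs_one_trace(t_flash, truths$flash_dcmu_ha$e, truths$flash_dcmu_ha$c,
                    "dcmu_ha", "flash", 0, ln, ec$noise_sd),
      ecs_one_trace(t_off, truths$light_off_control$e, truths$light_off_control$c,
                    "control", "light_off", 0, ln, ec$noise_sd),
      ecs_one_trace(t_off, truths$light_off_dcmu_ha$e, truths$light_off_dcmu_ha$c,
                    "dcmu_ha", "light_off", 0, ln, ec$noise_sd)
    )
  })
  attr(out, "truth") <- c(truths, list(
    a1 = ec$a1, psii_psi_ratio = row$psii_psi_ratio, j_flow = row$j_flow,
    k_decay = ec$k_decay, drift = ec$drift,
    t_flash = t_flash, t_off = t_off
  ))
  out
}

# ---------------------------------------------------------------------------
# Pigments and growth

#' Generate a per-cell pigment time course
#'
#' Three biological replicates (by default) per line and time point, with
#' independent lognormal multiplicative noise (mean-one, given CV) around the
#' configured per-cell means for Chl a, fucoxanthin, diadinoxanthin and
#' diatoxanthin.
#'
#' @inheritParams gen_npq_trace
#' @return Tibble (`line`, `time_h`, `replicate`, `chla`, `fx`, `ddx`, `dtx`),
#'   all pigments in fmol per cell.
#' @export
gen_pigment_timecourse <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  pg <- scenario$pigments
  base <- tidyr::expand_grid(pg$means, replicate = seq_len(pg$n_rep))
  out <- with_seed(seed, {
    n <- nrow(base)
    dplyr::mutate(base,
      chla = .data$chla * rlnorm_cv(n, pg$noise_cv),
      fx = .data$fx * rlnorm_cv(n, pg$noise_cv),
      ddx = .data$ddx * rlnorm_cv(n, pg$noise_cv),
      dtx = .data$dtx * rlnorm_cv(n, pg$noise_cv)
    )
  })
  out <- dplyr::select(out, "line", "time_h", "replicate", "chla", "fx", "ddx", "dtx")
  attr(out, "truth") <- list(means = pg$means, noise_cv = pg$noise_cv)
  out
}

#' Generate cell-count growth series
#'
#' Counts follow `N(t) = N0 * 2^(mu * max(t - lag, 0))` within the
#' exponential window, smoothly saturating towards the configured carrying
#' capacity (`N_obs = capacity * N / (capacity + N)` for finite capacity),
#' with lognormal multiplicative noise.
#'
#' @inheritParams gen_npq_trace
#' @return Tibble (`line`, `light`, `replicate`, `time_d`, `cells_per_ml`).
#' @export
gen_count_series <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  gr <- scenario$growth
  base <- tidyr::expand_grid(gr$rates, replicate = seq_len(gr$n_rep),
                             time_d = gr$times_d)
  n_true <- gr$n0 * 2^(base$mu * pmax(base$time_d - gr$lag_d, 0))
  if (is.finite(gr$capacity)) {
    n_true <- gr$capacity * n_true / (gr$capacity + n_true)
  }
  out <- with_seed(seed, {
    dplyr::mutate(base, cells_per_ml = n_true * rlnorm_cv(nrow(base), gr$noise_cv))
  })
  out <- dplyr::select(out, "line", "light", "replicate", "time_d", "cells_per_ml")
  attr(out, "truth") <- list(rates = gr$rates, n0 = gr$n0, lag_d = gr$lag_d,
                             capacity = gr$capacity, noise_cv = gr$noise_cv)
  out
}

# ---------------------------------------------------------------------------
# Photoinhibition (high light +/- lincomycin)

# Relative Fv/Fm (fraction of initial) under the two-state damage model with
# a sustained-quenching overlay. In the lincomycin arm repair is blocked and
# the damage constant absorbs all loss, so the trajectory is exp(-kd * t).
photoinhibition_model <- function(t, k_damage, k_repair, k_qrelax, q_hl, q_res,
                                  k_qind, hl_end = 60) {
  ks <- k_damage + k_repair
  d_hl <- if (ks > 0) k_damage / ks * (1 - exp(-ks * pmin(t, hl_end))) else rep(0, length(t))
  d60 <- if (ks > 0) k_damage / ks * (1 - exp(-ks * hl_end)) else 0
  d <- ifelse(t <= hl_end, d_hl, d60 * exp(-k_repair * (t - hl_end)))
  q60 <- q_hl * (1 - exp(-k_qind * hl_end))
  q <- ifelse(t <= hl_end,
              q_hl * (1 - exp(-k_qind * t)),
              q_res + (q60 - q_res) * exp(-k_qrelax * (t - hl_end)))
  (1 - d) * (1 - q)
}

#' Generate high-light (± lincomycin) Fv/Fm time courses
#'
#' Two arms per line: `HL` (high light, repair active) and `HL_LINC`
#' (lincomycin blocks chloroplast translation, hence PSII repair). The
#' damaged fraction follows `dD/dt = k_damage (1 - D) - k_repair D` during
#' the 60-min high-light phase (with `k_repair = 0` in the +LINC arm);
#' during the 30-min dim-light recovery damage stops and repair continues in
#' the -LINC arm only. A sustained-quenching term builds during high light
#' and relaxes with `k_qrelax` towards the residual `q_res` during recovery.
#' Reported `fv_fm = fvfm0 * (1 - D) * (1 - q)`, with multiplicative noise.
#' In the +LINC arm the damage constant absorbs the whole decline
#' (relative Fv/Fm is exactly `exp(-k_damage t)`).
#'
#' @inheritParams gen_npq_trace
#' @return Tibble (`line`, `arm`, `replicate`, `time_min`, `fv_fm`).
#' @export
gen_hl_linc_timecourse <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  ph <- scenario$photoinhibition
  base <- tidyr::expand_grid(ph$lines, arm = c("HL", "HL_LINC"))
  rows <- purrr::pmap(base, function(line, n_rep, k_damage, k_repair, k_qrelax,
                                     q_hl, q_res, arm, ...) {
    rel <- if (arm == "HL_LINC") {
      photoinhibition_model(ph$times_min, k_damage, 0, k_qrelax, 0, 0,
                            ph$k_qind, ph$hl_end_min)
    } else {
      photoinhibition_model(ph$times_min, k_damage, k_repair, k_qrelax, q_hl,
                            q_res, ph$k_qind, ph$hl_end_min)
    }
    tidyr::expand_grid(replicate = seq_len(n_rep),
                       tibble::tibble(time_min = ph$times_min, rel = rel)) %>%
      dplyr::mutate(line = line, arm = arm)
  })
  base_tbl <- dplyr::bind_rows(rows)
  out <- with_seed(seed, {
    dplyr::mutate(base_tbl,
      fv_fm = ph$fvfm0 * .data$rel * rnorm_cv(nrow(base_tbl), ph$noise_cv))
  })
  truth_rel <- dplyr::distinct(dplyr::select(base_tbl, "line", "arm", "time_min", "rel"))
  out <- dplyr::select(out, "line", "arm", "replicate", "time_min", "fv_fm")
  attr(out, "truth") <- list(lines = ph$lines, rel = truth_rel, fvfm0 = ph$fvfm0,
                             noise_cv = ph$noise_cv)
  out
}

# ---------------------------------------------------------------------------
# Proteomics

#' Generate a label-free protein abundance matrix with known truth
#'
#' Per-protein baseline log2 abundance is Normal(`mu0`, `sigma_protein`); a
#' fraction `pi_diff` of proteins carry a group effect whose magnitude is
#' drawn from Normal(`effect_mean`, `effect_sd`) (absolute value) with a
#' random sign shared by both mutant groups. Replicate noise is Normal on the
#' log2 scale. Missing values combine a missing-completely-at-random
#' component with intensity-dependent (logistic) censoring of low-abundance
#' measurements. Scenario `anchors` inject proteins with fixed, named
#' effects. Peptide counts are `1 + Poisson(lambda)`.
#'
#' @inheritParams gen_npq_trace
#' @return A [protein_quant] object; its truth attribute records per-protein
#'   differential flags and true log2 effects per group.
#' @export
gen_abundance_matrix <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  pr <- scenario$proteomics
  groups <- pr$groups
  n_grp <- length(groups)
  anchors <- pr$anchors
  n_anchor <- if (is.null(anchors)) 0L else nrow(anchors)
  n_free <- pr$n_prot - n_anchor
  if (n_free < 0) abort("proteomics: more anchors than proteins.")
  with_seed(seed, {
    ids <- c(if (n_anchor) anchors$protein_id,
             sprintf("P%05d", seq_len(n_free)))
    baseline <- rnorm(pr$n_prot, pr$mu0, pr$sigma_protein)
    is_diff <- c(rep(TRUE, n_anchor),
                 as.logical(rbinom(n_free, 1, pr$pi_diff)))
    # effects: one column per group; reference group (first) has none
    eff <- matrix(0, pr$n_prot, n_grp, dimnames = list(ids, groups))
    sign_free <- sample(c(-1, 1), n_free, replace = TRUE)
    for (g in seq_len(n_grp)[-1]) {
      mag <- abs(rnorm(n_free, pr$effect_mean, pr$effect_sd))
      eff[n_anchor + seq_len(n_free), g] <-
        ifelse(is_diff[n_anchor + seq_len(n_free)], sign_free * mag, 0)
    }
    if (n_anchor) {
      if (n_grp < 3) abort("proteomics: anchors need two non-reference groups.")
      eff[seq_len(n_anchor), 2] <- anchors$effect_mutant1
      eff[seq_len(n_anchor), 3] <- anchors$effect_mutant2
    }
    sample_ids <- paste(rep(groups, each = pr$n_rep),
                        rep(seq_len(pr$n_rep), n_grp), sep = "_")
    grp_of <- rep(groups, each = pr$n_rep)
    log2_mat <- matrix(NA_real_, pr$n_prot, length(sample_ids),
                       dimnames = list(ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      log2_mat[, j] <- baseline + eff[, grp_of[j]] + rnorm(pr$n_prot, 0, pr$sigma_rep)
    }
    p_miss <- pr$mcar_p + (1 - pr$mcar_p) *
      stats::plogis(-(log2_mat - pr$mnar_mid) * pr$mnar_slope)
    miss <- matrix(runif(length(log2_mat)) < p_miss, nrow = pr$n_prot)
    abn <- 2^log2_mat
    abn[miss] <- NA_real_
    peptides <- 1L + rpois(pr$n_prot, pr$peptide_lambda)
    if (n_anchor && !is.null(anchors$peptides)) {
      peptides[seq_len(n_anchor)] <- anchors$peptides
    }
    unique_peptides <- pmax(1L, peptides - rpois(pr$n_prot, 0.5))
    proteins <- tibble::tibble(
      protein_id = ids,
      description = c(if (n_anchor) anchors$label, rep("simulated protein", n_free)),
      location = sample(c("TM", "S", "L", "Cp"), pr$n_prot, replace = TRUE,
                        prob = c(0.4, 0.35, 0.1, 0.15)),
      encoded = sample(c("N", "Cp"), pr$n_prot, replace = TRUE, prob = c(0.8, 0.2)),
      peptides = peptides,
      unique_peptides = unique_peptides
    )
    pq <- protein_quant(
      abundance = dplyr::bind_cols(tibble::tibble(protein_id = ids),
                                   tibble::as_tibble(abn)),
      samples = tibble::tibble(sample_id = sample_ids, group = grp_of),
      proteins = proteins
    )
    truth <- dplyr::bind_cols(
      tibble::tibble(protein_id = ids, is_diff = is_diff, baseline_log2 = baseline),
      tibble::as_tibble(eff[, -1, drop = FALSE], .name_repair = ~ paste0("effect_", .x))
    )
    names(truth)[-(1:3)] <- paste0("effect_", groups[-1])
    attr(pq, "truth") <- truth
    pq
  })
}
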