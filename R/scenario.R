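#' Simulation scenarios with known ground truth
#'
#' A simulation scenario bundles every parameter needed to generate synthetic
#' versions of the inputs this package analyses: PAM fluorescence traces with
#' saturating-pulse annotations, three-wavelength electrochromic-shift (ECS)
#' traces, per-cell pigment time courses, cell-count growth series, high-light
#' (± lincomycin) Fv/Fm time courses, and label-free protein abundance
#' matrices. Each generator records the exact noise-free truth alongside its
#' output so that every downstream estimator can be checked for parameter
#' recovery.
#'
#' @param name Scenario name.
#' @param seed Default integer seed used when a generator is called without one.
#' @param fluor,rlc,ecs,pigments,growth,photoinhibition,proteomics Named lists
#'   overriding the corresponding parameter blocks; see [scenario_defaults()]
#'   for the fields and units of each block.
#' @return A validated `sim_scenario` object (a named list).
#' @seealso [load_scenario()], [scenario_cpftsy_study()]
#' @export
sim_scenario <- function(name = "custom", seed = 1L, fluor = list(),
                         rlc = list(), ecs = list(), pigments = list(),
                         growth = list(), photoinhibition = list(),
                         proteomics = list()) {
  base <- scenario_defaults()
  # shallow merge: table-valued fields (tibbles) are replaced wholesale
  merge_block <- function(b, o) { for (nm in names(o)) b[[nm]] <- o[[nm]]; b }
  sc <- list(
    name = name,
    seed = as.integer(seed),
    fluor = merge_block(base$fluor, fluor),
    rlc = merge_block(base$rlc, rlc),
    ecs = merge_block(base$ecs, ecs),
    pigments = merge_block(base$pigments, pigments),
    growth = merge_block(base$growth, growth),
    photoinhibition = merge_block(base$photoinhibition, photoinhibition),
    proteomics = merge_block(base$proteomics, proteomics)
  )
  class(sc) <- "sim_scenario"
  validate_scenario(sc)
}

#' Default scenario parameter blocks
#'
#' Units: irradiance in umol photons m^-2 s^-1, absorbance differences in
#' dimensionless delta-A, pigments in fmol per cell, counts in cells per ml,
#' times in the convention of each assay (seconds for traces, minutes for
#' photoinhibition, hours for pigments, days for growth). Rate constants are
#' per unit of the assay's time axis.
#'
#' @return Named list of parameter blocks.
#' @export
scenario_defaults <- function() {
  list(
    fluor = list(
      f0 = 150, fm = 600,            # dark-adapted minimal/maximal fluorescence (a.u.)
      npq_max = 1.2,                 # plateau of NPQ induction
      k_ind = 0.01,                  # induction rate constant (s^-1)
      f_fast = 0.8,                  # fraction of NPQ relaxing quickly
      k_rel = 0.015,                 # fast relaxation rate constant (s^-1)
      noise_cv = 0.03,
      dark_s = 180, induction_s = 360, relaxation_s = 360, pulse_interval_s = 30,
      e_induction = 470, e_relaxation = 8
    ),
    rlc = list(
      alpha = 0.55,                  # initial slope, rETR per unit irradiance
      retr_max = 60,                 # light-saturated rETR (asymptote)
      fv_fm = 0.65,                  # cap on quantum yield at vanishing light
      e_steps = rlc_default_steps(),
      noise_cv = 0.03
    ),
    ecs = list(
      a1 = 0.01,                     # delta-A per single charge per chain
      k_decay = 5,                   # flash decay rate constant (s^-1)
      drift = 0,                     # baseline drift (delta-A s^-1)
      noise_sd = 2e-4,               # additive Gaussian noise on each wavelength
      cytc_amp = 2e-3,               # amplitude of the cytochrome component
      dt_s = 5e-4,                   # sampling interval
      lines = tibble::tibble(
        line = c("WT", "cpftsy"),
        psii_psi_ratio = c(1.2, 0.8),
        j_flow = c(150, 75)          # electrons s^-1 chain^-1
      )
    ),
    pigments = list(
      n_rep = 3, noise_cv = 0.05,
      times_h = c(0, 0.5, 6, 24, 168),
      means = default_pigment_means()
    ),
    growth = list(
      n0 = 1e5,                      # starting density, cells ml^-1
      times_d = 0:3, n_rep = 3, noise_cv = 0.03,
      lag_d = 0, capacity = Inf,
      rates = tibble::tibble(
        line = "WT", light = "LL", mu = 1.42  # divisions day^-1
      )
    ),
    photoinhibition = list(
      fvfm0 = 0.65, noise_cv = 0.05,
      times_min = c(0, 15, 30, 45, 60, 75, 90),
      hl_end_min = 60, recovery_end_min = 90,
      k_qind = 0.1,                  # quenching induction rate (min^-1)
      lines = tibble::tibble(
        line = "WT", n_rep = 3,
        k_damage = 0.02, k_repair = 0.06, k_qrelax = 0.15,
        q_hl = 0.3, q_res = 0
      )
    ),
    proteomics = list(
      n_prot = 2000, n_rep = 5,
      groups = c("WT", "mutant1", "mutant2"),
      pi_diff = 0.1,                 # fraction of truly regulated proteins
      effect_mean = 1, effect_sd = 0.25,   # |log2 effect| distribution
      sigma_protein = 1.5,           # between-protein spread of baseline log2
      sigma_rep = 0.5,               # replicate noise, log2 scale
      mu0 = 20,                      # grand mean log2 abundance
      mcar_p = 0.02,                 # missing-completely-at-random probability
      mnar_mid = 17, mnar_slope = 1, # logistic missingness vs log2 abundance
      peptide_lambda = 4,            # peptides per protein ~ 1 + Poisson(lambda)
      anchors = NULL                 # optional tibble of fixed-effect proteins
    )
  )
}

#' Default rapid-light-curve irradiance grid
#'
#' Thirteen stepwise increasing irradiances spanning 4 to 1088
#' umol photons m^-2 s^-1 (geometric spacing), optionally extended by one
#' step at 1216 for strongly light-acclimated samples.
#'
#' @param extended Add the extra 1216 step.
#' @return Numeric vector of irradiances.
#' @export
rlc_default_steps <- function(extended = FALSE) {
  steps <- round(4 * (1088 / 4)^(seq(0, 12) / 12))
  steps[length(steps)] <- 1088
  if (extended) steps <- c(steps, 1216)
  steps
}

# Per-line pigment means (fmol per cell) across the low-light to medium-light
# shift. The de-epoxidation state rises with exposure time, more strongly in
# the mutants; cpftsy.2-2.8 carries more pigment per cell overall.
default_pigment_means <- function() {
  des_wt <- c(0.05, 0.18, 0.12, 0.10, 0.08)
  des_mut <- c(0.05, 0.20, 0.25, 0.30, 0.35)
  times <- c(0, 0.5, 6, 24, 168)
  build <- function(line, chla, fx, ddx, des) {
    tibble::tibble(
      line = line, time_h = times,
      chla = chla, fx = fx, ddx = ddx,
      dtx = des / (1 - des) * ddx
    )
  }
  dplyr::bind_rows(
    build("WT", 0.25, 0.18, 0.030, des_wt),
    build("cpftsy.1-25.7", 0.25, 0.18, 0.030, des_mut),
    build("cpftsy.2-2.8", 0.34, 0.24, 0.042, des_mut),
    build("cpftsy.2-4.8", 0.25, 0.18, 0.030, des_mut)
  )
}

#' Validate a simulation scenario
#'
#' Checks rate constants are non-negative, coefficients of variation lie in
#' `[0, 1)`, irradiance steps are strictly increasing, and amplitudes are
#' positive. Called by every generator.
#'
#' @param sc A `sim_scenario`.
#' @return The scenario, invisibly usable in pipes; errors on violation.
#' @export
validate_scenario <- function(sc) {
  if (!inherits(sc, "sim_scenario")) abort("Not a `sim_scenario` object.")
  fl <- sc$fluor
  check_number(fl$npq_max, "fluor$npq_max", lower = 0)
  check_number(fl$k_ind, "fluor$k_ind", lower = 0)
  check_number(fl$k_rel, "fluor$k_rel", lower = 0)
  check_number(fl$f_fast, "fluor$f_fast", lower = 0, upper = 1)
  check_number(fl$f0, "fluor$f0", lower = 0, allow_zero_lower = FALSE)
  if (fl$fm <= fl$f0) abort("fluor: `fm` must exceed `f0`.")
  rl <- sc$rlc
  check_number(rl$alpha, "rlc$alpha", lower = 0, allow_zero_lower = FALSE)
  check_number(rl$retr_max, "rlc$retr_max", lower = 0, allow_zero_lower = FALSE)
  if (any(rl$e_steps <= 0)) abort("rlc: irradiance steps must be positive.")
  if (any(diff(rl$e_steps) <= 0)) abort("rlc: irradiance steps must be strictly increasing.")
  check_number(sc$ecs$a1, "ecs$a1", lower = 0, allow_zero_lower = FALSE)
  check_number(sc$ecs$k_decay, "ecs$k_decay", lower = 0)
  check_number(sc$ecs$noise_sd, "ecs$noise_sd", lower = 0)
  if (any(sc$ecs$lines$j_flow < 0)) abort("ecs: electron flow truths must be >= 0.")
  if (any(sc$ecs$lines$psii_psi_ratio < 0)) abort("ecs: PSII/PSI ratios must be >= 0.")
  pg <- sc$pigments
  if (any(unlist(pg$means[c("chla", "fx", "ddx", "dtx")]) < 0)) {
    abort("pigments: configured means must be non-negative.")
  }
  gr <- sc$growth
  if (any(gr$rates$mu < 0)) abort("growth: division rates must be >= 0.")
  check_number(gr$n0, "growth$n0", lower = 0, allow_zero_lower = FALSE)
  ph <- sc$photoinhibition
  for (col in c("k_damage", "k_repair", "k_qrelax")) {
    if (any(ph$lines[[col]] < 0)) abort(sprintf("photoinhibition: `%s` must be >= 0.", col))
  }
  if (any(ph$lines$q_hl < 0 | ph$lines$q_hl >= 1)) {
    abort("photoinhibition: `q_hl` must lie in [0, 1).")
  }
  pr <- sc$proteomics
  check_number(pr$pi_diff, "proteomics$pi_diff", lower = 0, upper = 1)
  for (blk in c("fluor", "rlc", "pigments", "growth", "photoinhibition")) {
    cv <- sc[[blk]]$noise_cv
    if (!is.null(cv)) check_number(cv, paste0(blk, "$noise_cv"), lower = 0, upper = 1 - 1e-12)
  }
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$name, " (seed ", x$seed, ")\n", sep = "")
  cat("  growth lines:      ", paste(unique(x$growth$rates$line), collapse = ", "), "\n")
  cat("  ecs lines:         ", paste(x$ecs$lines$line, collapse = ", "), "\n")
  cat("  photoinh. lines:   ", paste(x$photoinhibition$lines$line, collapse = ", "), "\n")
  cat("  proteomics groups: ", paste(x$proteomics$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Back-compute photoinhibition quenching parameters from endpoint fractions
#'
#' The two-state photodamage model reports relative Fv/Fm
#' `(1 - D(t)) * (1 - q(t))`, with damage `D` following
#' `dD/dt = k_damage (1 - D) - k_repair D` during high light and pure repair
#' during dim-light recovery, and sustained quenching `q` rising with rate
#' `k_qind` during high light then relaxing with `k_qrelax` towards a residual.
#' Studies of this kind print endpoint fractions rather than rate constants,
#' so given the damage rate (from the translation-blocked arm), a chosen
#' repair rate and the two endpoint fractions, this solves for the quenching
#' amplitude `q_hl` and residual `q_res` that reproduce the endpoints exactly.
#'
#' @param k_damage Damage rate constant (min^-1).
#' @param k_repair Repair rate constant (min^-1).
#' @param frac_60 Relative Fv/Fm (0-1) at the end of the 60-min high-light phase.
#' @param frac_90 Relative Fv/Fm at the end of the 30-min recovery.
#' @param k_qrelax Quenching relaxation rate (min^-1).
#' @param k_qind Quenching induction rate during high light (min^-1).
#' @param hl_min,rec_min Phase durations in minutes.
#' @return List with `q_hl`, `q_res` and the implied damage levels.
#' @export
solve_quenching_params <- function(k_damage, k_repair, frac_60, frac_90,
                                   k_qrelax = 0.15, k_qind = 0.1,
                                   hl_min = 60, rec_min = 30) {
  ks <- k_damage + k_repair
  d60 <- k_damage / ks * (1 - exp(-ks * hl_min))
  q60 <- 1 - frac_60 / (1 - d60)
  q_hl <- q60 / (1 - exp(-k_qind * hl_min))
  d90 <- d60 * exp(-k_repair * rec_min)
  q90 <- 1 - frac_90 / (1 - d90)
  decay <- exp(-k_qrelax * rec_min)
  q_res <- (q90 - q60 * decay) / (1 - decay)
  if (q60 < 0 || q60 >= 1 || q_res < -1e-9) {
    abort(paste0(
      "Endpoint fractions are not attainable with these rate constants ",
      "(implied quenching outside [0, 1)); adjust `k_repair`."
    ))
  }
  list(q_hl = q_hl, q_res = max(q_res, 0), d60 = d60, d90 = d90, q60 = q60)
}

#' The packaged diatom cpftsy-vs-WT study scenario
#'
#' Truth values reproduce the published characterization of diatom mutants
#' lacking the chloroplast SRP receptor: exponential-phase division rates per
#' line under low and medium light; high-light (± lincomycin) Fv/Fm endpoint
#' fractions of 30% (translation-blocked arms), 52%/40% (WT/mutant at 60 min)
#' and 96%/70% (WT/mutant after 30 min recovery); a medium-light
#' electron-flow reduction of 50% in the mutant; and anchored proteomics
#' effects for the PsaC and APE1-like proteins.
#'
#' @param seed Default seed stored in the scenario.
#' @return A validated `sim_scenario`.
#' @export
scenario_cpftsy_study <- function(seed = 1L) {
  k_damage <- -log(0.30) / 60            # from the 30% translation-blocked endpoint
  wt <- solve_quenching_params(k_damage, k_repair = 0.065, frac_60 = 0.52, frac_90 = 0.96)
  mut <- solve_quenching_params(k_damage, k_repair = 0.040, frac_60 = 0.40, frac_90 = 0.70)
  anchors <- tibble::tibble(
    protein_id = c("A0T0L2", "B7G7J9", "A0T0B7"),
    label = c("PsaC", "APE1-homolog", "PetD"),
    effect_mutant1 = c(-1.35, 1.16, -0.39),
    effect_mutant2 = c(-1.96, 1.58, -0.53),
    peptides = c(4L, 5L, 3L)
  )
  sim_scenario(
    name = "cpftsy_study",
    seed = seed,
    fluor = list(npq_max = 1.2, k_ind = 0.01, f_fast = 0.8, k_rel = 0.015),
    rlc = list(alpha = 0.55, retr_max = 60, fv_fm = 0.65),
    growth = list(
      rates = tibble::tibble(
        line = rep(c("WT", "cpftsy.1-25.7", "cpftsy.2-2.8", "cpftsy.2-4.8"), each = 2),
        light = rep(c("LL", "ML"), 4),
        mu = c(1.42, 1.95, 0.87, 1.51, 0.64, 0.67, 0.96, 1.27)
      )
    ),
    ecs = list(
      lines = tibble::tibble(
        line = c("WT", "cpftsy"),
        psii_psi_ratio = c(1.2, 0.8),
        j_flow = c(150, 75)
      )
    ),
    photoinhibition = list(
      lines = tibble::tibble(
        line = c("WT", "cpftsy"),
        n_rep = c(3L, 9L),
        k_damage = k_damage,
        k_repair = c(0.065, 0.040),
        k_qrelax = 0.15,
        q_hl = c(wt$q_hl, mut$q_hl),
        q_res = c(wt$q_res, mut$q_res)
      )
    ),
    proteomics = list(
      groups = c("WT", "cpftsy.1-25.7", "cpftsy.2-4.8"),
      anchors = anchors
    )
  )
}

# Small, fast scenario for end-to-end pipeline runs and examples.
scenario_demo_small <- function(seed = 1L) {
  sc <- scenario_cpftsy_study(seed)
  sc$name <- "demo_small"
  sc$proteomics$n_prot <- 200
  sc
}

scenario_registry <- function() {
  list(
    cpftsy_study = scenario_cpftsy_study,
    demo_small = scenario_demo_small
  )
}

#' Load a packaged simulation scenario by name
#'
#' @param name One of the packaged scenario names; `"cpftsy_study"` is the
#'   fully parameterized study scenario, `"demo_small"` a faster variant with
#'   a reduced proteome for examples.
#' @param seed Optional seed overriding the scenario default.
#' @return A validated `sim_scenario`.
#' @export
load_scenario <- function(name, seed = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("Unknown scenario '%s'. Available scenarios: %s.",
                  name, paste(names(reg), collapse = ", ")))
  }
  sc <- if (is.null(seed)) reg[[name]]() else reg[[name]](seed = as.integer(seed))
  sc
}

# Scenario (de)serialization as structured text. Tables inside blocks are
# stored as column lists and restored to tibbles.

scenario_table_fields <- list(
  ecs = "lines", pigments = "means", growth = "rates",
  photoinhibition = "lines", proteomics = "anchors"
)

#' Write a scenario to a YAML file
#' @param sc A `sim_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  validate_scenario(sc)
  obj <- unclass(sc)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a scenario from a YAML file
#' @param path File written by [write_scenario()].
#' @return A validated `sim_scenario`.
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  for (blk in names(scenario_table_fields)) {
    fld <- scenario_table_fields[[blk]]
    if (!is.null(obj[[blk]][[fld]])) {
      obj[[blk]][[fld]] <- tibble::as_tibble(as.data.frame(obj[[blk]][[fld]]))
    }
  }
  obj$seed <- as.integer(obj$seed)
  if (!is.null(obj$growth$capacity) && is.character(obj$growth$capacity)) {
    obj$growth$capacity <- as.numeric(obj$growth$capacity)
  }
  class(obj) <- "sim_scenario"
  validate_scenario(obj)
}
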