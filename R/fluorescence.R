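# PAM chlorophyll-fluorescence parameters, NPQ time courses and rapid
# light-curve fitting.

#' PAM fluorescence parameters
#'
#' Standard saturating-pulse definitions: maximum quantum yield
#' `Fv/Fm = (Fm - F0)/Fm`, effective PSII quantum yield
#' `PhiPSII = (Fm' - F')/Fm'` and Stern-Volmer non-photochemical quenching
#' `NPQ = Fm/Fm' - 1`.
#'
#' Physiologically impossible inputs (`F0 > Fm` or `F' > Fm'`, as can happen
#' with instrument noise) are not clamped: the affected values are returned
#' as computed and flagged in the `valid` column.
#'
#' @param f0 Dark-adapted minimal fluorescence (a.u.).
#' @param fm Dark-adapted maximal fluorescence (a.u.); must be positive.
#' @param f_prime Steady-state fluorescence under actinic light.
#' @param fm_prime Maximal fluorescence under a saturating pulse in light;
#'   must be positive.
#' @return One-row tibble with `fv_fm`, `phi_psii`, `npq`, `valid`.
#' @examples
#' pam_parameters(150, 600, 300, 450)
#' @export
pam_parameters <- function(f0, fm, f_prime, fm_prime) {
  if (any(fm <= 0) || any(fm_prime <= 0)) {
    abort("`fm` and `fm_prime` must be positive.")
  }
  valid <- f0 <= fm & f_prime <= fm_prime & f0 > 0 & f_prime > 0
  if (any(!valid)) {
    warn("Some pulses violate F <= Fm; results flagged in `valid`.")
  }
  tibble::tibble(
    fv_fm = (fm - f0) / fm,
    phi_psii = (fm_prime - f_prime) / fm_prime,
    npq = fm / fm_prime - 1,
    valid = valid
  )
}

#' NPQ induction/relaxation time course from a pulse trace
#'
#' Computes Stern-Volmer NPQ for every saturating pulse against the
#' dark-adapted `Fm` (taken as the mean `fm_prime` over the dark phase unless
#' supplied), keeping the phase partition. The summary attribute reports NPQ
#' at the end of induction and at the end of relaxation, the comparison
#' points used when contrasting lines.
#'
#' @param trace Tibble with columns `time_s`, `phase`
#'   (`dark`/`induction`/`relaxation`), `fm_prime` (and optionally `f`), as
#'   produced by [gen_npq_trace()] or read from a fluorescence CSV.
#' @param fm Dark-adapted maximal fluorescence; defaults to the dark-phase mean.
#' @return Tibble (`time_s`, `phase`, `npq`) with attribute `summary`
#'   (`npq_end_induction`, `npq_end_relaxation`, `fm_dark`).
#' @export
npq_timecourse <- function(trace, fm = NULL) {
  req <- c("time_s", "phase", "fm_prime")
  if (!all(req %in% names(trace))) {
    abort(paste0("`trace` must have columns: ", paste(req, collapse = ", "), "."))
  }
  if (is.null(fm)) {
    dark <- trace$fm_prime[trace$phase == "dark"]
    if (length(dark) == 0) {
      abort("No dark-phase reference pulse present and `fm` not supplied.")
    }
    fm <- mean(dark)
  }
  if (fm <= 0) abort("Dark Fm must be positive.")
  out <- tibble::tibble(time_s = trace$time_s, phase = trace$phase,
                        npq = fm / trace$fm_prime - 1) %>%
    dplyr::arrange(.data$time_s)
  ind <- dplyr::filter(out, .data$phase == "induction")
  rel <- dplyr::filter(out, .data$phase == "relaxation")
  attr(out, "summary") <- list(
    fm_dark = fm,
    npq_end_induction = if (nrow(ind)) ind$npq[which.max(ind$time_s)] else NA_real_,
    npq_end_relaxation = if (nrow(rel)) rel$npq[which.max(rel$time_s)] else NA_real_
  )
  out
}

#' Relative electron transport rate
#'
#' `rETR = PhiPSII * E`. No absorptance or PSII-fraction factor is applied:
#' the rate is *relative*, and any constant factor cancels in Ek and in
#' mutant-to-wild-type comparisons.
#'
#' @param phi_psii Effective PSII quantum yield in `[0, 1]`.
#' @param e Irradiance (umol photons m^-2 s^-1), `>= 0`.
#' @return Numeric vector of rETR values.
#' @export
relative_etr <- function(phi_psii, e) {
  if (any(e < 0)) abort("Irradiance must be >= 0.")
  if (any(phi_psii < 0 | phi_psii > 1, na.rm = TRUE)) {
    abort("`phi_psii` must lie in [0, 1].")
  }
  phi_psii * e
}

#' Fit a rapid light curve (Webb model)
#'
#' Converts yields to rETR via [relative_etr()] and fits the saturating
#' exponential `rETR(E) = rETRmax (1 - exp(-alpha E / rETRmax))` by
#' unweighted nonlinear least squares. The light-saturation index is stored
#' as the exact quotient `Ek = rETRmax / alpha`. Initialization: `alpha`
#' from the regression slope of the three lowest irradiances, `rETRmax` from
#' the maximum observed rETR. If the fitted `Ek` exceeds the largest
#' measured irradiance the curve never saturated and the fit is flagged
#' `unsaturated` (the asymptote is then an extrapolation).
#'
#' @param points Tibble with columns `e` and `phi_psii` (at least 5 distinct
#'   irradiances).
#' @return A `light_curve_fit` object: list with `alpha`, `retr_max`, `ek`,
#'   `residual_rms`, `n_points`, `converged`, `unsaturated`, `retr_raw_max`
#'   and the fitted model.
#' @export
fit_light_curve <- function(points) {
  if (!all(c("e", "phi_psii") %in% names(points))) {
    abort("`points` must have columns `e` and `phi_psii`.")
  }
  points <- dplyr::filter(points, !is.na(.data$e), !is.na(.data$phi_psii))
  if (length(unique(points$e)) < 5) {
    abort("At least 5 points with distinct irradiance are required.")
  }
  df <- points %>%
    dplyr::mutate(retr = relative_etr(.data$phi_psii, .data$e)) %>%
    dplyr::arrange(.data$e)
  low <- head(df, 3)
  alpha0 <- unname(coef(lm(retr ~ 0 + e, data = low))[1])
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- max(df$retr) / max(df$e)
  retr_max0 <- max(df$retr)
  if (retr_max0 <= 0) abort("All rETR values are zero; nothing to fit.")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      retr ~ rmax * (1 - exp(-alpha * e / rmax)),
      data = df,
      start = list(alpha = alpha0, rmax = retr_max0),
      lower = c(1e-8, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(alpha = alpha0, retr_max = retr_max0,
                ek = retr_max0 / alpha0, residual_rms = NA_real_,
                n_points = nrow(df), converged = FALSE,
                unsaturated = NA, retr_raw_max = max(df$retr), fit = NULL)
    class(out) <- "light_curve_fit"
    return(out)
  }
  cf <- coef(fit)
  ek <- unname(cf["rmax"] / cf["alpha"])
  unsaturated <- max(df$e) < ek
  if (unsaturated) {
    warn("Curve did not reach saturation (max E < Ek); rETRmax is extrapolated.")
  }
  out <- list(
    alpha = unname(cf["alpha"]), retr_max = unname(cf["rmax"]), ek = ek,
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    n_points = nrow(df), converged = TRUE, unsaturated = unsaturated,
    retr_raw_max = max(df$retr), fit = fit
  )
  class(out) <- "light_curve_fit"
  out
}

#' @export
print.light_curve_fit <- function(x, ...) {
  cat("<light_curve_fit>\n")
  cat(sprintf("  alpha    %.4g rETR per (umol m^-2 s^-1)\n", x$alpha))
  cat(sprintf("  rETRmax  %.4g (raw max %.4g)\n", x$retr_max, x$retr_raw_max))
  cat(sprintf("  Ek       %.4g umol m^-2 s^-1\n", x$ek))
  cat(sprintf("  %d points, converged: %s%s\n", x$n_points, x$converged,
              if (isTRUE(x$unsaturated)) ", UNSATURATED" else ""))
  invisible(x)
}

#' @rdname fit_light_curve
#' @param x A `light_curve_fit`.
#' @param ... Unused.
#' @export
tidy.light_curve_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "retr_max", "ek"),
    estimate = c(x$alpha, x$retr_max, x$ek)
  )
}

#' @rdname fit_light_curve
#' @export
glance.light_curve_fit <- function(x, ...) {
  tibble::tibble(
    residual_rms = x$residual_rms, n_points = x$n_points,
    converged = x$converged, unsaturated = x$unsaturated,
    retr_raw_max = x$retr_raw_max
  )
}

#' @rdname fit_light_curve
#' @param object A `light_curve_fit`.
#' @export
autoplot.light_curve_fit <- function(object, ...) {
  df <- if (!is.null(object$fit)) {
    eval(object$fit$data, envir = environment(stats::formula(object$fit)))
  } else NULL
  grid <- tibble::tibble(e = seq(0, max(object$ek * 2, 1000), length.out = 200))
  grid$retr <- webb_retr(grid$e, object$alpha, object$retr_max)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$e, y = .data$retr)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ek, linetype = "dashed") +
    ggplot2::labs(x = "Irradiance (umol photons m^-2 s^-1)", y = "rETR",
                  title = sprintf("Webb fit: alpha = %.3g, rETRmax = %.3g, Ek = %.3g",
                                  object$alpha, object$retr_max, object$ek))
  p
}

#' Plot an NPQ induction/relaxation series
#' @param npq Tibble from [npq_timecourse()].
#' @return A ggplot object.
#' @export
plot_npq_timecourse <- function(npq) {
  ggplot2::ggplot(npq, ggplot2::aes(x = .data$time_s / 60, y = .data$npq,
                                    colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "NPQ (Fm/Fm' - 1)", colour = "Phase")
}
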