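# Hair-bundle stiffness, creep, and the gating-spring / pivot decomposition.

# Locate the step window from annotations or the command channel.
step_window <- function(trace) {
  a <- trace$annotations
  if (!is.null(a$step_on) && !is.null(a$step_off))
    return(c(on = a$step_on, off = a$step_off))
  cmd <- trace$command
  if (is.null(cmd)) stop_input("no step annotation and no command channel")
  thr <- max(abs(cmd)) / 2
  on_idx <- which(abs(cmd) > thr)
  if (!length(on_idx)) stop_input("no step detected in the command channel")
  c(on = (min(on_idx) - 1) * trace$dt, off = max(on_idx) * trace$dt)
}

# Displacement during the measurement window, baseline-corrected.
step_displacement <- function(trace, window = c(0.005, 0.010)) {
  w <- step_window(trace)
  base <- window_mean(trace$position, trace$dt, 0, w["on"])
  window_mean(trace$position, trace$dt, w["on"] + window[1], w["on"] + window[2]) - base
}

#' Estimate hair-bundle stiffness from a set of force-step responses
#'
#' For each trace, the bundle displacement X is the mean position over the
#' 5-10 ms window after step onset minus the pre-step baseline; the stiffness
#' K_HB is the least-squares slope of force against displacement (pN/nm =
#' mN/m). The fit includes an intercept (reported, expected ~0) to absorb
#' baseline offsets, and the R-squared of the relation is reported as a
#' linearity diagnostic.
#'
#' @param trace_set list of [trace_recording()]s, one per force level (at
#'   least 3). Command channels in volts are converted through `calib`;
#'   command channels already in pN (`command_units = "pN"`) are used as is.
#' @param calib optional [jet_calibration()]; required when commands are in
#'   volts.
#' @param window measurement window after step onset (s).
#' @return A list with `k_hb` (mN/m), the force-displacement table `fd`,
#'   `intercept_pn`, and `r_squared`.
#' @export
estimate_stiffness <- function(trace_set, calib = NULL, window = c(0.005, 0.010)) {
  if (length(trace_set) < 3) stop_input("need at least 3 force levels")
  fd <- do.call(rbind, lapply(trace_set, function(tr) {
    w <- step_window(tr)
    cmd_on <- window_mean(tr$command, tr$dt, w["on"] + window[1], w["on"] + window[2])
    f <- if (identical(tr$command_units, "pN")) cmd_on else {
      if (is.null(calib)) stop_input("command channel in volts requires a `calib`")
      effective_force(cmd_on, calib)
    }
    x <- step_displacement(tr, window)
    data.frame(force_pn = f, x_nm = x)
  }))
  if (any(abs(fd$x_nm) > 150))
    warning("displacement beyond the +/-150 nm linear range of the displacement monitor")
  fit <- stats::lm(force_pn ~ x_nm, data = fd)
  list(k_hb = unname(stats::coef(fit)[2]),
       fd = fd,
       intercept_pn = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Mechanical creep over a force step
#'
#' The fractional increase of the deflection over the step: (X_late -
#' X_early) / X_early, with X_early the mean over the 5-10 ms window after
#' onset and X_late the mean over the final 10% of the step.
#'
#' @param trace a single force-step [trace_recording()] with a step of at
#'   least 100 ms.
#' @param window early measurement window after onset (s).
#' @param noise_floor_nm smallest |X_early| (nm) for which the ratio is
#'   defined.
#' @return Creep as a dimensionless fraction (0.22 = 22%).
#' @export
creep_fraction <- function(trace, window = c(0.005, 0.010), noise_floor_nm = 1) {
  w <- step_window(trace)
  dur <- w["off"] - w["on"]
  if (dur < 0.1 - 1e-9) stop_input("creep requires a step of at least 100 ms")
  base <- window_mean(trace$position, trace$dt, 0, w["on"])
  x_early <- window_mean(trace$position, trace$dt, w["on"] + window[1], w["on"] + window[2]) - base
  x_late <- window_mean(trace$position, trace$dt, w["off"] - 0.1 * dur, w["off"]) - base
  if (abs(x_early) < noise_floor_nm)
    stop_input("early-step deflection below the noise floor; creep undefined")
  unname((x_late - x_early) / x_early)
}

#' Gating-spring fraction from amplitudes before and after disruption
#'
#' Disrupting the tip links removes the gating-spring contribution, so the
#' response to the same stimulus grows: r = 1 - amp_intact / amp_disrupted
#' is the fraction of hair-bundle stiffness contributed by the gating
#' springs. If the disrupted response is smaller (measurement noise can
#' invert the ratio) r is clamped to 0 with a warning.
#'
#' @param amp_intact,amp_disrupted response amplitudes (nm) to the same
#'   stimulus before and after tip-link disruption.
#' @return r in \[0, 1).
#' @export
gating_fraction <- function(amp_intact, amp_disrupted) {
  if (amp_disrupted < amp_intact) {
    warning("disrupted-state response smaller than intact: negative stiffness change; r clamped to 0")
    return(0)
  }
  1 - amp_intact / amp_disrupted
}

#' Decompose hair-bundle stiffness into gating-spring and pivot parts
#'
#' K_GS = r K_HB and K_SP = (1 - r) K_HB partition the bundle stiffness
#' exactly. Normalizing by morphology gives the single-element values:
#' kappa = K_SP h^2 / N_SP (rotational stiffness of one stereociliary
#' pivot) and k_GS = K_GS / (gamma^2 N_TL) (stiffness of one gating spring
#' along the tip-link axis). With K in mN/m, h in um, the numeric value of
#' K_SP h^2 / N_SP is directly in fN m/rad.
#'
#' @param k_hb hair-bundle stiffness (mN/m).
#' @param r gating-spring fraction in \[0, 1).
#' @param morph a [morphology()] (or any list with `h_um`, `n_sp`, `gamma`).
#' @param n_tl number of intact tip links (>= 1 for `k_gs_single`).
#' @return A list of class `stiffness_decomposition` with `k_hb`, `r`,
#'   `k_gs_bundle`, `k_sp_bundle` (mN/m), `kappa` (fN m/rad) and
#'   `k_gs_single` (mN/m).
#' @export
decompose_stiffness <- function(k_hb, r, morph, n_tl) {
  check_positive(k_hb, "k_hb")
  if (r < 0 || r >= 1) stop_input("`r` must be in [0, 1)")
  if (n_tl < 1 && r > 0) stop_input("k_GS per link undefined for n_tl < 1")
  k_gs <- r * k_hb
  k_sp <- (1 - r) * k_hb
  structure(
    list(k_hb = k_hb, r = r,
         k_gs_bundle = k_gs, k_sp_bundle = k_sp,
         kappa = k_sp * morph$h_um^2 / morph$n_sp,
         k_gs_single = if (r == 0) 0 else k_gs / (morph$gamma^2 * n_tl)),
    class = "stiffness_decomposition")
}

#' @export
print.stiffness_decomposition <- function(x, ...) {
  cat(sprintf("<stiffness_decomposition> K_HB=%.3g mN/m, r=%.3f | K_GS=%.3g, K_SP=%.3g mN/m | kappa=%.3g fN m/rad, k_GS=%.3g mN/m\n",
              x$k_hb, x$r, x$k_gs_bundle, x$k_sp_bundle, x$kappa, x$k_gs_single))
  invisible(x)
}
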