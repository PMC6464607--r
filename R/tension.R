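# Tip-link tension from iontophoresis traces: feature extraction and statics.

#' Extract biphasic features from an iontophoresis trace
#'
#' The response to a calcium-chelator step is biphasic: a negative excursion
#' (increased gating-spring tension) to an extremum DX_Ca, then - if the tip
#' links disrupt - a relaxation to a positive steady offset DX_R. The trace
#' is low-pass filtered by a 5-ms moving average; the extremum is the mean of
#' the smoothed trace within +/-5 ms of its minimum between step onset and
#' the polarity reversal (detected as the zero-crossing of the smoothed
#' derivative after the minimum, or taken from the annotation when present);
#' DX_R is the mean over the final 20% of the record minus the pre-step
#' baseline. Disruption is inferred from the companion current channel
#' (transduction abolished at the end of the record).
#'
#' @param trace a [trace_recording()] with a pre-step baseline of at least
#'   200 ms and a `step_on` annotation (or a command channel).
#' @param smooth_s moving-average width (s).
#' @param noise_floor_nm threshold below which the negative phase is deemed
#'   absent (DX_Ca = 0 with a warning).
#' @param drift_tol_nm baseline drift (first vs second half of the pre-step
#'   segment) beyond which a quality flag is set.
#' @return A list of class `ionto_features`: `dx_ca` (nm, <= 0), `dx_r`
#'   (nm), `t_reversal` (s), `disrupted`, `quality_flag`.
#' @export
extract_features <- function(trace, smooth_s = 0.005, noise_floor_nm = 1,
                             drift_tol_nm = 5) {
  a <- trace$annotations
  t0 <- if (!is.null(a$step_on)) a$step_on else step_window(trace)["on"]
  if (t0 < 0.2) stop_input("pre-step baseline shorter than 200 ms")
  dt <- trace$dt
  x <- trace$position
  n <- length(x)
  base <- window_mean(x, dt, 0, t0)
  drift <- abs(window_mean(x, dt, t0 / 2, t0) - window_mean(x, dt, 0, t0 / 2))
  sm <- moving_average(x - base, dt, smooth_s)
  tt <- (seq_len(n) - 1) * dt

  # negative extremum between onset and reversal
  in_step <- tt >= t0
  i_min <- which(in_step)[which.min(sm[in_step])]
  # polarity reversal: annotated, else smoothed-derivative zero-crossing
  if (!is.null(a$reversal)) {
    t_rev <- a$reversal
  } else {
    d <- diff(sm)
    after <- seq(from = i_min, to = n - 1)
    pos <- after[d[after] > 0]
    t_rev <- if (length(pos)) tt[min(pos)] else tt[n]
  }
  lo <- max(t0, tt[i_min] - smooth_s)
  hi <- min(t_rev, tt[i_min] + smooth_s)
  dx_ca <- window_mean(sm, dt, lo, hi)
  if (dx_ca > -noise_floor_nm) {
    warning("no negative phase above the noise floor; DX_Ca set to 0")
    dx_ca <- 0
  }
  dx_r <- window_mean(x, dt, 0.8 * n * dt, n * dt) - base

  disrupted <- NA
  if (!is.null(trace$current)) {
    cur <- trace$current
    early <- window_mean(abs(cur), dt, 0, t0)
    late <- window_mean(abs(cur), dt, 0.9 * n * dt, n * dt)
    disrupted <- late < 0.2 * early
  }
  structure(list(dx_ca = unname(dx_ca), dx_r = unname(dx_r),
                 t_reversal = unname(t_rev), disrupted = disrupted,
                 quality_flag = drift > drift_tol_nm),
            class = "ionto_features")
}

#' @export
print.ionto_features <- function(x, ...) {
  cat(sprintf("<ionto_features> DX_Ca=%.1f nm, DX_R=%.1f nm, reversal at %.3f s, disrupted=%s%s\n",
              x$dx_ca, x$dx_r, x$t_reversal, x$disrupted,
              if (isTRUE(x$quality_flag)) " [baseline drift]" else ""))
  invisible(x)
}

#' Resting tension in the hair bundle and in a single tip link
#'
#' The positive offset DX_R after tip-link disruption reports the released
#' resting tension: T_R = K_SP * DX_R (mN/m x nm = pN) along the bundle's
#' axis of bilateral symmetry, and t_R = T_R / (gamma N_TL) along the
#' oblique axis of one tip link.
#'
#' @param k_sp_bundle pivot stiffness K_SP (mN/m).
#' @param dx_r steady offset after disruption (nm).
#' @param gamma projection factor.
#' @param n_tl number of intact tip links (>= 1).
#' @return List with `t_bundle_rest` (pN) and `t_link_rest` (pN).
#' @export
tension_at_rest <- function(k_sp_bundle, dx_r, gamma, n_tl) {
  check_positive(k_sp_bundle, "k_sp_bundle")
  if (n_tl < 1) stop_input("single-link tension undefined for n_tl < 1")
  t_r <- k_sp_bundle * dx_r
  list(t_bundle_rest = t_r, t_link_rest = t_r / (gamma * n_tl))
}

#' Maximal tension increase under calcium chelation
#'
#' The negative excursion DX_Ca before disruption reports a tension
#' increase DT = -K_SP * DX_Ca >= 0; the maximal tension a single tip link
#' sustains just before disruption is t_max = t_R + DT / (gamma N_TL).
#'
#' @param k_sp_bundle pivot stiffness K_SP (mN/m).
#' @param dx_ca negative-phase extremum (nm), <= 0.
#' @param t_r_link resting single-link tension t_R (pN).
#' @param gamma projection factor.
#' @param n_tl number of intact tip links (>= 1).
#' @return List with `dt_bundle` (pN, >= 0) and `t_link_max` (pN).
#' @export
tension_under_chelation <- function(k_sp_bundle, dx_ca, t_r_link, gamma, n_tl) {
  check_positive(k_sp_bundle, "k_sp_bundle")
  if (dx_ca > 0) stop_input("`dx_ca` must be non-positive")
  if (n_tl < 1) stop_input("single-link tension undefined for n_tl < 1")
  dt_b <- -k_sp_bundle * dx_ca
  list(dt_bundle = dt_b, t_link_max = t_r_link + dt_b / (gamma * n_tl))
}
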