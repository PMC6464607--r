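# Synthetic-data generator: emulates every raw input the pipeline consumes,
# with ground truth recorded, so all downstream stages are testable by
# parameter recovery.

#' Generate a synthetic cohort of hair cells with ground truth
#'
#' Draws per-cell ground-truth parameters from the per-location priors
#' (truncated normals whose realized means match the prior means; see
#' [rnorm_trunc()]). Each cell gets its own random stream derived from the
#' master seed, so cohorts are reproducible under partial re-runs.
#'
#' @param location_table per-location priors, defaults to
#'   [default_location_priors()].
#' @param n_per_group optional vector overriding `n_cells` per row.
#' @param seed master integer seed.
#' @param noise_sd_pos,noise_sd_cur measurement noise SDs (nm, pA).
#' @return A data.frame, one row per cell, carrying morphology and the
#'   `*_true` ground-truth parameters.
#' @export
gen_cohort <- function(location_table = default_location_priors(),
                       n_per_group = NULL, seed = 1,
                       noise_sd_pos = 2, noise_sd_cur = 10) {
  if (is.null(n_per_group)) n_per_group <- location_table$n_cells
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, nrow(location_table))
  if (any(n_per_group < 1)) stop_input("`n_per_group` must be at least 1")
  if (any(location_table$k_hb_sd < 0) || any(location_table$r_sd < 0))
    stop_input("negative prior SD in location table")

  rows <- vector("list", nrow(location_table))
  idx <- 0L
  for (g in seq_len(nrow(location_table))) {
    loc <- location_table[g, ]
    n <- n_per_group[g]
    cells <- with_stream_seed(seed, g, {
      data.frame(
        cell_class = loc$cell_class, cf_khz = loc$cf_khz,
        h_um = loc$h_um, w_um = loc$w_um, n_sp = loc$n_sp, gamma = loc$gamma,
        k_hb_true = rnorm_trunc(n, loc$k_hb_mean, loc$k_hb_sd, lower = 0.05),
        r_true = rnorm_trunc(n, loc$r_mean, loc$r_sd, lower = 0, upper = 0.95),
        creep_frac_true = rnorm_trunc(n, loc$creep_mean, loc$creep_sd, lower = 0),
        dx_r_true = rnorm_trunc(n, loc$dx_r_mean, loc$dx_r_sd, lower = 0),
        dx_ca_true = rnorm_trunc(n, loc$dx_ca_mean, loc$dx_ca_sd, upper = 0),
        n_tl_true = rnorm_trunc(n, loc$n_tl,
                                if (is.null(loc$n_tl_sd)) 0.10 * loc$n_tl else loc$n_tl_sd,
                                lower = 1),
        stringsAsFactors = FALSE)
    })
    cc <- current_constants()
    cells$i_max_true <- if (loc$cell_class == "IHC") {
      cells$n_tl_true * cc$i1_ihc
    } else {
      # apical OHC locations sit below the 4-kHz anchor; extrapolation there
      # is the documented convention, so the warning is silenced here
      cells$n_tl_true * cc$channels_per_link *
        suppressWarnings(unitary_current_ohc(loc$cf_khz))
    }
    cells$cell_id <- sprintf("%s%02gk_%03d", loc$cell_class, loc$cf_khz, seq_len(n))
    cells$cell_seed <- (seed * 1000003 + 7919 * g + seq_len(n)) %% 2147483647
    idx <- idx + n
    rows[[g]] <- cells
  }
  out <- do.call(rbind, rows)
  out$noise_sd_pos <- noise_sd_pos
  out$noise_sd_cur <- noise_sd_cur
  rownames(out) <- NULL
  out
}

# Creep ramp: zero until `onset`, then rises with time constant tau,
# normalized to reach exactly 1 at t = step_dur. The slow phase starts just
# past the 5-10 ms stiffness window so the early-window amplitude isolates
# the elastic response, and the end-of-step deflection exceeds the early one
# by exactly creep_frac.
creep_ramp <- function(t, onset, tau, step_dur) {
  norm <- 1 - exp(-(step_dur - onset) / tau)
  ifelse(t <= onset, 0, (1 - exp(-(t - onset) / tau)) / norm)
}

#' Simulate force-step responses of one hair bundle
#'
#' For each force F the bundle deflects elastically by F/K_HB within the
#' step, then creeps in the direction of the stimulus: the end-of-step
#' deflection exceeds the early deflection by `creep_frac_true`. When
#' `disrupted`, the stiffness drops to the pivot contribution
#' (1 - r) * K_HB and the creep is strongly reduced (2% of intact).
#'
#' @param gt one row of a [gen_cohort()] data.frame (ground truth).
#' @param forces effective forces (pN), one trace per force.
#' @param step_dur step duration (s), 100 ms by default.
#' @param dt sampling interval (s).
#' @param pre,post baseline durations before/after the step (s).
#' @param disrupted simulate the tip-link-disrupted state.
#' @param noise_sd position noise SD (nm); defaults to the cohort value.
#' @return A list of [trace_recording()]s, one per force; the command channel
#'   holds the effective force in pN (`command_units = "pN"`).
#' @export
gen_force_step_response <- function(gt, forces, step_dur = 0.1, dt = 1e-4,
                                    pre = 0.02, post = 0.02, disrupted = FALSE,
                                    noise_sd = gt$noise_sd_pos) {
  check_positive(step_dur, "step_dur")
  if (is.null(noise_sd)) noise_sd <- 0
  k <- if (disrupted) (1 - gt$r_true) * gt$k_hb_true else gt$k_hb_true
  creep <- if (disrupted) 0.02 * gt$creep_frac_true else gt$creep_frac_true
  st <- default_settings()
  n_pre <- round(pre / dt); n_step <- round(step_dur / dt); n_post <- round(post / dt)
  t_step <- (seq_len(n_step) - 0.5) * dt
  ramp <- creep_ramp(t_step, st$creep_onset, st$tau_creep, step_dur)
  traces <- lapply(seq_along(forces), function(i) {
    f <- forces[i]
    x <- c(rep(0, n_pre), (f / k) * (1 + creep * ramp), rep(0, n_post))
    cmd <- c(rep(0, n_pre), rep(f, n_step), rep(0, n_post))
    noise <- with_stream_seed(gt$cell_seed, 100 + i + 1000 * disrupted,
                              stats::rnorm(length(x), 0, noise_sd))
    trace_recording(dt, position = x + noise, command = cmd,
                    annotations = list(step_on = n_pre * dt,
                                       step_off = (n_pre + n_step) * dt),
                    command_units = "pN")
  })
  traces
}

#' Simulate a biphasic iontophoresis response
#'
#' An iontophoretic step of a calcium chelator first pulls the bundle in the
#' negative direction (increased gating-spring tension) toward
#' `dx_ca_true`, where it dwells briefly; at the polarity reversal the tip
#' links begin to disrupt and the bundle relaxes to the positive steady
#' offset `dx_r_true`. If `disrupted = FALSE` (high-Ca regime) the movement
#' is reversible and the bundle returns to baseline after the step. The
#' concurrent current channel shows the inward current rising as channels
#' open, then (if disrupting) decaying to the all-closed level.
#'
#' @param gt one row of a [gen_cohort()] data.frame.
#' @param hold_na,step_na holding and step iontophoretic currents (nA).
#' @param pre,step_dur,post durations (s); `pre` must be at least 0.2 s.
#' @param t_rev time from step onset to polarity reversal (s).
#' @param tau_ca,tau_r time constants of the negative and relaxation phases
#'   (s); generator conventions, not measured values.
#' @param dt sampling interval (s).
#' @param disrupted whether the step disrupts the tip links.
#' @param noise_sd position noise SD (nm).
#' @return A [trace_recording()] with position, command (nA) and current
#'   channels and annotations `step_on`, `reversal`, `step_off`.
#' @export
gen_iontophoresis_trace <- function(gt, hold_na = 10, step_na = -100,
                                    pre = 0.3, step_dur = 0.5, post = 0.7,
                                    t_rev = 0.25, tau_ca = 0.05, tau_r = 0.1,
                                    dt = 2e-4, disrupted = TRUE,
                                    noise_sd = gt$noise_sd_pos) {
  if (pre < 0.2) stop_input("pre-step baseline must be at least 200 ms")
  if (is.null(noise_sd)) noise_sd <- 0
  n_pre <- round(pre / dt); n_step <- round(step_dur / dt); n_post <- round(post / dt)
  n <- n_pre + n_step + n_post
  t <- (seq_len(n) - 1) * dt
  t0 <- n_pre * dt            # step onset
  t1 <- t0 + n_step * dt      # step offset
  trev <- t0 + t_rev
  dwell <- 0.02               # plateau at the extremum before reversal

  dip <- function(tt) {
    # reaches dx_ca exactly at trev - dwell, holds until trev
    raw <- (1 - exp(-(tt - t0) / tau_ca)) / (1 - exp(-(t_rev - dwell) / tau_ca))
    pmin(raw, 1)
  }
  x <- numeric(n)
  neg <- t >= t0 & t < trev
  x[neg] <- gt$dx_ca_true * dip(t[neg])
  after <- t >= trev
  if (disrupted) {
    x[after] <- gt$dx_r_true + (gt$dx_ca_true - gt$dx_r_true) * exp(-(t[after] - trev) / tau_r)
  } else {
    # reversible: relax back toward baseline from the extremum; recovery
    # starts at the earlier of reversal and step offset
    tstart <- min(trev, t1)
    rel <- t >= tstart
    x[rel] <- gt$dx_ca_true * exp(-(t[rel] - tstart) / tau_r)
  }

  cmd <- c(rep(hold_na, n_pre), rep(hold_na + step_na, n_step), rep(hold_na, n_post))

  # current: resting open probability ~1/2; channels open during the dip,
  # then all close upon disruption (or reopen if reversible)
  p_open <- 0.5 + 0.5 * pmin(-x / max(1e-9, abs(gt$dx_ca_true)), 1)
  if (disrupted) p_open[t >= trev] <- 0.5 * exp(-(t[t >= trev] - trev) / tau_r)
  cur <- -gt$i_max_true * p_open

  noise <- with_stream_seed(gt$cell_seed, 7, list(
    pos = stats::rnorm(n, 0, noise_sd),
    cur = stats::rnorm(n, 0, if (is.null(gt$noise_sd_cur)) 0 else gt$noise_sd_cur)))
  trace_recording(dt, position = x + noise$pos, command = cmd,
                  current = cur + noise$cur,
                  annotations = list(step_on = t0, reversal = trev, step_off = t1),
                  command_units = "nA")
}

#' Generate bead-tracer velocity samples across the jet
#'
#' Samples lateral positions uniformly over +/- 2a and evaluates the jet
#' [velocity_profile()] plus Gaussian noise.
#'
#' @param vmax maximal axial speed (um/s).
#' @param a lateral extension of the velocity field (um).
#' @param x pipette-to-plane distance (um), stored as attribute.
#' @param n_beads number of samples.
#' @param noise_sd speed noise SD (um/s).
#' @param seed integer seed.
#' @return data.frame with columns `y_um`, `v_um_per_s`.
#' @export
gen_velocity_field <- function(vmax, a, x = 8, n_beads = 100, noise_sd = 0, seed = 1) {
  check_positive(vmax, "vmax"); check_positive(a, "a")
  with_stream_seed(seed, 11, {
    y <- stats::runif(n_beads, -2 * a, 2 * a)
    v <- velocity_profile(y, vmax, a) + stats::rnorm(n_beads, 0, noise_sd)
    structure(data.frame(y_um = y, v_um_per_s = v), x_um = x)
  })
}

#' Generate a fiber-calibration table
#'
#' Linear fiber deflection vs. voltage command: `dx = c_true * V / k_f`
#' plus noise (pN/V divided by mN/m gives nm/V).
#'
#' @param c_true true calibration constant (pN/V).
#' @param kf fiber stiffness (mN/m), within 0.2-2 mN/m.
#' @param commands voltage commands (V).
#' @param noise_sd deflection noise SD (nm).
#' @param seed integer seed.
#' @return data.frame with columns `v_command_V`, `dx_fiber_nm`.
#' @export
gen_fiber_calibration <- function(c_true, kf, commands, noise_sd = 0, seed = 1) {
  check_positive(c_true, "c_true")
  if (kf < 0.2 || kf > 2) warning("fiber stiffness outside the 0.2-2 mN/m fabrication range")
  with_stream_seed(seed, 13, {
    dx <- c_true * commands / kf + stats::rnorm(length(commands), 0, noise_sd)
    data.frame(v_command_V = commands, dx_fiber_nm = dx)
  })
}

#' Transduction current for a deflection series
#'
#' Two-state Boltzmann open probability (logistic in bundle deflection) with
#' midpoint `x0` and slope `s_nm`; with the default midpoint at the resting
#' position, the resting open probability is 1/2. The current saturates at
#' `i_max_true` for large positive deflections.
#'
#' @param gt one row of a [gen_cohort()] data.frame (uses `i_max_true`).
#' @param deflections bundle deflection series (nm).
#' @param x0 Boltzmann midpoint (nm).
#' @param s_nm Boltzmann slope (nm).
#' @param noise_sd current noise SD (pA).
#' @return Current series (pA).
#' @export
gen_current_response <- function(gt, deflections, x0 = 0,
                                 s_nm = default_settings()$boltzmann_slope_nm,
                                 noise_sd = 0) {
  check_positive(gt$i_max_true, "i_max_true")
  p <- 1 / (1 + exp(-(deflections - x0) / s_nm))
  cur <- gt$i_max_true * p
  if (noise_sd > 0)
    cur <- cur + with_stream_seed(gt$cell_seed, 17,
                                  stats::rnorm(length(cur), 0, noise_sd))
  cur
}
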