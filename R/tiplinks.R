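# Tip-link counts from saturating transduction currents.

#' Saturating transduction current from a current trace
#'
#' For a stimulus that drives the bundle through saturation in both
#' directions (e.g. a large sinusoid), the saturating current I_MAX is the
#' difference between the all-open plateau and the all-closed level. The
#' plateaus are estimated as the means of the samples within a small band of
#' the extremes of the smoothed current; saturation is verified by requiring
#' the plateau estimate to be insensitive (within `tol_frac`) to widening the
#' band, i.e. the response dwells at its extremes rather than merely peaking.
#'
#' @param current current series (pA) or a [trace_recording()] with a
#'   current channel.
#' @param dt sampling interval (s) when `current` is a bare series.
#' @param tol_frac saturation tolerance: maximal relative change of I_MAX
#'   between the narrow (2%) and wide (10%) plateau bands.
#' @param smooth_s moving-average width for plateau detection (s).
#' @return I_MAX (pA). Returns 0 with a `disrupted_links` attribute when the
#'   current is flat at zero.
#' @export
saturating_current <- function(current, dt = NULL, tol_frac = 0.03, smooth_s = 0.002) {
  if (inherits(current, "trace_recording")) {
    dt <- current$dt
    current <- current$current
  }
  if (is.null(current)) stop_input("no current channel")
  if (is.null(dt)) stop_input("`dt` required for a bare current series")
  sm <- moving_average(current, dt, smooth_s)
  rng <- range(sm)
  if (diff(rng) < 1e-6 || all(abs(sm) < 1e-6)) {
    out <- 0
    attr(out, "disrupted_links") <- TRUE
    return(out)
  }
  plateau <- function(frac) {
    band <- frac * diff(rng)
    top <- mean(sm[sm >= rng[2] - band])
    bot <- mean(sm[sm <= rng[1] + band])
    top - bot
  }
  i_narrow <- plateau(0.02)
  i_wide <- plateau(0.10)
  if (abs(i_wide - i_narrow) / i_narrow > tol_frac)
    stop_input("stimulus does not saturate the transduction current (plateau drift %.1f%%)",
               100 * abs(i_wide - i_narrow) / i_narrow)
  i_narrow
}

#' Number of intact tip links from the saturating current
#'
#' Inner hair cells: N_TL = I_MAX / I_1 with I_1 = 35.4 pA per transducing
#' stereocilium (one tip link per stereocilium). Outer hair cells: N_TL =
#' I_MAX / (2.36 i(CF)), where i(CF) is the unitary current interpolated
#' linearly in tonotopic distance through (4 kHz, 8.3 pA) and (14 kHz,
#' 12.1 pA), and 2.36 is the number of transduction channels per tip link.
#'
#' @param i_max saturating current (pA), non-negative.
#' @param cell_class "IHC" or "OHC".
#' @param cf_khz characteristic frequency (kHz); required for OHC.
#' @param n_sp optional stereocilia count; for IHC a warning is raised if
#'   the estimate exceeds it (at most one tip link per stereocilium).
#' @return N_TL, real-valued (attribute `"rounded"` holds the integer
#'   companion).
#' @export
count_tip_links <- function(i_max, cell_class, cf_khz = NULL, n_sp = NULL) {
  if (any(i_max < 0)) stop_input("`i_max` must be non-negative")
  cell_class <- match.arg(cell_class, c("IHC", "OHC"))
  cc <- current_constants()
  n <- if (cell_class == "IHC") {
    i_max / cc$i1_ihc
  } else {
    if (is.null(cf_khz)) stop_input("OHC tip-link count requires `cf_khz`")
    i_max / (cc$channels_per_link * unitary_current_ohc(cf_khz))
  }
  if (cell_class == "IHC" && !is.null(n_sp) && any(n > n_sp))
    warning("estimated tip links exceed the stereocilia count (one link per stereocilium)")
  attr(n, "rounded") <- round(n)
  n
}
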