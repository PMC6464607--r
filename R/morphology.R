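#' Tonotopic map anchors for the rat cochlea
#'
#' Characteristic frequencies (kHz) and fractional distances from the apex at
#' the four recording locations: (1 kHz, 5%), (2 kHz, 10%), (4 kHz, 20%),
#' (15 kHz, 50%).
#'
#' @return A data.frame with columns `cf_khz` and `distance`.
#' @export
tonotopic_anchors <- function() {
  data.frame(cf_khz = c(1, 2, 4, 15), distance = c(0.05, 0.10, 0.20, 0.50))
}

#' Map a characteristic frequency to a fractional tonotopic distance
#'
#' Interpolates the fractional distance from the cochlear apex against
#' log2(characteristic frequency), piecewise-linearly through the four anchor
#' locations; octave spacing is the natural scale of the map. Frequencies
#' beyond the anchor span are linearly extrapolated on the same scale and the
#' result is clamped to \[0, 1\].
#'
#' @param cf_khz characteristic frequency in kHz; must be positive. Values
#'   outside the rat hearing range (0.5-50 kHz) trigger a warning.
#' @return Fractional distance(s) from the apex in \[0, 1\].
#' @examples
#' cf_to_distance(c(1, 4, 15))
#' @export
cf_to_distance <- function(cf_khz) {
  if (any(!is.finite(cf_khz)) || any(cf_khz <= 0))
    stop_input("`cf_khz` must be positive")
  if (any(cf_khz < 0.5 | cf_khz > 50))
    warning("characteristic frequency outside the 0.5-50 kHz hearing range; extrapolating")
  an <- tonotopic_anchors()
  lx <- log2(an$cf_khz)
  x <- log2(cf_khz)
  d <- stats::approx(lx, an$distance, xout = pmin(pmax(x, min(lx)), max(lx)))$y
  # linear extrapolation with the terminal segment slopes
  lo <- x < min(lx)
  hi <- x > max(lx)
  if (any(lo)) {
    s <- (an$distance[2] - an$distance[1]) / (lx[2] - lx[1])
    d[lo] <- an$distance[1] + s * (x[lo] - lx[1])
  }
  if (any(hi)) {
    n <- nrow(an)
    s <- (an$distance[n] - an$distance[n - 1]) / (lx[n] - lx[n - 1])
    d[hi] <- an$distance[n] + s * (x[hi] - lx[n])
  }
  pmin(pmax(d, 0), 1)
}

#' Geometrical projection factor of the tip-link axis
#'
#' The projection factor gamma maps displacements and forces along the
#' bundle's horizontal axis of mechanosensitivity onto the oblique tip-link
#' axis. It scales inversely with bundle height: gamma = gamma0 * h0 / h,
#' capped at 1.
#'
#' @param h bundle height (um).
#' @param gamma0 reference projection factor, in (0, 1].
#' @param h0 reference bundle height (um) at which `gamma0` applies.
#' @return Projection factor(s) in (0, 1].
#' @export
projection_factor <- function(h, gamma0, h0) {
  check_positive(h, "h"); check_positive(h0, "h0")
  if (any(gamma0 <= 0) || any(gamma0 > 1)) stop_input("`gamma0` must be in (0, 1]")
  g <- gamma0 * h0 / h
  if (any(g > 1)) {
    warning("projection factor capped at 1")
    g <- pmin(g, 1)
  }
  g
}

#' Construct a per-cell morphology record
#'
#' @param cell_class "IHC" or "OHC".
#' @param cf_khz characteristic frequency (kHz).
#' @param h_um bundle height (um).
#' @param w_um bundle width (um).
#' @param n_sp number of stereocilia.
#' @param gamma projection factor in (0, 1].
#' @return An object of class `morphology` (a named list).
#' @export
morphology <- function(cell_class, cf_khz, h_um, w_um, n_sp, gamma) {
  cell_class <- match.arg(cell_class, c("IHC", "OHC"))
  check_positive(cf_khz, "cf_khz")
  check_positive(h_um, "h_um"); check_positive(w_um, "w_um")
  if (n_sp < 1) stop_input("`n_sp` must be at least 1")
  if (gamma <= 0 || gamma > 1) stop_input("`gamma` must be in (0, 1]")
  structure(
    list(cell_class = cell_class, cf_khz = cf_khz,
         distance = cf_to_distance(cf_khz),
         h_um = h_um, w_um = w_um, n_sp = n_sp, gamma = gamma),
    class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %s @ %g kHz (%.0f%% from apex): h=%.2f um, W=%.2f um, N_SP=%g, gamma=%.3f\n",
              x$cell_class, x$cf_khz, 100 * x$distance, x$h_um, x$w_um, x$n_sp, x$gamma))
  invisible(x)
}

#' Read a morphology table from delimited text
#'
#' Expects a CSV with header `cell_id, cell_class, cf_khz, h_um, w_um, n_sp,
#' gamma`.
#'
#' @param path file path.
#' @return A data.frame, one row per cell.
#' @export
read_morphology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_class", "cf_khz", "h_um", "w_um", "n_sp", "gamma")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_input("morphology table lacks columns: %s", paste(missing, collapse = ", "))
  df
}
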