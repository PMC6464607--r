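# Fluid-jet force calibration: hydrodynamic model converting voltage commands
# into calibrated effective forces at the bundle tip.

#' Effective hydrodynamic radius of a hair bundle (prolate ellipsoid)
#'
#' Approximates the bundle by a prolate ellipsoid of short axis `h` (height)
#' and long axis `w` (width) in a flow perpendicular to the axis of rotational
#' symmetry. With aspect ratio phi = w/h,
#' \deqn{R_{HB} = \frac{4h}{3\left[\frac{\phi}{\phi^2-1} +
#'   \frac{(2\phi^2-3)\,\ln(\phi+\sqrt{\phi^2-1})}{(\phi^2-1)^{3/2}}\right]}}
#' Near phi = 1 the bracket is evaluated by its series expansion
#' 8/3 - (16/15)(phi-1) + (52/105)(phi-1)^2, so the sphere limit R = h/2 is
#' recovered continuously.
#'
#' @param h short axis: bundle height (um).
#' @param w long axis: bundle width (um). If `w < h` the axes are swapped with
#'   a warning (the formula assumes `w` is the long axis).
#' @return Effective hydrodynamic radius, same units as `h`.
#' @export
ellipsoid_radius <- function(h, w) {
  check_positive(h, "h"); check_positive(w, "w")
  if (w < h) {
    warning("`w` < `h`: axes swapped (the long axis must be `w`)")
    tmp <- h; h <- w; w <- tmp
  }
  phi <- w / h
  if (abs(phi - 1) < 1e-4) {
    e <- phi - 1
    s <- 8 / 3 - (16 / 15) * e + (52 / 105) * e^2
  } else {
    q <- phi^2 - 1
    s <- phi / q + (2 * phi^2 - 3) * log(phi + sqrt(q)) / q^1.5
  }
  4 * h / (3 * s)
}

#' Effective hydrodynamic radius of a cylindrical fiber
#'
#' \eqn{R_F = 2L / (3 (\ln(L/D_F) + 0.84))} for a fiber of diameter `d_f`
#' intersecting the fluid cone over a length `l`.
#'
#' @param l intersection length (um); must exceed `d_f`.
#' @param d_f fiber diameter (um).
#' @return Effective hydrodynamic radius (um).
#' @export
fiber_radius <- function(l, d_f) {
  check_positive(l, "l"); check_positive(d_f, "d_f")
  if (any(l <= d_f)) stop_input("`l` must exceed the fiber diameter `d_f`")
  2 * l / (3 * (log(l / d_f) + 0.84))
}

#' Normalized drag factor from averaging the jet velocity profile
#'
#' Average of the velocity profile `1/(1+(y/A)^2)^2` over a probe of
#' half-width ratio `w` (= W/(2A) for a bundle of width W, or L/(2A) for a
#' fiber spanning the cone of width L):
#' \deqn{\beta(w) = \frac{1}{2w}\left(\frac{w}{1+w^2} + \arctan w\right)}
#' beta decreases monotonically from 1 (point probe) to 0.
#'
#' @param w positive half-width ratio; values below 1e-8 return the limit 1.
#' @return beta(w), dimensionless in (0, 1].
#' @export
beta_factor <- function(w) {
  if (any(w < 0)) stop_input("`w` must be non-negative")
  ifelse(w < 1e-8, 1, (w / (1 + w^2) + atan(w)) / (2 * w))
}

#' Jet velocity profile across the fluid cone
#'
#' \eqn{v_X(y) = V_{max} / (1 + (y/A)^2)^2}: the lateral profile of the axial
#' fluid speed at distance y from the jet axis, with maximal speed `vmax` on
#' the axis and lateral extension `a`.
#'
#' @param y lateral distance(s) from the jet axis (um).
#' @param vmax maximal speed on the axis.
#' @param a lateral extension of the velocity field (um).
#' @return Speed(s), same units as `vmax`.
#' @export
velocity_profile <- function(y, vmax, a) {
  check_positive(vmax, "vmax"); check_positive(a, "a")
  vmax / (1 + (y / a)^2)^2
}

#' Jet cone geometry
#'
#' @param d_fj pipette mouth diameter (um), typically 5-10 um.
#' @param alpha cone half-aperture (rad), in (0, pi/2).
#' @param x pipette-to-target projected distance (um), nominally ~8 um.
#' @return An object of class `jet_geometry`.
#' @export
jet_geometry <- function(d_fj = 6, alpha = 0.384, x = 8) {
  check_positive(d_fj, "d_fj")
  if (!is.finite(x) || x < 0) stop_input("`x` must be non-negative")
  if (alpha < 0 || alpha >= pi / 2) stop_input("`alpha` must be in [0, pi/2)")
  structure(list(d_fj = d_fj, alpha = alpha, x = x), class = "jet_geometry")
}

#' Width of the fluid cone at the target
#'
#' `L(x) = 2 x tan(alpha) + D_FJ`. The lateral extension of the velocity
#' field is approximately `A = L/2`.
#'
#' @param geometry a [jet_geometry()].
#' @return The cone width L (um), with the lateral extension as attribute
#'   `"A"`.
#' @export
jet_length <- function(geometry) {
  stopifnot(inherits(geometry, "jet_geometry"))
  L <- 2 * geometry$x * tan(geometry$alpha) + geometry$d_fj
  attr(L, "A") <- L / 2
  L
}

#' Calibration fiber probe
#'
#' @param d_f fiber diameter (um), typically 0.7-1.5 um.
#' @param k_f fiber stiffness (mN/m), typically 0.2-2 mN/m.
#' @param l intersection length with the jet (um); used to compute `r_f` via
#'   [fiber_radius()] when `r_f` is not given.
#' @param r_f effective hydrodynamic radius (um); computed from `l` and `d_f`
#'   if missing.
#' @return An object of class `fiber_probe`.
#' @export
fiber_probe <- function(d_f, k_f, l = NULL, r_f = NULL) {
  check_positive(d_f, "d_f"); check_positive(k_f, "k_f")
  if (is.null(r_f)) {
    if (is.null(l)) stop_input("supply either `r_f` or the intersection length `l`")
    r_f <- fiber_radius(l, d_f)
  }
  structure(list(d_f = d_f, k_f = k_f, r_f = r_f), class = "fiber_probe")
}

#' Fit the jet velocity profile to bead-tracer samples
#'
#' Nonlinear least squares of [velocity_profile()] against measured bead
#' velocities. Initial guesses: the sample maximum for `vmax`, and the
#' lateral distance at which the speed falls to a quarter of the maximum for
#' `a` (the profile predicts v(a) = vmax/4).
#'
#' @param bead_table data.frame with columns `y_um` and `v_um_per_s` (at
#'   least 5 samples spanning both signs of y).
#' @return A list with `vmax`, `a`, their standard errors, and the `nls` fit.
#' @export
fit_velocity_profile <- function(bead_table) {
  y <- bead_table$y_um; v <- bead_table$v_um_per_s
  if (length(y) < 5) stop_input("need at least 5 bead samples")
  if (all(y >= 0) || all(y <= 0))
    stop_input("bead samples must span both sides of the jet axis")
  vmax0 <- max(v)
  a0 <- abs(y[which.min(abs(v - vmax0 / 4))])
  if (!is.finite(a0) || a0 <= 0) a0 <- stats::sd(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax / (1 + (y / a)^2)^2,
                      start = list(vmax = vmax0, a = a0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_input("velocity-profile fit failed: %s", conditionMessage(e)))
  cf <- summary(fit)$coefficients
  list(vmax = cf["vmax", "Estimate"], a = abs(cf["a", "Estimate"]),
       vmax_se = cf["vmax", "Std. Error"], a_se = cf["a", "Std. Error"],
       fit = fit)
}

#' Calibration constant from a fiber-deflection table
#'
#' The force on the calibration fiber is `k_f * dx`; regressing it against
#' the voltage command gives the calibration constant C (slope, pN/V). The
#' intercept is fitted rather than forced through zero, to expose any
#' steady-state flow offset; it is reported and expected to be ~0.
#'
#' @param fiber_table data.frame with columns `v_command_V` and
#'   `dx_fiber_nm` over at least 3 distinct command levels.
#' @param k_f fiber stiffness (mN/m); mN/m x nm = pN.
#' @return List with `c_pn_per_v`, `c_se`, `intercept_pn`, `r_squared`.
#' @export
calibration_constant <- function(fiber_table, k_f) {
  check_positive(k_f, "k_f")
  v <- fiber_table$v_command_V
  if (length(unique(v)) < 3) stop_input("need at least 3 distinct command levels")
  f <- k_f * fiber_table$dx_fiber_nm
  fit <- stats::lm(f ~ v)
  s <- summary(fit)
  list(c_pn_per_v = unname(stats::coef(fit)[2]),
       c_se = s$coefficients[2, 2],
       intercept_pn = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared)
}

#' Geometry factor converting fiber-calibrated force to bundle force
#'
#' `G = beta(W/L) R_HB / (beta(1) R_F)`: the same jet exerts a larger drag on
#' the (narrow, close-to-axis) hair bundle than on the calibration fiber that
#' spans the whole cone. Uses A = L/2, so the bundle half-width ratio is
#' W/(2A) = W/L and the fiber ratio is L/(2A) = 1.
#'
#' @param morph a [morphology()] (uses `h_um`, `w_um`).
#' @param jet a [jet_geometry()].
#' @param fiber a [fiber_probe()].
#' @return The dimensionless geometry factor G.
#' @export
geometry_factor <- function(morph, jet, fiber) {
  stopifnot(inherits(fiber, "fiber_probe"))
  L <- as.numeric(jet_length(jet))
  r_hb <- ellipsoid_radius(morph$h_um, morph$w_um)
  beta_factor(morph$w_um / L) * r_hb / (beta_factor(1) * fiber$r_f)
}

#' Assemble a complete fluid-jet calibration
#'
#' @param c_pn_per_v calibration constant C (pN/V) from
#'   [calibration_constant()].
#' @param morph a [morphology()].
#' @param jet a [jet_geometry()].
#' @param fiber a [fiber_probe()].
#' @param eta fluid viscosity (Pa s); diagnostic only, C is empirical.
#' @return An object of class `jet_calibration` carrying C, G and the
#'   geometry pieces.
#' @export
jet_calibration <- function(c_pn_per_v, morph, jet, fiber, eta = 1e-3) {
  g <- geometry_factor(morph, jet, fiber)
  L <- as.numeric(jet_length(jet))
  structure(
    list(c_pn_per_v = c_pn_per_v, g = g,
         beta_hb = beta_factor(morph$w_um / L), beta_f = beta_factor(1),
         r_hb = ellipsoid_radius(morph$h_um, morph$w_um),
         fiber = fiber, geometry = jet, eta = eta),
    class = "jet_calibration")
}

#' Effective force at the bundle tip from a voltage command
#'
#' The drag force distributed over the bundle height is `F_D = G C V_C`; the
#' torque-equivalent point force at the bundle's tip is two thirds of it:
#' `F = (2/3) G C V_C`. (With a linear vertical velocity profile the drag per
#' unit length is proportional to height, putting the moment arm at 2h/3.)
#'
#' @param v_c voltage command(s) (V); sign convention: positive = suction =
#'   positive bundle deflection.
#' @param calib a [jet_calibration()].
#' @return Effective force(s) in pN.
#' @export
effective_force <- function(v_c, calib) {
  if (!inherits(calib, "jet_calibration")) stop_input("`calib` must be a jet_calibration")
  (2 / 3) * calib$g * calib$c_pn_per_v * v_c
}

#' @export
print.jet_calibration <- function(x, ...) {
  cat(sprintf("<jet_calibration> C = %.3g pN/V, G = %.3f (beta_HB=%.3f, beta_F=%.3f, R_HB=%.2f um, R_F=%.2f um)\n",
              x$c_pn_per_v, x$g, x$beta_hb, x$beta_f, x$r_hb, x$fiber$r_f))
  invisible(x)
}

#' Write / read a calibration artifact as JSON
#'
#' @param calib a [jet_calibration()].
#' @param path file path.
#' @return `read_calibration` returns a `jet_calibration`.
#' @export
write_calibration <- function(calib, path) {
  x <- unclass(calib)
  x$fiber <- unclass(x$fiber)
  x$geometry <- unclass(x$geometry)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fiber <- structure(x$fiber, class = "fiber_probe")
  x$geometry <- structure(x$geometry, class = "jet_geometry")
  structure(x, class = "jet_calibration")
}
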