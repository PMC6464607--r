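test_that("ellipsoid radius matches high-precision evaluations and the sphere limit", {
  # frozen oracle values: 20-digit symbolic evaluation of the prolate formula
  expect_equal(ellipsoid_radius(4.5, 9.0), 3.1025228780694712, tolerance = 1e-12)
  expect_equal(ellipsoid_radius(6.2, 12.0), 4.2021119727924866, tolerance = 1e-12)
  expect_equal(ellipsoid_radius(5.06, 6.0), 2.7158457817389151, tolerance = 1e-12)
  expect_equal(ellipsoid_radius(2.74, 8.0), 2.3296166596462810, tolerance = 1e-12)
  # sphere limit: Stokes radius of a sphere of diameter h
  expect_equal(ellipsoid_radius(4, 4 * (1 + 1e-6)), 2, tolerance = 1e-5)
  expect_equal(ellipsoid_radius(4, 4), 2, tolerance = 1e-9)
  # continuity across the series switch-over at |phi - 1| = 1e-4 (the two
  # radii differ by ~0.8 * d(phi) from the slope of the formula itself)
  expect_equal(ellipsoid_radius(4, 4 * (1 + 0.99e-4)),
               ellipsoid_radius(4, 4 * (1 + 1.01e-4)), tolerance = 5e-6)
  # monotone in width at fixed height
  w <- seq(5, 12, by = 0.5)
  r <- vapply(w, function(wi) ellipsoid_radius(5, wi), numeric(1))
  expect_true(all(diff(r) > 0))
  expect_warning(r_sw <- ellipsoid_radius(9, 4.5), "swapped")
  expect_equal(r_sw, ellipsoid_radius(4.5, 9))
})

test_that("fiber radius follows the logarithmic formula within the calibrated range", {
  expect_equal(fiber_radius(12, 1), 24 / (3 * (log(12) + 0.84)), tolerance = 1e-12)
  expect_equal(round(fiber_radius(12, 1), 2), 2.41)
  # doubling L less than doubles R_F
  expect_lt(fiber_radius(24, 1), 2 * fiber_radius(12, 1))
  # default geometry keeps R_F within the fabricated 2.5-3.2 um range
  L <- as.numeric(jet_length(default_jet()))
  rf <- fiber_radius(L, c(1.04, 1.2, 1.33, 1.5))
  expect_true(all(rf >= 2.5 & rf <= 3.2))
  expect_error(fiber_radius(1, 1), "exceed")
})

test_that("beta factor equals the profile quadrature, decays monotonically, limits to 1", {
  expect_equal(beta_factor(1), 0.25 + pi / 8, tolerance = 1e-12)
  expect_equal(beta_factor(0), 1)
  expect_equal(beta_factor(1e-9), 1)
  for (w in c(1e-3, 0.03, 0.3, 1, 3, 12, 50)) {
    quad <- stats::integrate(function(u) 1 / (1 + u^2)^2, -w, w,
                             rel.tol = 1e-12)$value / (2 * w)
    expect_equal(beta_factor(w), quad, tolerance = 1e-9)
  }
  ws <- exp(seq(log(1e-3), log(100), length.out = 80))
  expect_true(all(diff(beta_factor(ws)) < 0))
  expect_lt(beta_factor(1e4), 1e-3)
  expect_error(beta_factor(-0.1), "non-negative")
})

test_that("jet cone width follows L = 2 x tan(alpha) + D_FJ with A = L/2", {
  expect_equal(as.numeric(jet_length(jet_geometry(d_fj = 7, alpha = 0.3, x = 0))), 7)
  expect_equal(as.numeric(jet_length(jet_geometry(d_fj = 7, alpha = 0, x = 8))), 7)
  L <- jet_length(jet_geometry(d_fj = 6, alpha = 22 * pi / 180, x = 8))
  expect_equal(as.numeric(L), 16 * tan(22 * pi / 180) + 6)
  expect_equal(attr(L, "A"), as.numeric(L) / 2)
})

test_that("velocity-profile fit recovers parameters, noiseless and under noise", {
  tab <- gen_velocity_field(vmax = 80, a = 6, n_beads = 60, noise_sd = 0, seed = 3)
  fit <- fit_velocity_profile(tab)
  expect_equal(fit$vmax, 80, tolerance = 1e-6)
  expect_equal(fit$a, 6, tolerance = 1e-6)
  # fitted profile at y = a is a quarter of the fitted maximum
  expect_equal(velocity_profile(fit$a, fit$vmax, fit$a), fit$vmax / 4)
  # multiplicative-noise recovery within 3 SE
  set.seed(7)
  tabn <- gen_velocity_field(vmax = 80, a = 6, n_beads = 100, noise_sd = 0, seed = 8)
  tabn$v_um_per_s <- tabn$v_um_per_s * (1 + rnorm(100, 0, 0.05))
  fn <- fit_velocity_profile(tabn)
  expect_lt(abs(fn$vmax - 80), 3 * fn$vmax_se)
  expect_lt(abs(fn$a - 6), 3 * fn$a_se)
  expect_error(fit_velocity_profile(tab[1:4, ]), "at least 5")
  expect_error(fit_velocity_profile(tab[tab$y_um > 0, ]), "both sides")
})

test_that("calibration constant is the slope of fiber force against command", {
  tab <- gen_fiber_calibration(c_true = 12, kf = 1, commands = seq(0, 5, by = 0.5))
  cal <- calibration_constant(tab, k_f = 1)
  expect_equal(cal$c_pn_per_v, 12, tolerance = 1e-9)
  expect_equal(cal$intercept_pn, 0, tolerance = 1e-9)
  # slope scales with the fiber stiffness used to convert deflection to force
  cal2 <- calibration_constant(tab, k_f = 2)
  expect_equal(cal2$c_pn_per_v, 24, tolerance = 1e-9)
  # noisy table: recovery within 3 SE
  tn <- gen_fiber_calibration(c_true = 12, kf = 0.5, commands = rep(seq(0, 5), 4),
                              noise_sd = 8, seed = 21)
  cn <- calibration_constant(tn, k_f = 0.5)
  expect_lt(abs(cn$c_pn_per_v - 12), 3 * cn$c_se)
  expect_error(calibration_constant(data.frame(v_command_V = c(0, 1),
                                               dx_fiber_nm = c(0, 5)), 1),
               "3 distinct")
})

test_that("geometry factor reduces to 1 for a symmetric probe and matches defaults", {
  jet <- default_jet()
  L <- as.numeric(jet_length(jet))
  m_sym <- list(h_um = 2, w_um = L)      # bundle spanning the cone like the fiber
  fib <- fiber_probe(d_f = 1, k_f = 1, r_f = ellipsoid_radius(2, L))
  expect_equal(geometry_factor(m_sym, jet, fib), 1, tolerance = 1e-12)
  # representative per-location geometries: class means near the calibrated
  # values 1.4 (IHC) and 1.3 (OHC)
  lt <- default_location_priors()
  g <- vapply(seq_len(nrow(lt)), function(i)
    geometry_factor(list(h_um = lt$h_um[i], w_um = lt$w_um[i]), jet,
                    fiber_probe(lt$d_f_um[i], 1, r_f = lt$r_f_um[i])), numeric(1))
  expect_lt(abs(mean(g[lt$cell_class == "IHC"]) - 1.4), 0.1)
  expect_lt(abs(mean(g[lt$cell_class == "OHC"]) - 1.3), 0.1)
})

test_that("effective force is two thirds of the drag force and linear in the command", {
  m <- list(h_um = 5.196, w_um = 6)
  fib <- fiber_probe(d_f = 1.33, k_f = 1, r_f = 2.7)
  cal <- jet_calibration(c_pn_per_v = 10, m, default_jet(), fib)
  expect_equal(effective_force(0, cal), 0)
  v <- c(-3, 0.5, 1, 2)
  fd <- cal$g * cal$c_pn_per_v * v
  expect_equal(effective_force(v, cal) / fd, rep(2 / 3, 4))
  # worked value with G forced to 1.4: (2/3) * 1.4 * 10 * 3 = 28 pN
  cal14 <- cal; cal14$g <- 1.4
  expect_equal(effective_force(3, cal14), 28)
  # calibration artifact round-trips through JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal_rt <- read_calibration(path)
  expect_equal(cal_rt$g, cal$g)
  expect_equal(effective_force(2, cal_rt), effective_force(2, cal))
})

test_that("torque model: linear drag profile puts the moment arm at 2h/3 for any height", {
  for (h in c(2, 4.18, 7)) {
    f <- function(z) z                     # drag per unit length ~ local speed ~ z
    torque <- stats::integrate(function(z) f(z) * z, 0, h)$value
    total <- stats::integrate(f, 0, h)$value
    expect_equal(torque / total, 2 * h / 3, tolerance = 1e-9)
    # equivalent point force at the tip is 2/3 of the total drag
    expect_equal((torque / h) / total, 2 / 3, tolerance = 1e-9)
  }
})

test_that("counting fluid out to the cone edge raises G by roughly five percent", {
  lt <- default_location_priors()
  jet <- default_jet()
  L <- as.numeric(jet_length(jet))
  for (i in c(1, 4)) {                     # one OHC, one IHC geometry
    rf_L <- fiber_radius(L, lt$d_f_um[i])
    rf_2L <- fiber_radius(2 * L, lt$d_f_um[i])
    g_ratio <- (beta_factor(1) * rf_L) / (beta_factor(2) * rf_2L)
    expect_gt(g_ratio, 1.02)
    expect_lt(g_ratio, 1.08)
  }
})
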