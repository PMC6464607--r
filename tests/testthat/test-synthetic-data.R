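test_that("cohort generation is deterministic, mean-matched, and degenerate-safe", {
  lt <- default_location_priors()
  a <- gen_cohort(lt, seed = 5)
  b <- gen_cohort(lt, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, gen_cohort(lt, seed = 6)))
  # n = 1 with zero SDs returns the prior means exactly
  lt0 <- lt
  for (col in c("k_hb_sd", "r_sd", "creep_sd", "dx_r_sd", "dx_ca_sd")) lt0[[col]] <- 0
  one <- gen_cohort(lt0, n_per_group = 1, seed = 1)
  expect_equal(one$k_hb_true, lt$k_hb_mean)
  expect_equal(one$r_true, lt$r_mean)
  expect_equal(one$dx_ca_true, lt$dx_ca_mean)
  # invalid prior SD is a configuration error
  bad <- lt; bad$r_sd <- -0.1
  expect_error(gen_cohort(bad, seed = 1), "negative prior SD")
  # printed-n cohort: group sample means within 3 SE of the priors
  g1 <- a[a$cell_class == "OHC" & a$cf_khz == 1, ]
  se <- sd(g1$k_hb_true) / sqrt(nrow(g1))
  expect_equal(nrow(g1), 19)
  expect_lt(abs(mean(g1$k_hb_true) - 2.5), 3 * se)
})

test_that("generated parameter distributions match their priors (KS at alpha = 0.01)", {
  lt <- default_location_priors()[3, ]   # single group, large n
  lt$dx_r_sd <- 5                        # mild truncation: parent ~ normal
  lt$creep_sd <- 0.02
  co <- gen_cohort(lt, n_per_group = 500, seed = 11)
  expect_gt(stats::ks.test(co$creep_frac_true,
                           "pnorm", mean(co$creep_frac_true),
                           sd(co$creep_frac_true))$p.value, 0.01)
  expect_gt(stats::ks.test(co$dx_r_true, "pnorm", mean(co$dx_r_true),
                           sd(co$dx_r_true))$p.value, 0.01)
  # means are matched even under hard truncation
  en <- default_ensemble_priors()
  x <- withr::with_seed(31, rnorm_trunc(5e4, en$r$mean, en$r$sd, 0, 0.95))
  expect_lt(abs(mean(x) - 0.22), 0.003)
  expect_true(all(x >= 0 & x <= 0.95))
  xc <- withr::with_seed(32, rnorm_trunc(5e4, en$dx_ca$mean, en$dx_ca$sd, upper = 0))
  expect_lt(abs(mean(xc) + 26), 0.3)
})

test_that("force-step traces obey Hooke's law, the creep convention, and disruption", {
  gt <- fake_cell(k_hb = 2.5, creep = 0)
  tr <- gen_force_step_response(gt, forces = 25, noise_sd = 0)[[1]]
  on <- tr$annotations$step_on; off <- tr$annotations$step_off
  plateau <- tr$position[trace_time(tr) > on & trace_time(tr) < off]
  expect_equal(unique(round(plateau, 12)), 10)     # F/k = 25/2.5 nm, flat
  # end-of-step deflection exceeds the early deflection by exactly creep_frac
  gt22 <- fake_cell(k_hb = 2, creep = 0.22)
  tr22 <- gen_force_step_response(gt22, forces = 40, noise_sd = 0)[[1]]
  tt <- trace_time(tr22)
  early <- mean(tr22$position[tt >= on + 0.005 & tt <= on + 0.010])
  endstep <- tr22$position[max(which(tt < off))]
  expect_equal(endstep / early - 1, 0.22, tolerance = 1e-3)
  # disrupted traces: elastic response larger by 1/(1 - r), creep < 5% of intact
  trd <- gen_force_step_response(gt22, forces = 40, disrupted = TRUE, noise_sd = 0)[[1]]
  early_d <- mean(trd$position[tt >= on + 0.005 & tt <= on + 0.010])
  expect_equal(early_d / early, 1 / (1 - gt22$r_true), tolerance = 1e-9)
  expect_lt(creep_fraction(trd), 0.05 * creep_fraction(tr22) + 1e-6)
  expect_error(gen_force_step_response(gt22, 40, step_dur = -1), "positive")
})

test_that("iontophoresis traces reach the negative extremum and the steady offset", {
  gt <- fake_cell(dx_ca = -26, dx_r = 78)
  tr <- gen_iontophoresis_trace(gt, noise_sd = 0)
  expect_equal(min(tr$position), -26)
  n <- length(tr$position)
  expect_equal(mean(tr$position[seq(0.95 * n, n)]), 78, tolerance = 0.01)
  # command carries holding + step currents
  expect_equal(sort(unique(tr$command)), c(-90, 10))
  # current: biphasic, inward increase then decay to the all-closed level
  i_at_dip <- abs(tr$current[which.min(tr$position)])
  i_rest <- abs(tr$current[1])
  i_end <- abs(tr$current[n])
  expect_gt(i_at_dip, 1.8 * i_rest)
  expect_lt(i_end, 0.05 * i_rest)
  # reversible high-Ca regime: returns to baseline, no offset
  trv <- gen_iontophoresis_trace(gt, disrupted = FALSE, noise_sd = 0)
  expect_equal(min(trv$position), -26)
  expect_lt(abs(mean(trv$position[seq(0.95 * n, n)])), 1)
})

test_that("velocity-field generator hits the 25% and 4% landmark fractions", {
  tab <- gen_velocity_field(vmax = 100, a = 5, n_beads = 200, seed = 2)
  expect_true(all(abs(tab$y_um) <= 10))
  expect_equal(velocity_profile(0, 100, 5), 100)
  expect_equal(velocity_profile(5, 100, 5), 25)
  expect_equal(velocity_profile(10, 100, 5), 4)
})

test_that("current responses saturate at i_max with half activation at the midpoint", {
  gt <- fake_cell(i_max = 800)
  expect_equal(gen_current_response(gt, 1e6), 800)
  expect_equal(gen_current_response(gt, 0), 400)
  expect_equal(gen_current_response(gt, -1e6), 0, tolerance = 1e-9)
  t <- seq(0, 0.2, by = 1e-4)
  cur <- gen_current_response(gt, 300 * sin(2 * pi * 60 * t))
  expect_equal(diff(range(cur)), 800, tolerance = 0.01)
})

test_that("traces round-trip through delimited text plus JSON sidecar", {
  gt <- fake_cell()
  tr <- gen_iontophoresis_trace(gt, noise_sd = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  rt <- read_trace(path)
  expect_equal(rt$dt, tr$dt)
  expect_equal(rt$position, tr$position, tolerance = 1e-12)
  expect_equal(rt$current, tr$current, tolerance = 1e-12)
  expect_equal(rt$annotations$reversal, tr$annotations$reversal)
  expect_equal(rt$command_units, "nA")
})
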