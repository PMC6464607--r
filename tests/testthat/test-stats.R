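test_that("product SEM and effective degrees of freedom follow the propagation formulas", {
  # single variable: reduces to the plain SEM with n - 1 degrees of freedom
  p1 <- product_sem(5, 0.4, 12)
  expect_equal(p1$sigma_p, 0.4)
  expect_equal(p1$nu_eff, 11)
  # frozen worked example: means (2, 3), sems (0.2, 0.3), ns (10, 10)
  p2 <- product_sem(c(2, 3), c(0.2, 0.3), c(10, 10))
  expect_equal(p2$product, 6)
  expect_equal(p2$sigma_p, 6 * sqrt(0.02), tolerance = 1e-12)   # ~0.849
  expect_equal(round(p2$sigma_p, 3), 0.849)
  expect_equal(p2$nu_eff, 18, tolerance = 1e-12)
  # a zero-sem variable contributes nothing, to error or to df loss
  p3 <- product_sem(c(2, 3), c(0.2, 0), c(10, 10))
  expect_equal(p3$sigma_p, 3 * 0.2)
  expect_equal(p3$nu_eff, 9)
  # symmetry under permutation
  p4 <- product_sem(c(3, 2), c(0.3, 0.2), c(10, 10))
  expect_equal(p4$sigma_p, p2$sigma_p)
  expect_equal(p4$nu_eff, p2$nu_eff)
  expect_error(product_sem(c(0, 2), c(0.1, 0.1), c(5, 5)), "zero mean")
  expect_error(product_sem(c(1, 2), c(0.1, 0.1), c(1, 5)), "at least 2")
})

test_that("nu_eff never exceeds the summed degrees of freedom", {
  set.seed(4)
  for (i in 1:40) {
    m <- length(means <- runif(sample(2:5, 1), 0.5, 10))
    sems <- runif(m, 0.01, 1)
    ns <- sample(3:40, m, replace = TRUE)
    expect_lte(product_sem(means, sems, ns)$nu_eff, sum(ns - 1) + 1e-9)
  }
})

test_that("Welch t-test behaves on identical, pooled-equivalent and summary inputs", {
  x <- c(1.2, 1.4, 1.1, 1.6, 1.3)
  w <- welch_ttest(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  # equal n and equal variances: identical to the pooled t-test
  set.seed(2)
  a <- rnorm(12); b <- rnorm(12) + 0.5
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)    # force equal variance
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  wab <- welch_ttest(a, b)
  expect_equal(wab$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(wab$p, pooled$p.value, tolerance = 1e-9)
  # summary-based path agrees with the sample-based path
  ga <- group_summary(a); gb <- group_summary(b)
  ws <- welch_ttest(ga, gb)
  expect_equal(ws$t, wab$t, tolerance = 1e-12)
  expect_equal(ws$p, wab$p, tolerance = 1e-9)
  expect_error(welch_ttest(1, c(1, 2)), "n >= 2")
})

test_that("group comparisons at printed effect sizes are overwhelmingly significant", {
  # 1-kHz vs 4-kHz outer hair cells: means 2.5 vs 8.6, SDs from printed SEMs
  set.seed(9)
  hits <- mean(replicate(200, {
    a <- rnorm(19, 2.5, 0.2 * sqrt(19))
    b <- rnorm(21, 8.6, 0.5 * sqrt(21))
    welch_ttest(a, b)$p < 0.001
  }))
  expect_gte(hits, 0.95)
  # four inner-hair-cell locations: ANOVA detects the tonotopic variation
  lt <- default_location_priors()
  ihc <- lt[lt$cell_class == "IHC", ]
  hits_a <- mean(replicate(200, {
    g <- lapply(seq_len(nrow(ihc)), function(i)
      rnorm(ihc$n_cells[i], ihc$k_hb_mean[i], ihc$k_hb_sd[i]))
    one_way_anova(g)$p < 0.05
  }))
  expect_gte(hits_a, 0.95)
})

test_that("one-way ANOVA handles degenerate groups and matches t^2 for two groups", {
  same <- list(c(2, 2, 2), c(2, 2, 2))
  av0 <- one_way_anova(same)
  expect_equal(av0$f, 0)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10, 1)
  av <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(av$f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(av$p, tt$p.value, tolerance = 1e-9)
  expect_error(one_way_anova(list(a)), "2 groups")
  expect_error(one_way_anova(list(a, 1)), "at least 2 observations")
})

test_that("weighted gradient fits pass through two points and reduce to OLS", {
  f2 <- weighted_gradient(c(1, 4), c(2.5, 8.6), c(0.2, 0.5))
  expect_equal(f2$slope, (8.6 - 2.5) / 3, tolerance = 1e-12)
  expect_equal(f2$intercept + f2$slope * 1, 2.5, tolerance = 1e-12)
  # equal sems = ordinary least squares
  x <- c(1, 2, 4, 15); y <- c(1.7, 2.54, 3.8, 5.5)
  fw <- weighted_gradient(x, y, rep(0.3, 4))
  fo <- stats::lm(y ~ x)
  expect_equal(fw$slope, unname(coef(fo)[2]), tolerance = 1e-12)
  expect_equal(fw$slope_se, summary(fo)$coefficients[2, 2], tolerance = 1e-12)
  expect_warning(fz <- weighted_gradient(x, y, rep(0, 4)), "ordinary least squares")
  expect_equal(fz$slope, fw$slope, tolerance = 1e-12)
})

test_that("weighting by inverse variance is at least as efficient as OLS", {
  set.seed(17)
  x <- c(1, 2, 4, 8, 15)
  sems <- c(0.1, 0.1, 0.5, 1.0, 2.0)
  sl <- replicate(500, {
    y <- 1 + 0.3 * x + rnorm(5, 0, sems)
    c(w = weighted_gradient(x, y, sems)$slope,
      o = unname(coef(stats::lm(y ~ x))[2]))
  })
  expect_lte(var(sl["w", ]), var(sl["o", ]))
})

test_that("slope comparison is null for identical fits and flags the printed contrasts", {
  x <- c(1, 2, 4); y <- c(2.5, 4.6, 8.6); s <- c(0.2, 0.3, 0.5)
  fa <- weighted_gradient(x, y, s)
  cs <- compare_slopes(fa, fa)
  expect_equal(cs$t, 0)
  expect_equal(cs$p, 1)
  # stiffness gradients rebuilt from printed group means / SEMs: OHC steeper
  lt <- default_location_priors()
  o <- lt[lt$cell_class == "OHC", ]; i <- lt[lt$cell_class == "IHC", ]
  fo <- weighted_gradient(o$cf_khz, o$k_hb_mean, o$k_hb_sem)
  fi <- weighted_gradient(i$cf_khz, i$k_hb_mean, i$k_hb_sem)
  out <- compare_slopes(fo, fi)
  expect_gt(fo$slope, fi$slope)
  expect_lt(out$p, 0.05)
  # welch df variant is valid but far more conservative
  outw <- compare_slopes(fo, fi, df_method = "welch")
  expect_lt(outw$df, out$df)
  fa_no_se <- fa; fa_no_se$slope_se <- NA_real_
  expect_error(compare_slopes(fa_no_se, fi), "standard errors")
})

test_that("type-I error of the test suite sits at the nominal five percent", {
  set.seed(23)
  n_rep <- 2000
  fp_t <- mean(replicate(n_rep, welch_ttest(rnorm(10), rnorm(10))$p < 0.05))
  expect_gt(fp_t, 0.035); expect_lt(fp_t, 0.065)
  fp_a <- mean(replicate(1000, {
    one_way_anova(list(rnorm(10), rnorm(10), rnorm(10)))$p < 0.05
  }))
  expect_gt(fp_a, 0.030); expect_lt(fp_a, 0.070)
})
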