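# Error propagation for products of means, Welch tests, ANOVA, and weighted
# tonotopic-gradient regression.

#' Standard error and effective degrees of freedom of a product of means
#'
#' For a quantity estimated as the product of M independent variables with
#' means `means`, standard errors `sems` and sample sizes `ns`:
#' \deqn{\sigma_P = \left|\prod \bar X_i\right|
#'   \sqrt{\sum (\sigma_i/\bar X_i)^2}}
#' and the Welch-Satterthwaite effective number of degrees of freedom
#' \deqn{\nu_{eff} = \frac{(\sigma_P/\prod \bar X_i)^4}
#'   {\sum \frac{1}{n_i-1} (\sigma_i/\bar X_i)^4}.}
#' A quotient is a product with the inverse variable (same relative error),
#' so `means` may carry reciprocals.
#'
#' @param means variable means (all nonzero).
#' @param sems standard errors of the means.
#' @param ns sample sizes (all >= 2).
#' @return List with `product`, `sigma_p` and `nu_eff`.
#' @export
product_sem <- function(means, sems, ns) {
  if (length(means) != length(sems) || length(means) != length(ns))
    stop_input("`means`, `sems`, `ns` must have equal length")
  if (any(means == 0)) stop_input("relative error undefined for a zero mean")
  if (any(ns < 2)) stop_input("each variable needs at least 2 measurements")
  rel2 <- (sems / means)^2
  p <- prod(means)
  sigma_p <- abs(p) * sqrt(sum(rel2))
  nu_eff <- if (sigma_p == 0) Inf else sum(rel2)^2 / sum(rel2^2 / (ns - 1))
  list(product = p, sigma_p = sigma_p, nu_eff = nu_eff)
}

#' Group summary (mean, SEM, n, effective degrees of freedom)
#'
#' @param x numeric sample, or a mean when `sem` is supplied.
#' @param sem,n,nu_eff explicit summary pieces for derived quantities; for a
#'   directly measured sample `nu_eff = n - 1`.
#' @param label optional label, e.g. `c("OHC", "4")`.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(x, sem = NULL, n = NULL, nu_eff = NULL, label = NULL) {
  if (is.null(sem)) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2) stop_input("need at least 2 observations")
    out <- list(mean = mean(x), sem = stats::sd(x) / sqrt(n), n = n,
                nu_eff = n - 1, label = label)
  } else {
    if (sem < 0) stop_input("`sem` must be non-negative")
    if (is.null(nu_eff)) {
      if (is.null(n)) stop_input("supply `n` or `nu_eff`")
      nu_eff <- n - 1
    }
    out <- list(mean = x, sem = sem, n = n, nu_eff = nu_eff, label = label)
  }
  structure(out, class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) x else group_summary(x)
}

#' Welch's two-sample t-test on samples or group summaries
#'
#' Two-tailed unpaired t-test with Welch's correction. Raw samples are
#' passed to [stats::t.test()]; `group_summary` inputs (mean, sem,
#' effective degrees of freedom) are combined directly:
#' t = (m1 - m2)/sqrt(sem1^2 + sem2^2), with Welch-Satterthwaite degrees of
#' freedom built from the per-group `nu_eff` - matching how derived
#' quantities (products of means) are compared.
#'
#' @param a,b numeric samples (n >= 2) or [group_summary()] objects.
#' @return List with `t`, `df`, `p` and significance `stars`
#'   (*p<0.05, **p<0.01, ***p<0.001).
#' @export
welch_ttest <- function(a, b) {
  if (!inherits(a, "group_summary") && !inherits(b, "group_summary") &&
      is.numeric(a) && is.numeric(b)) {
    if (length(a) < 2 || length(b) < 2) stop_input("each sample needs n >= 2")
    ht <- stats::t.test(a, b, var.equal = FALSE)
    out <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  } else {
    a <- as_group_summary(a); b <- as_group_summary(b)
    se2 <- a$sem^2 + b$sem^2
    t <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (a$sem^4 / a$nu_eff + b$sem^4 / b$nu_eff)
    out <- list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  out$stars <- star_code(out$p)
  out
}

#' One-way ANOVA across groups
#'
#' Standard one-way analysis of variance of a measured property across
#' cochlear locations (or any grouping).
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return List with `f`, `df1`, `df2`, `p`, `stars`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop_input("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop_input("each group needs at least 2 observations")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(y) == 0) {
    # degenerate all-identical data: no variation to partition
    return(list(f = 0, df1 = length(groups) - 1, df2 = length(y) - length(groups),
                p = 1, stars = "n.s."))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(f = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1], stars = star_code(tab$`Pr(>F)`[1]))
}

#' Weighted linear regression of group means against frequency
#'
#' Characterizes a tonotopic gradient: weighted least squares of the group
#' means against characteristic frequency, each point weighted by the
#' inverse of its squared standard error of the mean. If all SEMs are zero
#' the fit falls back to ordinary least squares with a warning.
#'
#' @param x characteristic frequencies (kHz).
#' @param means group means.
#' @param sems group standard errors (same length).
#' @return An object of class `gradient_fit`: `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `weights`, `df`, and the `lm` fit.
#' @export
weighted_gradient <- function(x, means, sems) {
  if (length(x) < 2) stop_input("need at least 2 points")
  if (any(sems < 0)) stop_input("negative SEM")
  if (all(sems == 0)) {
    warning("all SEMs are zero; falling back to ordinary least squares")
    w <- rep(1, length(x))
  } else {
    if (any(sems == 0)) stop_input("mixed zero and positive SEMs")
    w <- 1 / sems^2
  }
  fit <- stats::lm(means ~ x, weights = w)
  s <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         slope_se = s$coefficients[2, 2],
         intercept = unname(stats::coef(fit)[1]),
         intercept_se = s$coefficients[1, 2],
         weights = w, df = fit$df.residual, fit = fit),
    class = "gradient_fit")
}

#' Compare two regression slopes
#'
#' t-test on the difference of two gradient slopes:
#' t = (b1 - b2)/sqrt(se1^2 + se2^2). Degrees of freedom default to the
#' pooled residual degrees of freedom of the two regressions (df_a + df_b),
#' the convention of standard slope-comparison tests; a Welch-Satterthwaite
#' combination of the two slope variances is available via
#' `df_method = "welch"`, but note that with the few residual degrees of
#' freedom of short tonotopic series it is extremely conservative.
#'
#' @param fit_a,fit_b [weighted_gradient()] fits.
#' @param df_method "pooled" (default, df_a + df_b) or "welch".
#' @return List with `t`, `df`, `p`, `stars`.
#' @export
compare_slopes <- function(fit_a, fit_b, df_method = c("pooled", "welch")) {
  df_method <- match.arg(df_method)
  if (is.null(fit_a$slope_se) || is.null(fit_b$slope_se) ||
      !is.finite(fit_a$slope_se) || !is.finite(fit_b$slope_se))
    stop_input("both fits must carry slope standard errors")
  se2 <- fit_a$slope_se^2 + fit_b$slope_se^2
  t <- (fit_a$slope - fit_b$slope) / sqrt(se2)
  df <- if (df_method == "welch") {
    se2^2 / (fit_a$slope_se^4 / fit_a$df + fit_b$slope_se^4 / fit_b$df)
  } else {
    fit_a$df + fit_b$df
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, stars = star_code(p))
}
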