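# Internal helpers: argument checks, seeded streams, truncated-normal draws.

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop_input("`%s` must be positive and finite", name)
  invisible(x)
}

#' Evaluate code with a reproducible per-cell random stream
#'
#' Derives a child seed from a master seed and an integer stream id, runs
#' `code` under that seed, and restores the caller's RNG state afterwards.
#' Used so that individual synthetic cells are reproducible under partial
#' re-runs of a cohort.
#'
#' @param master integer master seed.
#' @param id integer stream identifier (e.g. cell index).
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_stream_seed <- function(master, id, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  child <- (as.double(master) * 1000003 + as.double(id)) %% 2147483647
  set.seed(as.integer(child))
  force(code)
}

# Mean of a normal(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Draw from a truncated normal whose realized mean matches the target
#'
#' Samples a normal distribution truncated to `[lower, upper]` by inverse-CDF
#' sampling, after shifting the location parameter so that the mean of the
#' *truncated* distribution equals `mean`. Without the shift, truncating e.g.
#' a gating-spring fraction at zero would inflate the generated ensemble mean
#' above its prior.
#'
#' @param n number of draws.
#' @param mean target mean of the generated values.
#' @param sd standard deviation of the parent normal; `sd = 0` returns `mean`.
#' @param lower,upper truncation bounds (may be infinite).
#' @param stratified draw by Latin-hypercube stratification of the CDF
#'   instead of iid sampling: each draw keeps the correct marginal
#'   distribution, but the ensemble mean has far smaller Monte Carlo error.
#'   Useful when an ensemble statistic, not realization-to-realization
#'   scatter, is the quantity of interest (e.g. parameter-recovery checks).
#' @return Numeric vector of `n` draws.
#' @export
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        stratified = FALSE) {
  if (sd < 0) stop_input("negative prior SD")
  if (mean < lower || mean > upper)
    stop_input("prior mean %g outside truncation range [%g, %g]", mean, lower, upper)
  if (sd == 0) return(rep(mean, n))
  mu <- mean
  if (is.finite(lower) || is.finite(upper)) {
    f <- function(m) truncnorm_mean(m, sd, lower, upper) - mean
    # the truncated mean is monotone in mu; bracket generously
    mu <- stats::uniroot(f, interval = c(mean - 8 * sd, mean + 8 * sd),
                         extendInt = "upX", tol = 1e-10)$root
  }
  p0 <- stats::pnorm(lower, mu, sd)
  p1 <- stats::pnorm(upper, mu, sd)
  u <- if (stratified) {
    (sample.int(n) - stats::runif(n)) / n
  } else {
    stats::runif(n)
  }
  stats::qnorm(p0 + u * (p1 - p0), mu, sd)
}

# Mean of a channel over a time window [t0, t1] (seconds, inclusive).
window_mean <- function(x, dt, t0, t1) {
  i0 <- max(1L, floor(t0 / dt) + 1L)
  i1 <- min(length(x), ceiling(t1 / dt))
  if (i1 < i0) stop_input("empty time window [%g, %g]", t0, t1)
  mean(x[i0:i1])
}

# Centered moving average over a window of `width` seconds.
moving_average <- function(x, dt, width) {
  k <- max(1L, round(width / dt))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L) return(x)
  pad <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(pad + 1L):(pad + length(x))]
}

star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}
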