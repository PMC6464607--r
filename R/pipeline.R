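# End-to-end orchestration: simulate -> analyze -> summarize.

#' Default run configuration
#'
#' @param seed master seed for all randomness.
#' @param location_table per-location priors.
#' @param n_per_group optional override of per-group cohort sizes.
#' @param forces_pn force-step amplitudes (pN) scaled per cell so
#'   displacements stay within the monitor's linear range; expressed as
#'   displacement targets (nm) times the group stiffness when NULL.
#' @param noiseless set all measurement noise to zero (generator truths are
#'   then recovered to numerical precision).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, location_table = default_location_priors(),
                               n_per_group = NULL, forces_pn = NULL,
                               noiseless = FALSE) {
  st <- default_settings()
  structure(
    list(seed = seed, location_table = location_table, n_per_group = n_per_group,
         displacement_targets_nm = c(10, 20, 30, 40, 50),
         forces_pn = forces_pn,
         window = st$window, step_dur = st$step_dur,
         noise_sd_pos = if (noiseless) 0 else st$noise_sd_pos,
         noise_sd_cur = if (noiseless) 0 else st$noise_sd_cur),
    class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; the location table may be supplied as a list of
#' records.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("reading YAML configs requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- default_run_config(seed = if (!is.null(raw$seed)) raw$seed else 1)
  if (!is.null(raw$location_table)) cfg$location_table <- as.data.frame(raw$location_table)
  for (f in setdiff(names(raw), c("seed", "location_table")))
    cfg[[f]] <- raw[[f]]
  cfg
}

# Analyze one synthetic cell end to end; returns a one-row data.frame.
analyze_cell <- function(gt, cfg) {
  st <- default_settings()
  forces <- cfg$displacement_targets_nm * gt$k_hb_true
  # mechanics: stiffness from intact force steps, creep from the largest step
  intact <- gen_force_step_response(gt, forces, step_dur = cfg$step_dur,
                                    noise_sd = cfg$noise_sd_pos)
  est <- estimate_stiffness(intact, window = cfg$window)
  creep <- creep_fraction(intact[[length(intact)]], window = cfg$window)

  # gating fraction: same mid-range stimulus before and after disruption
  f_mid <- forces[3]
  disr <- gen_force_step_response(gt, rep(f_mid, 3), step_dur = cfg$step_dur,
                                  disrupted = TRUE, noise_sd = cfg$noise_sd_pos)
  amp_i <- mean(vapply(intact[3], step_displacement, numeric(1), window = cfg$window))
  amp_d <- mean(vapply(disr, step_displacement, numeric(1), window = cfg$window))
  r_hat <- suppressWarnings(gating_fraction(amp_i, amp_d))

  # tip links from a saturating sinusoidal stimulus
  tsin <- seq(0, 0.2, by = st$dt_step)
  defl <- 300 * sin(2 * pi * 60 * tsin)
  cur <- gen_current_response(gt, defl, noise_sd = cfg$noise_sd_cur)
  i_max <- saturating_current(cur, dt = st$dt_step)
  n_tl <- suppressWarnings(count_tip_links(i_max, gt$cell_class, gt$cf_khz, gt$n_sp))

  # iontophoresis features and tensions
  ionto <- gen_iontophoresis_trace(gt, noise_sd = cfg$noise_sd_pos)
  feats <- suppressWarnings(extract_features(ionto))
  dec <- decompose_stiffness(est$k_hb, max(0, min(r_hat, 0.95)), gt, max(1, n_tl))
  rest <- tension_at_rest(dec$k_sp_bundle, feats$dx_r, gt$gamma, max(1, n_tl))
  chel <- tension_under_chelation(dec$k_sp_bundle, min(feats$dx_ca, 0),
                                  rest$t_link_rest, gt$gamma, max(1, n_tl))

  data.frame(
    cell_id = gt$cell_id, cell_class = gt$cell_class, cf_khz = gt$cf_khz,
    h_um = gt$h_um, w_um = gt$w_um, n_sp = gt$n_sp, gamma = gt$gamma,
    k_hb_mN_per_m = est$k_hb, r = r_hat,
    k_gs_bundle = dec$k_gs_bundle, k_sp_bundle = dec$k_sp_bundle,
    kappa_fNm_per_rad = dec$kappa, k_gs_single = dec$k_gs_single,
    creep_pct = 100 * creep, r2_linearity = est$r_squared,
    i_max_pa = as.numeric(i_max), n_tl = as.numeric(n_tl),
    dx_r_nm = feats$dx_r, dx_ca_nm = feats$dx_ca,
    t_bundle_rest_pN = rest$t_bundle_rest, t_link_rest_pN = rest$t_link_rest,
    dt_bundle_pN = chel$dt_bundle, t_link_max_pN = chel$t_link_max,
    disrupted = isTRUE(feats$disrupted),
    stringsAsFactors = FALSE)
}

#' Run the full simulate-analyze-summarize pipeline
#'
#' Generates a synthetic cohort from the configured priors, simulates every
#' raw recording each cell would produce (force-step series intact and after
#' tip-link disruption, saturating transduction currents, iontophoresis
#' traces), runs the estimators on them, and summarizes per-group means with
#' propagated SEMs, ANOVA, pairwise Welch tests and weighted gradients.
#'
#' @param config a [default_run_config()].
#' @param out_dir optional directory; when given, the per-cell estimates,
#'   group summaries and statistics report are written as CSV alongside a
#'   `run_manifest.json`.
#' @return List with `cells` (ground truth), `estimates` (per-cell),
#'   `summaries`, `stats`, `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  cohort <- gen_cohort(config$location_table, config$n_per_group,
                       seed = config$seed,
                       noise_sd_pos = config$noise_sd_pos,
                       noise_sd_cur = config$noise_sd_cur)
  est <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    analyze_cell(cohort[i, ], config)))
  summ <- summarize_cohort(est)
  out <- list(cells = cohort, estimates = est,
              summaries = summ$summaries, stats = summ$stats, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(est, file.path(out_dir, "per_cell_estimates.csv"), row.names = FALSE)
    utils::write.csv(summ$summaries, file.path(out_dir, "group_summaries.csv"), row.names = FALSE)
    utils::write.csv(summ$stats, file.path(out_dir, "statistics_report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_cells = nrow(cohort),
           files = c("per_cell_estimates.csv", "group_summaries.csv",
                     "statistics_report.csv"),
           r_version = R.version.string, timestamp = format(Sys.time())),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  out
}

# Group summary of one directly measured column.
measured_summary <- function(df, col) {
  x <- df[[col]]
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x),
    nu_eff = length(x) - 1)
}

#' Summarize per-cell estimates into group tables and statistics
#'
#' Per (cell class, characteristic frequency) group: means, SEMs and n of
#' the directly measured quantities, and propagated SEMs (via
#' [product_sem()]) with Welch-Satterthwaite effective degrees of freedom
#' for the derived quantities K_GS, K_SP, kappa, k_GS, T_R, t_R, DT and
#' t_max, which are products/quotients of group means. Group tests: one-way
#' ANOVA across locations per class, pairwise Welch t-tests, and weighted
#' gradient regressions with an OHC-vs-IHC slope comparison.
#'
#' @param estimates per-cell estimates from [run_pipeline()] (or a
#'   compatible data.frame).
#' @return List with `summaries` (one row per group x variable) and `stats`
#'   (test report: variable, comparison, statistic, df, p, stars).
#' @export
summarize_cohort <- function(estimates) {
  groups <- split(estimates, list(estimates$cell_class, estimates$cf_khz), drop = TRUE)
  small <- vapply(groups, nrow, integer(1)) < 2
  if (any(small)) {
    warning("groups with n < 2 excluded: ", paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
    estimates <- do.call(rbind, groups)
  }

  summaries <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    cls <- g$cell_class[1]; cf <- g$cf_khz[1]
    direct <- list(
      k_hb = measured_summary(g, "k_hb_mN_per_m"),
      r = measured_summary(g, "r"),
      dx_r = measured_summary(g, "dx_r_nm"),
      dx_ca = measured_summary(g, "dx_ca_nm"),
      creep = measured_summary(g, "creep_pct"),
      n_tl = measured_summary(g, "n_tl"))
    omr <- 1 - g$r
    direct$one_minus_r <- c(mean = mean(omr), sem = stats::sd(omr) / sqrt(n),
                            n = n, nu_eff = n - 1)
    h2 <- g$h_um^2
    direct$h2 <- c(mean = mean(h2), sem = stats::sd(h2) / sqrt(n), n = n, nu_eff = n - 1)
    gamma <- g$gamma[1]; n_sp <- g$n_sp[1]

    prod_row <- function(name, means, sems, ns, scale = 1) {
      ps <- product_sem(means, sems, ns)
      data.frame(cell_class = cls, cf_khz = cf, variable = name,
                 mean = scale * ps$product, sem = abs(scale) * ps$sigma_p,
                 n = n, nu_eff = ps$nu_eff, stringsAsFactors = FALSE)
    }
    direct_row <- function(name, s) {
      data.frame(cell_class = cls, cf_khz = cf, variable = name,
                 mean = s["mean"], sem = s["sem"], n = s["n"], nu_eff = s["nu_eff"],
                 stringsAsFactors = FALSE)
    }
    sem_guard <- function(s) {  # product_sem needs sem >= 0 and mean != 0
      s["sem"] <- max(s["sem"], 1e-12); s
    }
    kh <- sem_guard(direct$k_hb); rr <- sem_guard(direct$r)
    om <- sem_guard(direct$one_minus_r); xr <- sem_guard(direct$dx_r)
    xc <- sem_guard(direct$dx_ca); nt <- sem_guard(direct$n_tl)
    hh <- sem_guard(direct$h2)

    k_gs <- prod_row("k_gs_bundle", c(rr["mean"], kh["mean"]),
                     c(rr["sem"], kh["sem"]), c(n, n))
    k_sp <- prod_row("k_sp_bundle", c(om["mean"], kh["mean"]),
                     c(om["sem"], kh["sem"]), c(n, n))
    kappa <- prod_row("kappa", c(om["mean"], kh["mean"], hh["mean"]),
                      c(om["sem"], kh["sem"], hh["sem"]), c(n, n, n),
                      scale = 1 / n_sp)
    k_gs1 <- prod_row("k_gs_single", c(rr["mean"], kh["mean"], 1 / nt["mean"]),
                      c(rr["sem"], kh["sem"], (nt["sem"] / nt["mean"]) / nt["mean"]),
                      c(n, n, n), scale = 1 / gamma^2)
    t_r <- prod_row("t_bundle_rest", c(om["mean"], kh["mean"], xr["mean"]),
                    c(om["sem"], kh["sem"], xr["sem"]), c(n, n, n))
    t_r1 <- prod_row("t_link_rest",
                     c(om["mean"], kh["mean"], xr["mean"], 1 / nt["mean"]),
                     c(om["sem"], kh["sem"], xr["sem"],
                       (nt["sem"] / nt["mean"]) / nt["mean"]),
                     c(n, n, n, n), scale = 1 / gamma)
    dt_b <- prod_row("dt_bundle", c(om["mean"], kh["mean"], xc["mean"]),
                     c(om["sem"], kh["sem"], xc["sem"]), c(n, n, n), scale = -1)
    # t_max = t_R + DT/(gamma N_TL): sum of two propagated terms
    dt_link <- prod_row("dt_link", c(om["mean"], kh["mean"], xc["mean"], 1 / nt["mean"]),
                        c(om["sem"], kh["sem"], xc["sem"],
                          (nt["sem"] / nt["mean"]) / nt["mean"]),
                        c(n, n, n, n), scale = -1 / gamma)
    t_max <- data.frame(cell_class = cls, cf_khz = cf, variable = "t_link_max",
                        mean = t_r1$mean + dt_link$mean,
                        sem = sqrt(t_r1$sem^2 + dt_link$sem^2),
                        n = n,
                        nu_eff = (t_r1$sem^2 + dt_link$sem^2)^2 /
                          (t_r1$sem^4 / t_r1$nu_eff + dt_link$sem^4 / dt_link$nu_eff),
                        stringsAsFactors = FALSE)

    rbind(direct_row("k_hb", direct$k_hb), direct_row("r", direct$r),
          direct_row("dx_r", direct$dx_r), direct_row("dx_ca", direct$dx_ca),
          direct_row("creep_pct", direct$creep), direct_row("n_tl", direct$n_tl),
          k_gs, k_sp, kappa, k_gs1, t_r, t_r1, dt_b, t_max)
  }))
  rownames(summaries) <- NULL

  stats_report <- summarize_tests(estimates, summaries)
  list(summaries = summaries, stats = stats_report)
}

# ANOVA / pairwise Welch / gradient comparisons mirroring the study's tables.
summarize_tests <- function(estimates, summaries) {
  rows <- list()
  add <- function(variable, comparison, statistic, df, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, comparison = comparison,
      statistic = signif(statistic, 3), df = signif(df, 4),
      p = signif(p, 3), stars = star_code(p), stringsAsFactors = FALSE)
  }
  for (cls in unique(estimates$cell_class)) {
    sub <- estimates[estimates$cell_class == cls, ]
    grp <- split(sub$k_hb_mN_per_m, sub$cf_khz)
    if (length(grp) >= 2) {
      av <- one_way_anova(grp)
      add("k_hb", paste0("ANOVA across locations (", cls, ")"), av$f,
          av$df2, av$p)
      cfs <- names(grp)
      for (i in seq_len(length(grp) - 1)) {
        wt <- safe_welch(grp[[i]], grp[[i + 1]])
        if (!is.null(wt))
          add("k_hb", sprintf("%s %s vs %s kHz", cls, cfs[i], cfs[i + 1]),
              wt$t, wt$df, wt$p)
      }
    }
  }
  # OHC vs IHC at shared locations
  shared <- intersect(unique(estimates$cf_khz[estimates$cell_class == "OHC"]),
                      unique(estimates$cf_khz[estimates$cell_class == "IHC"]))
  for (cf in shared) {
    a <- estimates$k_hb_mN_per_m[estimates$cell_class == "OHC" & estimates$cf_khz == cf]
    b <- estimates$k_hb_mN_per_m[estimates$cell_class == "IHC" & estimates$cf_khz == cf]
    if (length(a) >= 2 && length(b) >= 2) {
      wt <- safe_welch(a, b)
      if (!is.null(wt))
        add("k_hb", sprintf("OHC vs IHC at %g kHz", cf), wt$t, wt$df, wt$p)
    }
  }
  # weighted gradients and slope comparison per variable
  grads <- list()
  for (v in c("k_hb", "t_link_rest")) {
    for (cls in c("OHC", "IHC")) {
      s <- summaries[summaries$variable == v & summaries$cell_class == cls, ]
      if (nrow(s) >= 2)
        grads[[paste(v, cls)]] <- tryCatch(
          suppressWarnings(weighted_gradient(s$cf_khz, s$mean, s$sem)),
          error = function(e) NULL)
    }
    fa <- grads[[paste(v, "OHC")]]; fb <- grads[[paste(v, "IHC")]]
    if (!is.null(fa) && !is.null(fb)) {
      cs <- tryCatch(compare_slopes(fa, fb), error = function(e) NULL)
      if (!is.null(cs)) add(v, "Gradient OHC vs gradient IHC", cs$t, cs$df, cs$p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), comparison = character(),
               statistic = numeric(), df = numeric(), p = numeric(),
               stars = character(), stringsAsFactors = FALSE)
  attr(out, "gradients") <- grads
  out
}

# Welch test that degrades gracefully on degenerate (constant) groups.
safe_welch <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = Inf, df = length(a) + length(b) - 2, p = 0))
  }
  tryCatch(welch_ttest(a, b), error = function(e) NULL)
}
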