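# Shared fixtures: small ground-truth records and canonical geometry, built
# in code at test time.

fake_cell <- function(k_hb = 2.5, r = 0.2, creep = 0.12, dx_r = 9, dx_ca = -26,
                      n_tl = 38, i_max = 600, cell_class = "OHC", cf = 1,
                      h = 5.196, w = 6, n_sp = 45, gamma = 0.1,
                      noise_pos = 0, noise_cur = 0, seed = 99) {
  data.frame(cell_id = "test", cell_class = cell_class, cf_khz = cf,
             h_um = h, w_um = w, n_sp = n_sp, gamma = gamma,
             k_hb_true = k_hb, r_true = r, creep_frac_true = creep,
             dx_r_true = dx_r, dx_ca_true = dx_ca, n_tl_true = n_tl,
             i_max_true = i_max, noise_sd_pos = noise_pos,
             noise_sd_cur = noise_cur, cell_seed = seed,
             stringsAsFactors = FALSE)
}

default_jet <- function() default_settings()$jet

# Group summaries of a per-location chain built directly from the default
# priors (no simulation): means are the deterministic products, sems are
# propagated from the per-location prior scatter at the printed n.
chain_summary <- function(m, what = c("t_link_rest", "t_link_max", "k_gs_single")) {
  what <- match.arg(what)
  n <- m$n_cells
  r_sem <- 0.1 / sqrt(n)
  ntl_rel_sem <- 0.10 / sqrt(n)
  ksp <- (1 - m$r_mean) * m$k_hb_mean
  tr <- ksp * m$dx_r_mean / (m$gamma * m$n_tl)
  if (what == "t_link_rest") {
    ps <- product_sem(c(1 - m$r_mean, m$k_hb_mean, m$dx_r_mean, 1 / m$n_tl),
                      c(r_sem, m$k_hb_sem, m$dx_r_sem, ntl_rel_sem / m$n_tl),
                      rep(n, 4))
    return(c(mean = ps$product / m$gamma, sem = ps$sigma_p / m$gamma))
  }
  if (what == "k_gs_single") {
    ps <- product_sem(c(m$r_mean, m$k_hb_mean, 1 / m$n_tl),
                      c(r_sem, m$k_hb_sem, ntl_rel_sem / m$n_tl),
                      rep(n, 3))
    return(c(mean = ps$product / m$gamma^2, sem = ps$sigma_p / m$gamma^2))
  }
  ps <- product_sem(c(1 - m$r_mean, m$k_hb_mean, -m$dx_ca_mean, 1 / m$n_tl),
                    c(r_sem, m$k_hb_sem, m$dx_ca_sd / sqrt(n), ntl_rel_sem / m$n_tl),
                    rep(n, 4))
  c(mean = tr + ps$product / m$gamma, sem = ps$sigma_p / m$gamma)
}
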