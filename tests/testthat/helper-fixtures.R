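# shared helpers: random parameter draws and random valid histories

rand_params <- function(n_occasions, min = 0.05, max = 0.95) {
  r <- function() stats::runif(1, min, max)
  param_set(phi_B = r(), phi_NB = r(), psi_BB = r(), psi_NBB = r(),
            m_B = r(), m_NB = r(), p_u = r(), b_e = r(),
            n_occasions = n_occasions)
}

# random event suffix beginning with a breeding-season event
rand_history <- function(len) {
  c(sample(c(1L, 2L, 3L, 5L, 6L, 7L), 1L),
    if (len > 1L) sample(0:7, len - 1L, replace = TRUE))
}

# quick event-level dataset for fitting tests
quick_sim <- function(n = 200, T = 6, seed = 1, ...) {
  cfg <- sim_config(n_occasions = T, cohorts = c(n, rep(0L, T - 1L)), ...)
  simulate_histories(cfg, seed = seed)
}
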