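# shared fixtures, computed lazily and cached for the whole test run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# full +-180 min STC window sweep at standard parameters (37 cells)
full_window_sweep <- function() {
  memo("window_sweep", stc_window_sweep(stc_params(), -180, 180, 10))
}

# single-spine e-LTP trajectory at standard parameters
eltp_trajectory <- function() {
  memo("eltp_traj", {
    stc_integrate(stc_params(N = 1), make_schedule(n_E = 1, s_E1_min = 0))
  })
}

# single-spine l-LTP trajectory at standard parameters
lltp_trajectory <- function() {
  memo("lltp_traj", {
    stc_integrate(stc_params(N = 1), make_schedule(n_E = 0, lltp_at_min = 0))
  })
}

# experiment II mu_Pd scans at n_E = 5, ds_E = 5 (21 levels each window)
exp2_scan <- function(s_E1) {
  memo(paste0("exp2_", s_E1),
       experiment_II(stc_params(), n_E = 5, s_E1_min = s_E1, ds_E_min = 5))
}

# random valid state for property tests (components within their ranges)
random_state <- function(N) {
  Z <- runif(N, 0.05, 0.3)
  stc_state(U_d = runif(1), M_d = runif(1, 0, 2), P_d = runif(1, 0, 1),
            U_s = runif(N), T_p = runif(N, 0, 1), P_s = runif(N, 0, 1),
            Z = Z, W = Z + runif(N, 0, 0.4))
}
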