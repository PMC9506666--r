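#' Right-hand side of the STC model (reference R implementation)
#'
#' Evaluates the time derivative of the full state for a given instantaneous
#' stimulus vector `Y` (0/1 per spine) and drug multiplier on `alpha_Ud`.
#' The production integrator uses a C translation of the same equations
#' compiled into the package; this R version is the readable reference used
#' by the test oracles.
#'
#' The equations (per spine `n`, shared dendritic pool without superscript):
#' \deqn{dU_s^{[n]}/dt = k_{Us} W^{[n]} Y^{[n]} (1 - U_s^{[n]}) - \beta_{Us} U_s^{[n]}}
#' \deqn{dU_d/dt = k_{Ud} \Theta[\sum_n \alpha_{Ud} \beta_{Us} U_s^{[n]}, K_{Ud}, h_{Ud}] (1 - U_d) - \beta_{Ud} U_d}
#' \deqn{dM_d/dt = -(M_d - \mu_{Md})/\tau_{Md} - k_{Pd} \Theta[U_d, K_{Pd}, h_{Pd}] M_d}
#' \deqn{dP_d/dt = -(P_d - \mu_{Pd})/\tau_{Pd} + k_{Pd} \Theta[U_d, K_{Pd}, h_{Pd}] M_d
#'   - \sum_n k_{Ps} \Theta[P_d T_p^{[n]}, K_{Ps}, h_{Ps}] + \sum_n \beta_{Ps} P_s^{[n]}}
#' \deqn{dT_p^{[n]}/dt = k_{TP} W^{[n]} \Theta[U_s^{[n]}, K_{TP}, h_{TP}] (1 - T_p^{[n]}) - (T_p^{[n]} - \mu_{TP})/\tau_{TP}}
#' \deqn{dP_s^{[n]}/dt = k_{Ps} \Theta[P_d T_p^{[n]}, K_{Ps}, h_{Ps}] - \beta_{Ps} P_s^{[n]}
#'   - k_Z \Theta[P_s^{[n]}, K_Z, h_Z] (W^{[n]} - Z^{[n]})}
#' \deqn{dZ^{[n]}/dt = k_Z \Theta[P_s^{[n]}, K_Z, h_Z] (W^{[n]} - Z^{[n]})}
#' \deqn{dW^{[n]}/dt = k_W \Theta[U_s^{[n]}, K_W, h_W] (1 + U_d) - W^{[n]} (W^{[n]} - Z^{[n]})/\tau_W}
#'
#' @param t time, s (the RHS is autonomous given `Y` and `alpha_mult`).
#' @param y packed state vector (see [stc_state()]), length `3 + 5 N`.
#' @param params an [stc_params()] object.
#' @param Y per-spine stimulus intensity, each 0 or 1, length `N`.
#' @param alpha_mult multiplier applied to `alpha_Ud` (the bath-applied
#'   FSK/SKF drug factor; `lltp_gain` while an l-LTP drug window is open,
#'   otherwise 1).
#' @return named derivative vector, same layout as `y`.
#' @export
stc_rhs <- function(t, y, params, Y, alpha_mult = 1) {
  p <- params
  N <- p$N
  if (length(y) != 3L + 5L * N)
    stop("state length ", length(y), " does not match N = ", N)
  if (length(Y) != N)
    stop("stimulus vector length ", length(Y), " does not match N = ", N)
  s <- stc_unpack(y)

  dU_s <- p$k_Us * s$W * Y * (1 - s$U_s) - p$beta_Us * s$U_s

  # hill() inputs are clamped at 0: an adaptive solver may overshoot a
  # variable to -1e-15 between accepted steps
  drive <- sum(alpha_mult * p$alpha_Ud * p$beta_Us * s$U_s)
  dU_d <- p$k_Ud * hill(max(drive, 0), p$K_Ud, p$h_Ud) * (1 - s$U_d) -
    p$beta_Ud * s$U_d

  synth <- p$k_Pd * hill(max(s$U_d, 0), p$K_Pd, p$h_Pd) * s$M_d
  dM_d <- -(s$M_d - p$mu_Md) / p$tau_Md - synth

  capture <- p$k_Ps * hill(pmax(s$P_d * s$T_p, 0), p$K_Ps, p$h_Ps)
  dP_d <- -(s$P_d - p$mu_Pd) / p$tau_Pd + synth -
    sum(capture) + sum(p$beta_Ps * s$P_s)

  us <- pmax(s$U_s, 0)
  dT_p <- p$k_TP * s$W * hill(us, p$K_TP, p$h_TP) * (1 - s$T_p) -
    (s$T_p - p$mu_TP) / p$tau_TP

  consume <- p$k_Z * hill(pmax(s$P_s, 0), p$K_Z, p$h_Z) * (s$W - s$Z)
  dP_s <- capture - p$beta_Ps * s$P_s - consume
  dZ <- consume

  dW <- p$k_W * hill(us, p$K_W, p$h_W) * (1 + s$U_d) -
    s$W * (s$W - s$Z) / p$tau_W

  stc_state(dU_d, dM_d, dP_d, dU_s, dT_p, dP_s, dZ, dW)
}
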