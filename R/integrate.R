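# parameter vector handed to the compiled RHS; Y padded to 20 slots
#' @noRd
build_parvec <- function(p, Y, alpha_mult) {
  c(p$N,
    p$k_Us, p$beta_Us,
    p$k_Ud, p$alpha_Ud * alpha_mult, p$beta_Ud, p$K_Ud, p$h_Ud,
    p$tau_Md, p$tau_Pd, p$mu_Md, p$mu_Pd,
    p$k_Pd, p$K_Pd, p$h_Pd,
    p$k_Ps, p$K_Ps, p$h_Ps, p$beta_Ps,
    p$k_TP, p$K_TP, p$h_TP, p$tau_TP, p$mu_TP,
    p$k_Z, p$K_Z, p$h_Z,
    p$k_W, p$K_W, p$h_W, p$tau_W,
    c(Y, rep(0, 20L - p$N)))
}

#' @noRd
default_span <- function(schedule, buffer_s = 600, horizon_s = 180 * 60) {
  onsets <- schedule_onsets(schedule)
  c(min(onsets) - buffer_s, max(onsets) + horizon_s)
}

#' Integrate the STC model over a stimulation schedule
#'
#' Piecewise integration of the eight-equation system: the right-hand side
#' is smooth between pulse and drug-window edges, so the trajectory is
#' advanced segment by segment with `deSolve::ode` (LSODA, compiled RHS) and
#' a mandatory breakpoint at every edge — a 5-ms uncaging pulse drives
#' `U_s` at ~100 / s and must never be stepped over. Within segments the
#' stimulus vector `Y` and the drug multiplier on `alpha_Ud` are constant.
#'
#' The run starts 10 min before the earliest protocol onset from the
#' unstimulated fixed point ([steady_state_baseline()]) and extends to
#' 180 min past the latest onset, so every spine's volume readout time is
#' covered. All sampled states are checked against the model invariants
#' (activities and tag in `[0, 1]`, concentrations nonnegative, `W >= Z`).
#'
#' @param params an [stc_params()] object; `params$N` must equal the number
#'   of spines in the schedule.
#' @param schedule an [make_schedule()] schedule.
#' @param sample_dt output sampling interval, s.
#' @param t_start,t_end simulation span, s; defaults to
#'   `min(onset) - 600` and `max(onset) + 10800`.
#' @param init_state initial packed state; default the baseline fixed point.
#' @param rtol,atol solver tolerances.
#' @param engine `"compiled"` (default) or `"R"` (reference RHS, slow; used
#'   for cross-checks).
#' @param check_invariants tolerance for the post-hoc state-invariant check;
#'   set `NA` to skip.
#' @return an `stc_trajectory`: list with `times` (s), `states` (matrix,
#'   one row per sample, columns named as in [stc_state()]), `schedule`,
#'   `params`, `solver_meta`.
#' @export
stc_integrate <- function(params, schedule, sample_dt = 10,
                          t_start = NULL, t_end = NULL, init_state = NULL,
                          rtol = 1e-8, atol = 1e-10,
                          engine = c("compiled", "R"),
                          check_invariants = 1e-6) {
  engine <- match.arg(engine)
  validate_stc_params(params)
  stopifnot(inherits(schedule, "stc_schedule"), sample_dt > 0)
  if (params$N != schedule$n)
    stop("params$N (", params$N, ") does not match schedule spine count (",
         schedule$n, ")")
  span <- default_span(schedule)
  if (is.null(t_start)) t_start <- span[1L]
  if (is.null(t_end)) t_end <- span[2L]
  stopifnot(t_end > t_start)
  if (is.null(init_state)) init_state <- steady_state_baseline(params)

  onsets <- schedule_onsets(schedule)
  readouts <- onsets + 180 * 60
  samples <- sort(unique(c(seq(t_start, t_end, by = sample_dt),
                           readouts[readouts >= t_start & readouts <= t_end],
                           t_end)))
  bps <- schedule_breakpoints(schedule)
  bps <- bps[bps > t_start & bps < t_end]
  knots <- sort(unique(c(t_start, bps, t_end)))

  rfunc <- NULL
  if (engine == "R") {
    rfunc <- function(t, y, parms) {
      list(stc_rhs(t, y, params, Y = parms$Y, alpha_mult = parms$alpha_mult))
    }
  }

  y <- init_state
  nvar <- length(y)
  rows <- vector("list", length(knots) - 1L)
  times_out <- vector("list", length(knots) - 1L)
  n_steps <- 0L
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    inp <- schedule_inputs_at(schedule, (a + b) / 2, params$lltp_gain)
    tt <- sort(unique(c(a, samples[samples > a & samples < b], b)))
    sol <- if (engine == "compiled") {
      deSolve::ode(y = y, times = tt, func = "stc_derivs",
                   parms = build_parvec(params, inp$Y, inp$alpha_mult),
                   dllname = "stcsim", initfunc = "stc_init",
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 1e5)
    } else {
      deSolve::ode(y = y, times = tt, func = rfunc,
                   parms = list(Y = inp$Y, alpha_mult = inp$alpha_mult),
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 1e5)
    }
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed on interval [", a, ", ", b, "] s")
    n_steps <- n_steps + attr(sol, "istate")[3L]
    y <- sol[nrow(sol), -1L]
    keep <- tt %in% samples
    keep[length(keep)] <- keep[length(keep)] & (i == length(knots) - 1L)
    if (any(keep)) {
      rows[[i]] <- sol[keep, -1L, drop = FALSE]
      times_out[[i]] <- tt[keep]
    }
  }
  states <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  times <- unlist(times_out)
  colnames(states) <- state_names(params$N)
  traj <- structure(
    list(times = times, states = states, schedule = schedule,
         params = params,
         solver_meta = list(engine = engine, rtol = rtol, atol = atol,
                            sample_dt = sample_dt, n_segments =
                              length(knots) - 1L, n_steps = n_steps)),
    class = "stc_trajectory")
  if (!is.na(check_invariants))
    check_trajectory(traj, tol = check_invariants)
  traj
}

#' Check state invariants along a trajectory
#'
#' Asserts, at every sample: `0 <= U_s, U_d <= 1`; `0 <= T_p <= 1`;
#' `P_s, P_d, M_d >= 0`; and `W >= Z` componentwise, all up to `tol` for
#' solver overshoot.
#'
#' @param traj an `stc_trajectory`.
#' @param tol numerical tolerance.
#' @return `TRUE` invisibly, or an error naming the violated bound.
#' @export
check_trajectory <- function(traj, tol = 1e-6) {
  st <- traj$states
  N <- traj$params$N
  ix <- state_index(N)
  chk <- function(ok, what) if (!all(ok))
    stop("trajectory violates invariant: ", what)
  unit <- function(v) v >= -tol & v <= 1 + tol
  chk(unit(st[, ix$U_d]), "0 <= U_d <= 1")
  chk(unit(st[, ix$U_s]), "0 <= U_s <= 1")
  chk(unit(st[, ix$T_p]), "0 <= T_p <= 1")
  chk(st[, ix$M_d] >= -tol, "M_d >= 0")
  chk(st[, ix$P_d] >= -tol, "P_d >= 0")
  chk(st[, ix$P_s] >= -tol, "P_s >= 0")
  chk(st[, ix$W, drop = FALSE] - st[, ix$Z, drop = FALSE] >= -tol, "W >= Z")
  invisible(TRUE)
}

#' Spine head volume 180 min after a spine's stimulation onset
#'
#' The universal readout of potentiation outcome: `W` of the given spine at
#' exactly its protocol onset + 180 min (linear interpolation between
#' trajectory samples; the integrator places a sample at the exact readout
#' time, so interpolation is normally a no-op).
#'
#' @param traj an `stc_trajectory`.
#' @param spine spine label, e.g. `"E1"` or `"L1"`.
#' @return volume in um^3.
#' @export
readout_W180 <- function(traj, spine) {
  labels <- schedule_labels(traj$schedule)
  k <- match(spine, labels)
  if (is.na(k)) stop("unknown spine label: ", spine)
  t_star <- traj$schedule$spines[[k]]$onset_s + 180 * 60
  if (t_star > max(traj$times) + 1e-9)
    stop("trajectory ends before ", spine, "'s readout time (",
         t_star, " s)")
  w <- traj$states[, state_index(traj$params$N)$W[k]]
  stats::approx(traj$times, w, xout = t_star, rule = 1)$y
}

#' Fixed-step RK4 reference integrator
#'
#' Brute-force classical Runge-Kutta over the same piecewise-smooth
#' segments as [stc_integrate()], using the pure-R right-hand side
#' [stc_rhs()]. Slow by construction; serves as the independent oracle for
#' the adaptive compiled path.
#'
#' @inheritParams stc_integrate
#' @param dt_pulse step size during stimulus pulses, s.
#' @param dt_base step size elsewhere, s.
#' @return an `stc_trajectory` (invariant check skipped; the oracle is
#'   compared against the production path instead).
#' @export
stc_integrate_rk4 <- function(params, schedule, sample_dt = 10,
                              t_start = NULL, t_end = NULL,
                              init_state = NULL,
                              dt_pulse = 1e-4, dt_base = 1e-2) {
  validate_stc_params(params)
  stopifnot(inherits(schedule, "stc_schedule"))
  if (params$N != schedule$n) stop("params$N does not match schedule")
  span <- default_span(schedule)
  if (is.null(t_start)) t_start <- span[1L]
  if (is.null(t_end)) t_end <- span[2L]
  if (is.null(init_state)) init_state <- steady_state_baseline(params)

  samples <- sort(unique(c(seq(t_start, t_end, by = sample_dt), t_end)))
  bps <- schedule_breakpoints(schedule)
  bps <- bps[bps > t_start & bps < t_end]
  knots <- sort(unique(c(t_start, bps, t_end, samples)))

  y <- init_state
  out <- matrix(NA_real_, nrow = length(samples), ncol = length(y),
                dimnames = list(NULL, state_names(params$N)))
  if (knots[1L] %in% samples) out[1L, ] <- y
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    inp <- schedule_inputs_at(schedule, (a + b) / 2, params$lltp_gain)
    dt <- if (any(inp$Y > 0)) dt_pulse else dt_base
    nstep <- max(1L, ceiling((b - a) / dt))
    h <- (b - a) / nstep
    f <- function(yy) stc_rhs(a, yy, params, inp$Y, inp$alpha_mult)
    for (s in seq_len(nstep)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    j <- match(b, samples)
    if (!is.na(j)) out[j, ] <- y
  }
  structure(list(times = samples, states = out, schedule = schedule,
                 params = params,
                 solver_meta = list(engine = "rk4", dt_pulse = dt_pulse,
                                    dt_base = dt_base,
                                    sample_dt = sample_dt)),
            class = "stc_trajectory")
}

#' @export
print.stc_trajectory <- function(x, ...) {
  cat("STC trajectory:", length(x$times), "samples,",
      x$params$N, "spine(s),",
      sprintf("t = [%.0f, %.0f] s", min(x$times), max(x$times)), "\n")
  cat("  engine:", x$solver_meta$engine, "\n")
  invisible(x)
}

#' Tidy long-format export of a trajectory
#'
#' @param x an `stc_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame with columns `time_s`, `variable`, `spine_label`
#'   (`NA` for the shared dendritic variables), `value`.
#' @export
as.data.frame.stc_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  N <- x$params$N
  labels <- schedule_labels(x$schedule)
  cols <- colnames(x$states)
  var <- sub("[0-9]+$", "", cols)
  spine_ix <- suppressWarnings(as.integer(sub("^[A-Za-z_]+", "", cols)))
  spine <- ifelse(is.na(spine_ix), NA_character_, labels[spine_ix])
  data.frame(
    time_s = rep(x$times, times = length(cols)),
    variable = rep(var, each = length(x$times)),
    spine_label = rep(spine, each = length(x$times)),
    value = as.vector(x$states),
    stringsAsFactors = FALSE)
}
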