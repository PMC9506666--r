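#' Sweep the timing of the weak (e-LTP) protocol against a fixed l-LTP
#' protocol
#'
#' The classic two-pathway late-associativity experiment: spine L1 receives
#' the l-LTP protocol at t = 0; spine E1 receives the e-LTP protocol at
#' `s_E1` minutes, swept over a grid. Each cell is an independent two-spine
#' simulation; the readout is each spine's head volume 180 min after its
#' own protocol onset.
#'
#' @param params an [stc_params()] object (its `N` is overridden to 2).
#' @param s_min,s_max sweep range of `s_E1`, minutes.
#' @param step grid step, minutes (> 0).
#' @param ... passed to [stc_integrate()] (e.g. `rtol`).
#' @return an `stc_window_result` data.frame with columns `s_E1_min`,
#'   `W180_E1`, `W180_L1`, and attributes `step_min`, `params`. A cell whose
#'   integration fails is reported as `NA` with a warning, without aborting
#'   the sweep.
#' @export
stc_window_sweep <- function(params, s_min = -180, s_max = 180, step = 10,
                             ...) {
  stopifnot(step > 0, s_min <= s_max)
  params$N <- 2L
  grid <- seq(s_min, s_max, by = step)
  res <- data.frame(s_E1_min = grid, W180_E1 = NA_real_, W180_L1 = NA_real_)
  for (i in seq_along(grid)) {
    cell <- tryCatch({
      sch <- make_schedule(n_E = 1, s_E1_min = grid[i], lltp_at_min = 0)
      traj <- stc_integrate(params, sch, ...)
      c(readout_W180(traj, "E1"), readout_W180(traj, "L1"))
    }, error = function(e) {
      warning("sweep cell s_E1 = ", grid[i], " min failed: ",
              conditionMessage(e))
      c(NA_real_, NA_real_)
    })
    res$W180_E1[i] <- cell[1L]
    res$W180_L1[i] <- cell[2L]
  }
  structure(res, step_min = step, params = params,
            class = c("stc_window_result", "data.frame"))
}

#' Width of the effective STC window on one side of t = 0
#'
#' A grid cell is "effective" when E1's 180-min volume exceeds the baseline
#' volume by more than `epsilon`. The width is the extent (max - min of
#' `s_E1`) of the maximal contiguous run of effective cells on the chosen
#' side of zero (the side includes `s_E1 = 0`).
#'
#' @param result an `stc_window_result` from [stc_window_sweep()] on a
#'   uniform grid.
#' @param side `"left"` (`s_E1 <= 0`) or `"right"` (`s_E1 >= 0`).
#' @param epsilon effectiveness threshold above baseline, um^3.
#' @param W0 baseline spine head volume, um^3.
#' @return width in minutes (0 if no cell is effective).
#' @export
window_width <- function(result, side = c("left", "right"),
                         epsilon = 0.005, W0 = 0.10) {
  side <- match.arg(side)
  s <- result$s_E1_min
  if (length(s) > 1L) {
    d <- diff(s)
    if (max(abs(d - d[1L])) > 1e-9)
      stop("window_width() requires a uniform s_E1 grid")
  }
  keep <- if (side == "left") s <= 0 else s >= 0
  s <- s[keep]
  eff <- result$W180_E1[keep] > W0 + epsilon
  eff[is.na(eff)] <- FALSE
  if (!any(eff)) return(0)
  runs <- rle(eff)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  max(s[starts[best]:ends[best]]) - min(s[starts[best]:ends[best]])
}

#' Synchronized competition for the shared PRP pool (Experiment I)
#'
#' `n_E` spines receive the e-LTP protocol at exactly the same time `s_E1`
#' while L1 receives the l-LTP protocol at t = 0, for every combination of
#' `n_E`, basal PRP level and `s_E1` on the requested grids. All E-spines
#' are biochemically equivalent and synchronously driven, so their
#' trajectories coincide; E1's readout represents the group.
#'
#' @param params an [stc_params()] object (`N` set per cell).
#' @param n_E_values vector of E-spine counts (each `n_E + 1 <= 20`).
#' @param mu_Pd_values vector of basal PRP levels.
#' @param s_min,s_max,step `s_E1` grid, minutes.
#' @param ... passed to [stc_integrate()].
#' @return data.frame with columns `n_E`, `mu_Pd`, `s_E1_min`, `W180_E1`,
#'   `W180_L1`; failed cells are `NA` with a warning.
#' @export
experiment_I <- function(params, n_E_values, mu_Pd_values = params$mu_Pd,
                         s_min = -180, s_max = 180, step = 10, ...) {
  stopifnot(all(n_E_values >= 1), all(n_E_values + 1 <= 20), step > 0)
  grid <- expand.grid(n_E = as.integer(n_E_values), mu_Pd = mu_Pd_values,
                      s_E1_min = seq(s_min, s_max, by = step),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$n_E, grid$mu_Pd, grid$s_E1_min), , drop = FALSE]
  rownames(grid) <- NULL
  grid$W180_E1 <- NA_real_
  grid$W180_L1 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cell <- tryCatch({
      p <- params
      p$mu_Pd <- grid$mu_Pd[i]
      p$N <- grid$n_E[i] + 1L
      sch <- make_schedule(n_E = grid$n_E[i], s_E1_min = grid$s_E1_min[i],
                           lltp_at_min = 0, synchronized = TRUE)
      traj <- stc_integrate(p, sch, ...)
      c(readout_W180(traj, "E1"), readout_W180(traj, "L1"))
    }, error = function(e) {
      warning("experiment I cell (n_E = ", grid$n_E[i], ", mu_Pd = ",
              grid$mu_Pd[i], ", s_E1 = ", grid$s_E1_min[i], ") failed: ",
              conditionMessage(e))
      c(NA_real_, NA_real_)
    })
    grid$W180_E1[i] <- cell[1L]
    grid$W180_L1[i] <- cell[2L]
  }
  grid
}

#' Intragroup mean and standard deviation of post-enhancement volumes
#'
#' Population statistics over the E-spines of one stimulation pattern:
#' mean of the 180-min volumes, and the intragroup standard deviation
#' \eqn{S_g = \sqrt{(1/N) \sum_n (W_{180}^{[n]} - \bar W_{180})^2}}
#' (divisor `N`, not `N - 1`).
#'
#' @param W180 numeric vector of per-spine volumes.
#' @return list with `mean` and `S_g`.
#' @export
intragroup_stats <- function(W180) {
  stopifnot(is.numeric(W180), length(W180) >= 1)
  m <- mean(W180)
  list(mean = m, S_g = sqrt(mean((W180 - m)^2)))
}

#' Asynchronous competition for the shared PRP pool (Experiment II)
#'
#' L1 receives the l-LTP protocol at t = 0; `n_E` spines receive e-LTP
#' protocols whose onsets recede from zero starting at `s_E1` with equal
#' interval `ds_E` (left window for `s_E1 < 0`, right window for
#' `s_E1 > 0`). For each basal PRP level the per-spine 180-min volumes, the
#' intragroup mean and standard deviation, and the enhancement-type label
#' ([classify_type()]) are returned.
#'
#' @param params an [stc_params()] object (`N` set to `n_E + 1`).
#' @param n_E number of E-spines.
#' @param s_E1_min onset of E1, minutes; must be nonzero.
#' @param ds_E_min interval between consecutive E-spines, minutes.
#' @param mu_Pd_values basal PRP levels to scan (default: the published
#'   grid, `10^seq(-4, 0, by = 0.2)`).
#' @param ... passed to [stc_integrate()].
#' @return data.frame with one row per (`mu_Pd`, spine): columns `n_E`,
#'   `s_E1_min`, `ds_E_min`, `mu_Pd`, `synapse_label`, `W180_um3`,
#'   `W180_mean`, `S_g`, `type_label`.
#' @export
experiment_II <- function(params, n_E, s_E1_min, ds_E_min,
                          mu_Pd_values = 10^seq(-4, 0, by = 0.2), ...) {
  stopifnot(n_E >= 3, n_E + 1 <= 20, ds_E_min >= 0)
  if (s_E1_min == 0) stop("s_E1 must be nonzero (left or right window)")
  out <- vector("list", length(mu_Pd_values))
  labels <- paste0("E", seq_len(n_E))
  for (i in seq_along(mu_Pd_values)) {
    p <- params
    p$mu_Pd <- mu_Pd_values[i]
    p$N <- as.integer(n_E) + 1L
    row <- tryCatch({
      sch <- make_schedule(n_E = n_E, s_E1_min = s_E1_min,
                           ds_E_min = ds_E_min, lltp_at_min = 0)
      traj <- stc_integrate(p, sch, ...)
      w <- vapply(labels, function(l) readout_W180(traj, l), numeric(1))
      st <- intragroup_stats(w)
      data.frame(n_E = n_E, s_E1_min = s_E1_min, ds_E_min = ds_E_min,
                 mu_Pd = mu_Pd_values[i], synapse_label = labels,
                 W180_um3 = unname(w), W180_mean = st$mean, S_g = st$S_g,
                 type_label = classify_type(w), stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("experiment II cell mu_Pd = ", mu_Pd_values[i], " failed: ",
              conditionMessage(e))
      data.frame(n_E = n_E, s_E1_min = s_E1_min, ds_E_min = ds_E_min,
                 mu_Pd = mu_Pd_values[i], synapse_label = labels,
                 W180_um3 = NA_real_, W180_mean = NA_real_, S_g = NA_real_,
                 type_label = NA_character_, stringsAsFactors = FALSE)
    })
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Classify the enhancement tendency across asynchronously stimulated
#' spines
#'
#' Operational classifier of the qualitative volume orderings observed
#' across E1..En after asynchronous stimulation:
#' \describe{
#'   \item{IV}{nearly equal volumes: `max - min < flat_tol * mean`.}
#'   \item{I}{volumes decreasing with spine index (E1 largest).}
#'   \item{III}{volumes increasing with spine index (En largest).}
#'   \item{II}{downward-convex: decreasing to a single interior minimum,
#'     then increasing.}
#'   \item{unclassified}{anything else (regime boundaries).}
#' }
#' Monotonicity is judged on a 3-point moving average with slack
#' `trend_tol * mean`, to absorb single-cell jitter.
#'
#' @param W180 per-spine volumes ordered E1..En (n >= 3).
#' @param flat_tol flatness tolerance, fraction of the group mean.
#' @param trend_tol trend tolerance, fraction of the group mean.
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`, `"unclassified"`.
#' @examples
#' classify_type(c(0.5, 0.4, 0.3, 0.2, 0.1))    # "I"
#' classify_type(c(0.3, 0.1, 0.1, 0.2, 0.4))    # "II"
#' @export
classify_type <- function(W180, flat_tol = 0.05, trend_tol = 0.02) {
  n <- length(W180)
  if (n < 3L) stop("classification needs at least 3 spines")
  m <- mean(W180)
  if (max(W180) - min(W180) < flat_tol * m) return("IV")
  s <- vapply(seq_len(n), function(i)
    mean(W180[max(1L, i - 1L):min(n, i + 1L)]), numeric(1))
  tol <- trend_tol * m
  d <- diff(s)
  net <- s[n] - s[1L]
  if (all(d <= tol) && net < -tol) return("I")
  if (all(d >= -tol) && net > tol) return("III")
  k <- which.min(s)
  if (k > 1L && k < n &&
      all(d[seq_len(k - 1L)] <= tol) && all(d[k:(n - 1L)] >= -tol) &&
      s[1L] - s[k] > tol && s[n] - s[k] > tol)
    return("II")
  "unclassified"
}
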