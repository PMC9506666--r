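PULSE_DUR_S <- 0.005   # glutamate-uncaging pulse length
PULSE_PERIOD_S <- 2.0  # 0.5 Hz
N_PULSES <- 30L

#' e-LTP induction pulse train
#'
#' 30 rectangular pulses of 5 ms at 0.5 Hz (amplitude Y = 1), the standard
#' glutamate-uncaging e-LTP protocol. Times are given in minutes at the
#' interface and stored in seconds.
#'
#' @param onset_min onset of the first pulse, minutes.
#' @return a two-column matrix `(start_s, end_s)`, one row per pulse.
#' @examples
#' tr <- make_eltp_protocol(0)
#' nrow(tr)           # 30
#' tr[2, 1]           # 2.0 s
#' @export
make_eltp_protocol <- function(onset_min) {
  t0 <- onset_min * 60
  starts <- t0 + PULSE_PERIOD_S * (seq_len(N_PULSES) - 1L)
  cbind(start_s = starts, end_s = starts + PULSE_DUR_S)
}

#' l-LTP induction protocol
#'
#' The same 30 x 5 ms / 0.5 Hz train as the e-LTP protocol, plus a drug
#' window during which the bath-applied PKA/D1R agonists (FSK/SKF) multiply
#' `alpha_Ud` by `lltp_gain`. By default the window spans the pulse train
#' (first pulse onset to last pulse offset, 58.005 s); a fixed bath duration
#' can be requested instead.
#'
#' @param onset_min onset of the first pulse, minutes.
#' @param drug_duration_s optional drug-window length in seconds measured
#'   from the first pulse; default `NULL` means the train span.
#' @return list with `pulses` (matrix as in [make_eltp_protocol()]) and
#'   `drug_window` (length-2 numeric, seconds).
#' @export
make_lltp_protocol <- function(onset_min, drug_duration_s = NULL) {
  pulses <- make_eltp_protocol(onset_min)
  t0 <- unname(pulses[1L, 1L])
  t1 <- if (is.null(drug_duration_s)) unname(pulses[N_PULSES, 2L]) else {
    stopifnot(drug_duration_s > 0)
    t0 + drug_duration_s
  }
  list(pulses = pulses, drug_window = c(t0, t1))
}

#' Build a multi-spine stimulation schedule
#'
#' Assembles the per-spine pulse trains of a competition experiment:
#' `n_E` spines `E1..En` receive the e-LTP protocol and, optionally, one
#' spine `L1` receives the l-LTP protocol. When `synchronized`, all E-spines
#' are stimulated at `s_E1`. Otherwise the onsets recede from t = 0:
#' E-spine k starts at `s_E1 + sign(s_E1) * (k - 1) * ds_E` minutes, so that
#' E1 is always the E-spine stimulated closest to time zero (left window for
#' `s_E1 < 0`, right window for `s_E1 > 0`).
#'
#' @param n_E number of e-LTP spines (>= 0).
#' @param s_E1_min onset of E1's protocol, minutes.
#' @param ds_E_min interval between consecutive E-spines, minutes (>= 0).
#' @param lltp_at_min onset of L1's l-LTP protocol in minutes, or `NULL`
#'   for no l-LTP spine.
#' @param synchronized if `TRUE` all E-spines share the onset `s_E1_min`.
#' @param drug_duration_s passed to [make_lltp_protocol()].
#' @return an `stc_schedule`: list with `spines` (each with `label`,
#'   `protocol`, `onset_s`, `pulses`), `drug_windows` matrix, `n` spines,
#'   and the scheduling arguments.
#' @examples
#' sch <- make_schedule(n_E = 3, s_E1_min = -10, ds_E_min = 5,
#'                      lltp_at_min = 0)
#' sapply(sch$spines, `[[`, "label")    # "L1" "E1" "E2" "E3"
#' @export
make_schedule <- function(n_E, s_E1_min = 0, ds_E_min = 0,
                          lltp_at_min = NULL, synchronized = FALSE,
                          drug_duration_s = NULL) {
  n_E <- as.integer(n_E)
  stopifnot(n_E >= 0, ds_E_min >= 0)
  n_tot <- n_E + as.integer(!is.null(lltp_at_min))
  if (n_tot < 1L) stop("schedule must stimulate at least one spine")
  if (n_tot > 20L)
    stop("spine budget exceeded: ", n_tot, " > 20")

  spines <- list()
  drug_windows <- matrix(numeric(0), ncol = 2,
                         dimnames = list(NULL, c("start_s", "end_s")))
  if (!is.null(lltp_at_min)) {
    lp <- make_lltp_protocol(lltp_at_min, drug_duration_s)
    spines[[1L]] <- list(label = "L1", protocol = "lltp",
                         onset_s = lltp_at_min * 60, pulses = lp$pulses)
    drug_windows <- rbind(drug_windows, lp$drug_window)
  }
  if (n_E > 0L) {
    onsets <- if (synchronized) rep(s_E1_min, n_E) else
      s_E1_min + sign(s_E1_min) * (seq_len(n_E) - 1L) * ds_E_min
    for (k in seq_len(n_E)) {
      spines[[length(spines) + 1L]] <-
        list(label = paste0("E", k), protocol = "eltp",
             onset_s = onsets[k] * 60,
             pulses = make_eltp_protocol(onsets[k]))
    }
  }
  structure(list(spines = spines, drug_windows = drug_windows,
                 n = n_tot, s_E1_min = if (n_E > 0L) s_E1_min else NA_real_,
                 ds_E_min = ds_E_min, synchronized = synchronized),
            class = "stc_schedule")
}

#' @export
print.stc_schedule <- function(x, ...) {
  cat("STC stimulation schedule:", x$n, "spine(s)\n")
  for (sp in x$spines)
    cat(sprintf("  %-3s %s onset %8.1f min (%d pulses)\n", sp$label,
                sp$protocol, sp$onset_s / 60, nrow(sp$pulses)))
  if (nrow(x$drug_windows))
    cat(sprintf("  drug window(s): %s\n",
                paste(apply(x$drug_windows, 1, function(w)
                  sprintf("[%.1f, %.1f] s", w[1], w[2])), collapse = ", ")))
  invisible(x)
}

#' Spine labels of a schedule
#' @param schedule an `stc_schedule`.
#' @return character vector of labels in spine order.
#' @export
schedule_labels <- function(schedule) {
  vapply(schedule$spines, `[[`, character(1), "label")
}

#' Protocol onsets of a schedule
#' @param schedule an `stc_schedule`.
#' @return named numeric vector of onsets in seconds.
#' @export
schedule_onsets <- function(schedule) {
  out <- vapply(schedule$spines, `[[`, numeric(1), "onset_s")
  names(out) <- schedule_labels(schedule)
  out
}

# all time points at which the piecewise-constant inputs switch
#' @noRd
schedule_breakpoints <- function(schedule) {
  edges <- unlist(lapply(schedule$spines, function(sp) sp$pulses))
  sort(unique(c(edges, as.numeric(schedule$drug_windows))))
}

# instantaneous inputs at time t (evaluated mid-segment by the integrator,
# so boundary conventions are immaterial)
#' @noRd
schedule_inputs_at <- function(schedule, t, lltp_gain) {
  Y <- vapply(schedule$spines, function(sp)
    as.numeric(any(t >= sp$pulses[, 1L] & t < sp$pulses[, 2L])), numeric(1))
  in_drug <- nrow(schedule$drug_windows) > 0 &&
    any(t >= schedule$drug_windows[, 1L] & t < schedule$drug_windows[, 2L])
  list(Y = Y, alpha_mult = if (in_drug) lltp_gain else 1)
}

#' Serialize a schedule to JSON
#'
#' @param schedule an `stc_schedule`.
#' @return a JSON string (onsets in minutes, pulse edges in seconds).
#' @export
schedule_to_json <- function(schedule) {
  doc <- list(
    n = schedule$n,
    s_E1_min = schedule$s_E1_min,
    ds_E_min = schedule$ds_E_min,
    synchronized = schedule$synchronized,
    spines = lapply(schedule$spines, function(sp) list(
      label = sp$label, protocol = sp$protocol,
      onset_min = sp$onset_s / 60,
      n_pulses = nrow(sp$pulses),
      first_pulse_s = sp$pulses[1L, 1L],
      last_pulse_end_s = sp$pulses[nrow(sp$pulses), 2L])),
    drug_windows_s = apply(schedule$drug_windows, 1, identity,
                           simplify = FALSE))
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
}
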