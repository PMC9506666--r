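#' Load a run configuration
#'
#' Reads a YAML document with a flat `params:` mapping of parameter
#' overrides (Table-style names: `k_Us`, `beta_Us`, `mu_Pd`, ...) plus run
#' settings. Unknown parameter names and out-of-range values are rejected;
#' a fully-default config reproduces the standard parameter set exactly.
#'
#' Recognised top-level keys: `params` (mapping), `experiment` (one of
#' `"simulate"`, `"window"`, `"exp1"`, `"exp2"`), `experiment_args`
#' (mapping passed to the experiment function), `output_dir`, `sample_dt`
#' (s), `solver` (mapping with `rtol`, `atol`).
#'
#' @param path path to the YAML file.
#' @return an `stc_config`: list with resolved `params` ([stc_params()]),
#'   `experiment`, `experiment_args`, `output_dir`, `sample_dt`, `solver`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  known <- c("params", "experiment", "experiment_args", "output_dir",
             "sample_dt", "solver", "plot")
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  ov <- as.list(doc$params)
  # YAML 1.1 resolves a bare key `N` (or `n`) to a boolean; restore the
  # spine-count name so configs need not quote it
  names(ov)[names(ov) == "FALSE"] <- "N"
  params <- do.call(stc_params, ov)
  experiment <- doc$experiment %||% "simulate"
  if (!experiment %in% c("simulate", "window", "exp1", "exp2"))
    stop("unknown experiment: ", experiment)
  solver <- list(rtol = doc$solver$rtol %||% 1e-8,
                 atol = doc$solver$atol %||% 1e-10)
  structure(list(params = params,
                 experiment = experiment,
                 experiment_args = as.list(doc$experiment_args),
                 output_dir = doc$output_dir %||% ".",
                 sample_dt = doc$sample_dt %||% 10,
                 solver = solver,
                 plot = isTRUE(doc$plot)),
            class = "stc_config")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# atomic text write: temp file in the same directory, then rename
#' @noRd
write_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path),
                  fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Write a data frame as CSV with fixed numeric formatting
#'
#' Numbers are printed with 12 significant digits, `.` decimal separator,
#' no locale dependence; the write is atomic (temp file then rename) so an
#' interrupted run never leaves a truncated file under the final name.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  fmt <- function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.12g", col)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  write_atomic(lines, path)
}

#' Write run metadata as a JSON sidecar
#'
#' Records the fully-resolved parameter set, the schedule (if any), solver
#' settings and package version next to a result CSV.
#'
#' @param path output path (`.json`).
#' @param params an [stc_params()] object.
#' @param schedule optional `stc_schedule`.
#' @param extra optional named list merged into the document.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, params, schedule = NULL,
                               extra = list()) {
  doc <- c(list(
    package = "stcsim",
    version = as.character(utils::packageVersion("stcsim")),
    params = unclass(params)),
    if (!is.null(schedule))
      list(schedule = jsonlite::fromJSON(schedule_to_json(schedule),
                                         simplifyVector = FALSE)),
    extra)
  write_atomic(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's experiment functions, used by the
#' installed `exec/stcsim` script. Subcommands:
#' \describe{
#'   \item{simulate}{one trajectory; `--protocol eltp|lltp`,
#'     `--onset-min`, `--mu-pd`.}
#'   \item{window}{STC temporal-window sweep; `--s-min`, `--s-max`,
#'     `--step-min`, `--mu-pd`.}
#'   \item{exp1}{synchronized competition; `--n` (comma-separated counts),
#'     `--mu-pd` (comma-separated levels), `--s-min`, `--s-max`,
#'     `--step-min`.}
#'   \item{exp2}{asynchronous competition; `--n`, `--s-e1`, `--ds`,
#'     `--mu-pd` (comma-separated levels, default the published grid).}
#'   \item{version}{print the package version.}
#' }
#' Common flags: `--config <yaml>`, `--out-dir <dir>`, `--sample-dt <s>`.
#' Results are written as tidy CSV plus a JSON metadata sidecar, both
#' atomically; progress goes to `stderr`.
#'
#' @param argv character vector of arguments (excluding the program name),
#'   e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly (0 on success).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: stcsim <simulate|window|exp1|exp2|version> [options]",
    "  common options: --config FILE --out-dir DIR --sample-dt SEC",
    sep = "\n")
  if (length(argv) < 1L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- argv[1L]
  args <- parse_cli_flags(argv[-1L])
  if (cmd == "version") {
    cat(as.character(utils::packageVersion("stcsim")), "\n")
    return(invisible(0L))
  }
  if (!cmd %in% c("simulate", "window", "exp1", "exp2")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- if (!is.null(args$config)) load_config(args$config) else
      list(params = stc_params(), output_dir = ".", sample_dt = 10,
           solver = list(rtol = 1e-8, atol = 1e-10),
           experiment_args = list())
    out_dir <- args$`out-dir` %||% cfg$output_dir
    sample_dt <- as.numeric(args$`sample-dt` %||% cfg$sample_dt)
    params <- cfg$params
    if (!is.null(args$`mu-pd`) && cmd != "exp1" && cmd != "exp2")
      params$mu_Pd <- as.numeric(args$`mu-pd`)
    num_list <- function(x) as.numeric(strsplit(x, ",")[[1L]])
    t0 <- Sys.time()
    log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

    if (cmd == "simulate") {
      protocol <- args$protocol %||% "eltp"
      onset <- as.numeric(args$`onset-min` %||% 0)
      sch <- if (protocol == "lltp")
        make_schedule(n_E = 0, lltp_at_min = onset)
      else
        make_schedule(n_E = 1, s_E1_min = onset)
      params$N <- sch$n
      log_msg("integrating single-spine ", protocol, " protocol")
      traj <- stc_integrate(params, sch, sample_dt = sample_dt,
                            rtol = cfg$solver$rtol, atol = cfg$solver$atol)
      df <- as.data.frame(traj)
      write_result_csv(df, file.path(out_dir, "trajectory.csv"))
      write_run_metadata(file.path(out_dir, "trajectory.json"), params, sch,
                         extra = list(solver = traj$solver_meta))
      log_msg("wrote ", nrow(df), " rows")
    } else if (cmd == "window") {
      s_min <- as.numeric(args$`s-min` %||% -180)
      s_max <- as.numeric(args$`s-max` %||% 180)
      step <- as.numeric(args$`step-min` %||% 10)
      log_msg("window sweep: ", (s_max - s_min) / step + 1, " cells")
      res <- stc_window_sweep(params, s_min, s_max, step,
                              sample_dt = sample_dt,
                              rtol = cfg$solver$rtol,
                              atol = cfg$solver$atol)
      df <- as.data.frame(res)
      df$window_left_min <- window_width(res, "left")
      df$window_right_min <- window_width(res, "right")
      write_result_csv(df, file.path(out_dir, "window.csv"))
      write_run_metadata(file.path(out_dir, "window.json"), params,
                         extra = list(step_min = step))
    } else if (cmd == "exp1") {
      n_E <- as.integer(num_list(args$n %||% "1"))
      mu <- if (!is.null(args$`mu-pd`)) num_list(args$`mu-pd`) else
        params$mu_Pd
      s_min <- as.numeric(args$`s-min` %||% -180)
      s_max <- as.numeric(args$`s-max` %||% 180)
      step <- as.numeric(args$`step-min` %||% 10)
      log_msg("experiment I: ", length(n_E) * length(mu) *
                ((s_max - s_min) / step + 1), " cells")
      df <- experiment_I(params, n_E, mu, s_min, s_max, step,
                         sample_dt = sample_dt,
                         rtol = cfg$solver$rtol, atol = cfg$solver$atol)
      write_result_csv(df, file.path(out_dir, "exp1.csv"))
      write_run_metadata(file.path(out_dir, "exp1.json"), params,
                         extra = list(n_E = n_E, mu_Pd = mu,
                                      step_min = step))
    } else if (cmd == "exp2") {
      n_E <- as.integer(args$n %||% 5)
      s_e1 <- as.numeric(args$`s-e1` %||% -10)
      ds <- as.numeric(args$ds %||% 5)
      mu <- if (!is.null(args$`mu-pd`)) num_list(args$`mu-pd`) else
        10^seq(-4, 0, by = 0.2)
      log_msg("experiment II: ", length(mu), " basal PRP levels, n_E = ",
              n_E)
      df <- experiment_II(params, n_E, s_e1, ds, mu,
                          sample_dt = sample_dt,
                          rtol = cfg$solver$rtol, atol = cfg$solver$atol)
      write_result_csv(df, file.path(out_dir, "exp2.csv"))
      write_run_metadata(file.path(out_dir, "exp2.json"), params,
                         extra = list(n_E = n_E, s_E1_min = s_e1,
                                      ds_E_min = ds, mu_Pd = mu))
    }
    log_msg("done in ",
            format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# --flag value pairs (and bare --flag as TRUE) into a named list
#' @noRd
parse_cli_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}
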