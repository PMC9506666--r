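#' Model parameters for the STC compartment model
#'
#' Constructs the full parameter set of the synaptic tagging and capture
#' model: rate constants, Hill constants and exponents, time constants and
#' baseline levels for the per-spine variables (calcium-cascade activity
#' \eqn{U_s}, synaptic tag \eqn{T_p}, captured PRP \eqn{P_s}, plasticity
#' state \eqn{Z}, spine head volume \eqn{W}) and the shared dendritic
#' variables (PRP-synthesis cascade \eqn{U_d}, mRNA \eqn{M_d}, dendritic PRP
#' \eqn{P_d}). Defaults are the standard values used throughout all
#' simulations.
#'
#' Units: rates in s^-1 (except `k_W`, um^3 s^-1), time constants in s,
#' volumes in um^3; cascade activities, tag intensity and scaled
#' concentrations are dimensionless.
#'
#' @param ... named overrides of any parameter, e.g. `mu_Pd = 5e-2`,
#'   `N = 6`. Unknown names are an error.
#' @return An object of class `stc_params`: a named list of parameters.
#' @examples
#' p <- stc_params()                 # standard values
#' p50 <- stc_params(mu_Pd = 5e-2)   # 50x basal PRP level
#' @export
stc_params <- function(...) {
  p <- list(
    # stimulus-dependent Ca2+ cascade (per spine)
    k_Us    = 1.0e3,   # on-rate while a pulse is applied
    beta_Us = 0.1,     # off-rate
    # PRP-synthesis cascade (dendritic, shared)
    k_Ud     = 0.1,
    alpha_Ud = 1.0,    # gain on the summed spine drive; x lltp_gain under the drug
    beta_Ud  = 1.0e-3,
    K_Ud     = 0.8,
    h_Ud     = 8,
    # mRNA and dendritic PRP pool
    tau_Md = 1.0e4,
    tau_Pd = 2.0e2,
    mu_Md  = 1.0,
    mu_Pd  = 1.0e-3,   # basal PRP level; the key swept hyperparameter
    k_Pd   = 5.0e2,
    K_Pd   = 0.2,
    h_Pd   = 8,
    # capture into the spine
    k_Ps    = 3.0e-3,
    K_Ps    = 0.1,
    h_Ps    = 1,
    beta_Ps = 5.0e-3,  # efflux back to the dendrite
    # synaptic tag
    k_TP   = 0.2,
    K_TP   = 5.0e-2,
    h_TP   = 8,
    tau_TP = 2.0e4,
    mu_TP  = 0.1,
    # plasticity state
    k_Z = 5.0e-4,
    K_Z = 6.0e-2,
    h_Z = 8,
    # spine head volume
    k_W   = 3.0e-3,
    K_W   = 5.0e-2,
    h_W   = 8,
    tau_W = 3.3e2,
    # structure
    N  = 1L,           # number of spines in the compartment (1..20)
    W0 = 0.10,         # initial spine head volume, um^3
    Z0 = 0.10,         # initial plasticity state
    lltp_gain = 100    # alpha_Ud multiplier during the l-LTP drug window
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p$N <- as.integer(p$N)
  p$h_Ud <- as.numeric(p$h_Ud); p$h_Pd <- as.numeric(p$h_Pd)
  p$h_Ps <- as.numeric(p$h_Ps); p$h_TP <- as.numeric(p$h_TP)
  p$h_Z  <- as.numeric(p$h_Z);  p$h_W  <- as.numeric(p$h_W)
  class(p) <- "stc_params"
  validate_stc_params(p)
  p
}

#' Validate an `stc_params` object
#'
#' Checks strict positivity of all rates, time constants and Hill constants,
#' Hill exponents >= 1, and the 1..20 spine budget of the 10-um compartment.
#'
#' @param p an `stc_params` object.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_stc_params <- function(p) {
  stopifnot(inherits(p, "stc_params"))
  pos <- c("k_Us", "beta_Us", "k_Ud", "alpha_Ud", "beta_Ud", "K_Ud",
           "tau_Md", "tau_Pd", "mu_Md", "mu_Pd", "k_Pd", "K_Pd",
           "k_Ps", "K_Ps", "beta_Ps", "k_TP", "K_TP", "tau_TP", "mu_TP",
           "k_Z", "K_Z", "k_W", "K_W", "tau_W", "W0", "Z0", "lltp_gain")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number")
  }
  for (nm in c("h_Ud", "h_Pd", "h_Ps", "h_TP", "h_Z", "h_W")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("Hill exponent '", nm, "' must be >= 1")
  }
  if (!is.integer(p$N) || length(p$N) != 1L || is.na(p$N) ||
      p$N < 1L || p$N > 20L)
    stop("N must be an integer between 1 and 20 (2 spines/um over 10 um)")
  invisible(p)
}

#' @export
print.stc_params <- function(x, ...) {
  cat("STC model parameters (", x$N, " spine",
      if (x$N > 1L) "s", ")\n", sep = "")
  nm <- setdiff(names(x), "N")
  vals <- vapply(nm, function(k) format(x[[k]], digits = 6), character(1))
  cat(paste0("  ", format(nm, width = 10), " = ", vals), sep = "\n")
  invisible(x)
}

#' @export
as.list.stc_params <- function(x, ...) {
  unclass(x)
}
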