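#' Hill activation function
#'
#' The sigmoidal activation \eqn{\Theta[x, K, h] = x^h / (x^h + K^h)} used by
#' every nonlinear step of the model (cascade activation, PRP synthesis,
#' capture, tagging, consolidation, volume growth). Returns exactly 0 at
#' x = 0 and 0.5 at x = K; approaches 1 as x grows.
#'
#' @param x nonnegative input (vectorised).
#' @param K half-maximum constant, > 0.
#' @param h Hill exponent, >= 1.
#' @return values in `[0, 1)`.
#' @examples
#' hill(0.2, 0.1, 1)   # 2/3
#' hill(0.8, 0.8, 8)   # 0.5
#' @export
hill <- function(x, K, h) {
  if (any(x < 0)) stop("hill(): x must be nonnegative")
  stopifnot(K > 0, h >= 1)
  xh <- x^h
  out <- xh / (xh + K^h)
  out[x == 0] <- 0  # avoid 0/0 when h is such that 0^h underflows oddly
  out
}
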