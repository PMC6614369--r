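#' Evaluate the four-parameter logistic curve
#'
#' The 4PL model used throughout the package,
#' \deqn{y(x) = bottom + (top - bottom) / (1 + (x / ic50)^{hill}),}
#' where `top` is the zero-dose asymptote and `bottom` the high-dose
#' asymptote. Values are on the percent-of-control scale, doses in molar.
#' `bottom > top` is permitted (a response that rises with dose, e.g. the
#' CMV reporter under some HDAC inhibitors).
#'
#' @param x dose (molar), vectorised.
#' @param top zero-dose asymptote (%).
#' @param bottom infinite-dose asymptote (%).
#' @param hill Hill slope (> 0).
#' @param ic50 inflection dose (molar, > 0).
#' @return response values, same length as `x`.
#' @export
four_pl <- function(x, top, bottom, hill, ic50) {
  stopifnot(all(ic50 > 0), all(hill > 0), all(x >= 0))
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

# Multiplicative lognormal noise with unit mean: sdlog chosen so that
# E[factor] = 1 and CV(factor) = cv. cv = 0 returns exactly 1.
lognormal_factor <- function(n, cv) {
  stopifnot(length(cv) == 1L, is.finite(cv), cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent stop() with the calling operation's name in the message.
abort_op <- function(op, msg) stop(sprintf("[%s] %s", op, msg), call. = FALSE)
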