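#' Latent log-price process specification
#'
#' A latent market price is modelled on the log scale as a random walk with a
#' deterministic per-period drift and i.i.d. innovations:
#' \deqn{x_t = x_{t-1} + c_t + \epsilon_t,}
#' where \eqn{c_t} captures common inflationary pressure (constant or
#' seasonal) and \eqn{\epsilon_t} follows a skewed generalized error
#' distribution (\code{\link{innovation_spec}}).
#'
#' @param T number of periods (>= 2).
#' @param x0 initial log price (e.g. \code{log(500)} for a 500 NGN/kg staple).
#' @param drift either a single number (constant drift), or a numeric vector
#'   of length \code{T} (explicit per-period drift).
#' @param innovations an \code{\link{innovation_spec}}; \code{sigma = 0} gives
#'   the noiseless drift line.
#' @return an object of class \code{"latent_process_spec"}.
#' @examples
#' spec <- latent_process_spec(35, x0 = log(500), drift = 0.005,
#'                             innovations = innovation_spec(0, 0.03))
#' x <- simulate_latent_walk(spec, seed = 7)
#' @export
latent_process_spec <- function(T, x0 = log(500), drift = 0,
                                innovations = innovation_spec(0, 0.03)) {
  if (!is.numeric(T) || length(T) != 1L || T < 2)
    stop("`T` must be a single integer >= 2", call. = FALSE)
  T <- as.integer(T)
  if (length(drift) == 1L) drift <- rep(as.numeric(drift), T)
  if (length(drift) != T)
    stop("`drift` must have length 1 or length T = ", T, call. = FALSE)
  if (!inherits(innovations, "innovation_spec"))
    stop("`innovations` must be an innovation_spec()", call. = FALSE)
  structure(list(T = T, x0 = x0, drift = drift, innovations = innovations),
            class = "latent_process_spec")
}

#' Seasonal-sinusoid drift vector
#'
#' Convenience constructor for a drift sequence with a constant component plus
#' a sinusoidal seasonal cycle, \eqn{c_t = c_0 + a\sin(2\pi t/P)}.
#'
#' @param T number of periods.
#' @param base constant drift per period.
#' @param amplitude seasonal amplitude (log-price units per period).
#' @param period cycle length in periods (e.g. 52 for weekly data).
#' @return numeric vector of length \code{T}.
#' @export
drift_seasonal <- function(T, base = 0, amplitude = 0, period = 52) {
  base + amplitude * sin(2 * pi * seq_len(T) / period)
}

#' Simulate a latent log-price random walk
#'
#' @param spec a \code{\link{latent_process_spec}}.
#' @param seed optional integer for reproducible innovations.
#' @return numeric vector of length \code{spec$T}: the log-price path. The
#'   increments \code{diff(x) - drift[-1]} are i.i.d. draws from
#'   \code{spec$innovations}. The first element is
#'   \code{x0 + drift[1] + eps[1]}.
#' @export
simulate_latent_walk <- function(spec, seed = NULL) {
  if (!inherits(spec, "latent_process_spec"))
    stop("`spec` must be a latent_process_spec()", call. = FALSE)
  inn <- spec$innovations
  eps <- if (inn$sigma == 0) rep(inn$mu, spec$T) else rsged(spec$T, inn, seed)
  spec$x0 + cumsum(spec$drift + eps)
}
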