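#' Skewed generalized error (exponential-power) innovation family
#'
#' The innovation distribution used by the latent price-walk generator is a
#' two-piece (Fernandez--Steel-type) skewing of the symmetric exponential-power
#' density. The symmetric kernel with scale \eqn{\sigma} and shape \eqn{k} is
#' \deqn{g(u) = \frac{k}{2\sigma\Gamma(1/k)} \exp\{-(|u|/\sigma)^k\},}
#' and the skewed density of the centred variable \eqn{z = x - \mu} is
#' \deqn{f(z) = \frac{2s}{1+s^2}\,\{g(z/s)\,[z \ge 0] + g(sz)\,[z < 0]\}.}
#'
#' Reference points of this parameterization:
#' \itemize{
#'   \item \code{s = 1, k = 2}: exactly normal with mean \eqn{\mu} and standard
#'     deviation \eqn{\sigma/\sqrt{2}} (the constant \eqn{c = 1/\sqrt 2}).
#'   \item \code{s = 1, k = 1}: Laplace with scale \eqn{\sigma}
#'     (excess kurtosis 3).
#'   \item \code{s > 1} puts mass on the right tail, \code{s < 1} on the left;
#'     \eqn{P(Z \ge 0) = s^2/(1+s^2)}.
#' }
#' \eqn{\mu} is a location parameter, not the mean: for \eqn{s \ne 1} the mean
#' of \eqn{Z} is nonzero (see \code{\link{sged_moments}}).
#'
#' @param mu location (log-price units).
#' @param sigma scale (log-price units, > 0; 0 is accepted only by
#'   \code{innovation_spec} to denote a degenerate point mass at \code{mu},
#'   used for noiseless drift walks).
#' @param s skewness (> 0; 1 = symmetric).
#' @param k shape (> 0; 2 = Gaussian kernel, 1 = Laplace).
#' @return \code{innovation_spec} returns an object of class
#'   \code{"innovation_spec"}.
#' @examples
#' spec <- innovation_spec(mu = 0, sigma = 0.05, s = 1.5, k = 1.5)
#' x <- rsged(1000, spec, seed = 1)
#' sged_moments(spec)
#' @export
innovation_spec <- function(mu = 0, sigma = 1, s = 1, k = 2) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("`s` (skewness) must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("`k` (shape) must be a single finite number > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, s = s, k = k),
            class = "innovation_spec")
}

#' @export
print.innovation_spec <- function(x, ...) {
  cat(sprintf("<innovation_spec> mu=%g sigma=%g s=%g k=%g\n",
              x$mu, x$sigma, x$s, x$k))
  invisible(x)
}

check_sged_spec <- function(spec) {
  if (!inherits(spec, "innovation_spec"))
    spec <- do.call(innovation_spec, as.list(spec))
  if (spec$sigma <= 0)
    stop("sged functions require sigma > 0 (degenerate sigma = 0 specs are ",
         "only valid inside simulate_latent_walk())", call. = FALSE)
  spec
}

#' Density, distribution, quantile and sampling for the skewed GED
#'
#' @param x,q numeric vector of evaluation points.
#' @param p numeric vector of probabilities.
#' @param n number of draws (>= 1).
#' @param spec an \code{\link{innovation_spec}}.
#' @param seed optional integer; when given, draws are reproducible.
#' @return \code{dsged}/\code{psged}/\code{qsged} return numeric vectors;
#'   \code{rsged} returns \code{n} i.i.d. draws.
#' @seealso \code{\link{innovation_spec}} for the parameterization.
#' @export
dsged <- function(x, spec) {
  spec <- check_sged_spec(spec)
  z <- x - spec$mu
  s <- spec$s; sig <- spec$sigma; k <- spec$k
  g <- function(u) k / (2 * sig * gamma(1 / k)) * exp(-(abs(u) / sig)^k)
  out <- ifelse(z >= 0, g(z / s), g(s * z))
  2 * s / (1 + s^2) * out
}

#' @rdname dsged
#' @export
psged <- function(q, spec) {
  spec <- check_sged_spec(spec)
  z <- q - spec$mu
  s <- spec$s; sig <- spec$sigma; k <- spec$k
  pos <- z >= 0
  out <- numeric(length(z))
  # half-kernel CDF via the gamma integral: P(|U| <= u) = pgamma((u/sigma)^k, 1/k)
  out[pos] <- 1 / (1 + s^2) +
    s^2 / (1 + s^2) * stats::pgamma((z[pos] / (s * sig))^k, 1 / k)
  out[!pos] <- 1 / (1 + s^2) *
    (1 - stats::pgamma((-z[!pos] * s / sig)^k, 1 / k))
  out
}

#' @rdname dsged
#' @export
qsged <- function(p, spec) {
  spec <- check_sged_spec(spec)
  stopifnot(all(p >= 0 & p <= 1))
  s <- spec$s; sig <- spec$sigma; k <- spec$k
  p0 <- 1 / (1 + s^2)                      # mass below the mode-side split
  lower <- p <= p0
  z <- numeric(length(p))
  z[lower] <- -sig / s *
    stats::qgamma(1 - p[lower] * (1 + s^2), 1 / k)^(1 / k)
  z[!lower] <- sig * s *
    stats::qgamma((p[!lower] * (1 + s^2) - 1) / s^2, 1 / k)^(1 / k)
  z + spec$mu
}

#' @rdname dsged
#' @export
rsged <- function(n, spec, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  spec <- check_sged_spec(spec)
  s <- spec$s; sig <- spec$sigma; k <- spec$k
  draw <- function() {
    mag <- sig * stats::rgamma(n, shape = 1 / k)^(1 / k)
    pos <- stats::runif(n) < s^2 / (1 + s^2)
    spec$mu + ifelse(pos, s * mag, -mag / s)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Closed-form moments of the skewed GED
#'
#' Mean, variance, skewness and excess kurtosis of the distribution described
#' by an \code{\link{innovation_spec}}, from the absolute-moment formula
#' \eqn{E|U|^r = \sigma^r \Gamma((r+1)/k)/\Gamma(1/k)} of the symmetric kernel
#' and the two-piece weights.
#'
#' @param spec an \code{\link{innovation_spec}}.
#' @return named list with \code{mean}, \code{var}, \code{skewness},
#'   \code{ex_kurtosis}.
#' @export
sged_moments <- function(spec) {
  spec <- check_sged_spec(spec)
  s <- spec$s; sig <- spec$sigma; k <- spec$k
  absm <- function(r) sig^r * gamma((r + 1) / k) / gamma(1 / k)
  raw <- function(r) absm(r) * (s^(r + 2) + (-1)^r * s^(-r)) / (1 + s^2)
  m1 <- raw(1); m2 <- raw(2); m3 <- raw(3); m4 <- raw(4)
  v <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  list(mean = spec$mu + m1, var = v,
       skewness = mu3 / v^1.5, ex_kurtosis = mu4 / v^2 - 3)
}
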