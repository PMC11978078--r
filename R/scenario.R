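#' Named simulation scenarios
#'
#' Presets encoding the regimes the equivalence framework distinguishes. Each
#' scenario has one or two latent log-price walks and two observation layers
#' ("x" and "y", e.g. crowdsourced vs enumerator):
#' \describe{
#'   \item{null_same_process}{both sources observe the same walk with equal
#'     measurement-error sds and no markup; the difference sequence is pure
#'     measurement noise, \eqn{D = e - v \sim N(0, \sigma_e^2 + \sigma_v^2)}.}
#'   \item{fixed_markup}{as above but source x carries a fixed log markup
#'     \eqn{\tau} (default 0.1), so \eqn{E[D] = \tau}.}
#'   \item{unequal_variance}{shared walk, no markup, but
#'     \eqn{\sigma_e \ne \sigma_v}.}
#'   \item{divergent_walks}{two distinct walks sharing the same drift vector
#'     (element-wise identical, so the drift cancels in the difference) but
#'     driven by independent skewed/heavy-tailed innovations; the difference
#'     is itself a random walk whose increments carry the innovation
#'     non-normality.}
#' }
#'
#' @param name one of \code{"null_same_process"}, \code{"fixed_markup"},
#'   \code{"unequal_variance"}, \code{"divergent_walks"}.
#' @param overrides named list overriding preset defaults: \code{T},
#'   \code{x0}, \code{drift} (scalar or length-T vector), \code{mu},
#'   \code{sigma}, \code{s}, \code{k} (latent innovations), \code{sigma_e},
#'   \code{sigma_v} (measurement sds of sources x and y), \code{tau} (markup
#'   on source x).
#' @return an object of class \code{"price_scenario"} with fields
#'   \code{name}, \code{share_latent}, \code{walk_x}, \code{walk_y} (NULL
#'   when shared), \code{sigma_e}, \code{sigma_v}, \code{tau}.
#' @examples
#' scn <- make_scenario("fixed_markup", list(T = 27, tau = 0.1))
#' sim <- simulate_scenario(scn, seed = 3)
#' mean(sim$X - sim$Y)   # close to tau
#' @export
make_scenario <- function(name, overrides = list()) {
  valid <- c("null_same_process", "fixed_markup", "unequal_variance",
             "divergent_walks")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown scenario name; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  defaults <- list(T = 35, x0 = log(500), drift = 0.005,
                   mu = 0, sigma = 0.03, s = 1, k = 2,
                   sigma_e = 0.02, sigma_v = 0.02, tau = 0)
  preset <- switch(name,
    null_same_process = list(),
    fixed_markup      = list(tau = 0.1),
    unequal_variance  = list(sigma_v = 0.06),
    divergent_walks   = list(sigma = 0.05, k = 1)
  )
  p <- utils::modifyList(utils::modifyList(defaults, preset), overrides)
  inn <- innovation_spec(p$mu, p$sigma, p$s, p$k)
  walk_x <- latent_process_spec(p$T, p$x0, p$drift, inn)
  share <- name != "divergent_walks"
  walk_y <- if (share) NULL else latent_process_spec(p$T, p$x0, p$drift, inn)
  structure(list(name = name, share_latent = share,
                 walk_x = walk_x, walk_y = walk_y,
                 sigma_e = p$sigma_e, sigma_v = p$sigma_v, tau = p$tau),
            class = "price_scenario")
}

#' @export
print.price_scenario <- function(x, ...) {
  cat(sprintf(
    "<price_scenario> %s: T=%d, share_latent=%s, sigma_e=%g, sigma_v=%g, tau=%g\n",
    x$name, x$walk_x$T, x$share_latent, x$sigma_e, x$sigma_v, x$tau))
  invisible(x)
}

#' Simulate a scenario at the period level
#'
#' Draws the latent walk(s) and one observed log price per period per source:
#' \eqn{X_t = x_t + \tau + e_t}, \eqn{Y_t = y_t + v_t} (with \eqn{y = x} when
#' the latent process is shared). This is the series-level view used by the
#' Monte-Carlo studies; \code{\link{generate_observations}} provides the
#' record-level view.
#'
#' @param scenario a \code{\link{make_scenario}} object.
#' @param seed optional integer; identical scenario + seed gives a
#'   bit-identical result.
#' @return tibble with columns \code{period} (1..T), \code{x}, \code{y}
#'   (latent log prices), \code{X}, \code{Y} (observed log prices).
#' @export
simulate_scenario <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "price_scenario"))
    stop("`scenario` must come from make_scenario()", call. = FALSE)
  gen <- function() {
    x <- simulate_latent_walk(scenario$walk_x)
    y <- if (scenario$share_latent) x else simulate_latent_walk(scenario$walk_y)
    T <- scenario$walk_x$T
    tibble::tibble(
      period = seq_len(T), x = x, y = y,
      X = x + scenario$tau + stats::rnorm(T, 0, scenario$sigma_e),
      Y = y + stats::rnorm(T, 0, scenario$sigma_v)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
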