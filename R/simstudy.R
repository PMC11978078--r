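#' @title Monte-Carlo verification studies
#' @description Helpers shared by the study runners: binomial interval for
#'   rejection rates, normal interval for means, and the per-replicate seed
#'   stream (master seed plus a prime stride of 7919 per replicate, modulo
#'   2^31 - 1, so any single replicate can be re-run in isolation).
#' @name simstudy
NULL

rate_row <- function(metric, hits, reps) {
  ci <- stats::binom.test(hits, reps)$conf.int
  tibble::tibble(metric = metric, estimate = hits / reps,
                 lo = ci[1], hi = ci[2], n = reps)
}

mean_row <- function(metric, values) {
  m <- mean(values); se <- stats::sd(values) / sqrt(length(values))
  tibble::tibble(metric = metric, estimate = m,
                 lo = m - 1.96 * se, hi = m + 1.96 * se, n = length(values))
}

new_mc_study <- function(name, metrics, replicates, config) {
  structure(list(name = name, metrics = metrics, replicates = replicates,
                 config = config), class = "mc_study")
}

#' @export
print.mc_study <- function(x, ...) {
  cat(sprintf("<mc_study> %s (%d replicates)\n", x$name,
              x$config$reps %||% NA_integer_))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Type-I-error calibration under the shared-process null
#'
#' Verifies that, when two sources measure the same price with independent
#' normal errors (so the difference sequence is i.i.d.
#' \eqn{N(\tau, \sigma_e^2 + \sigma_v^2)}), each component test rejects at
#' its nominal rate: Shapiro-Wilk on D, the paired t-test at the true markup,
#' and the variance-ratio test. Also compares the mean sample variance of D
#' with the theoretical \eqn{\sigma_e^2 + \sigma_v^2}.
#'
#' The study runs the measurement-error regime literally: the latent price is
#' held flat (zero drift, zero innovation scale), so X and Y are i.i.d.
#' samples and the F test's F(n-1, n-1) reference distribution applies. With
#' a live shared random walk the common walk variance dominates both sample
#' variances and the F test becomes extremely conservative — a property of
#' applying a variance-ratio test to nonstationary series, discussed in the
#' methods vignette.
#'
#' @param T periods per replicate.
#' @param sigma_e,sigma_v measurement-error sds of the two sources.
#' @param tau fixed markup on source x (the t-test is run at this true value).
#' @param reps number of Monte-Carlo replicates.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return an \code{"mc_study"} with rejection-rate metrics (binomial 95\%
#'   intervals), \code{var_d_mean} and \code{var_d_theory}. If
#'   \code{sigma_e = sigma_v = 0} the difference sequence is degenerate at
#'   \code{tau}; the study reports the degenerate branch instead of testing.
#' @export
run_calibration <- function(T = 35, sigma_e = 0.02, sigma_v = 0.02, tau = 0,
                            reps = 1000, alpha = 0.05, seed = 1) {
  scn <- make_scenario("null_same_process",
                       list(T = T, drift = 0, sigma = 0,
                            sigma_e = sigma_e, sigma_v = sigma_v, tau = tau))
  config <- list(T = T, sigma_e = sigma_e, sigma_v = sigma_v, tau = tau,
                 reps = reps, alpha = alpha, seed = seed)
  if (sigma_e == 0 && sigma_v == 0) {
    metrics <- tibble::tibble(metric = "degenerate", estimate = 1,
                              lo = 1, hi = 1, n = reps)
    return(new_mc_study("calibration", metrics, tibble::tibble(), config))
  }
  log <- lapply(seq_len(reps), function(i) {
    sim <- simulate_scenario(scn, replicate_seed(seed, i))
    d <- sim$X - sim$Y
    tibble::tibble(
      rep = i,
      sw_rej = shapiro_wilk(d)$p < alpha,
      t_rej  = paired_t(d, tau = tau)$p < alpha,
      vr_rej = variance_ratio(sim$X, sim$Y, use_log = FALSE)$p < alpha,
      var_d  = stats::var(d))
  })
  log <- dplyr::bind_rows(log)
  metrics <- dplyr::bind_rows(
    rate_row("sw_rejection_rate", sum(log$sw_rej), reps),
    rate_row("t_rejection_rate",  sum(log$t_rej), reps),
    rate_row("vr_rejection_rate", sum(log$vr_rej), reps),
    mean_row("var_d_mean", log$var_d),
    tibble::tibble(metric = "var_d_theory",
                   estimate = sigma_e^2 + sigma_v^2,
                   lo = NA_real_, hi = NA_real_, n = reps))
  new_mc_study("calibration", metrics, log, config)
}

#' Power of the normality criterion against divergent walks
#'
#' Under the divergent-walks alternative the difference sequence is itself a
#' random walk whose increments follow the convolution of the two innovation
#' densities. Two rejection rates are reported per horizon T:
#' \describe{
#'   \item{levels}{Shapiro-Wilk applied to D itself (the procedure applied to
#'     real data). A random walk's values are far from an i.i.d. normal
#'     sample for any innovation law, so this rate grows with T even for
#'     Gaussian innovations — it detects nonstationarity as much as
#'     non-normality.}
#'   \item{increments}{Shapiro-Wilk applied to the first differences of D,
#'     which isolates the distributional signal: with Gaussian innovations
#'     (s = 1, k = 2) the rate stays at the nominal level, while skewed or
#'     heavy-tailed innovations are detected with power increasing in T.}
#' }
#'
#' @param T_grid integer vector of horizons.
#' @param s,k,sigma innovation skewness, shape and scale for both walks.
#' @param sigma_e,sigma_v measurement-error sds. Default 0: the
#'   divergent-walks alternative concerns the latent processes themselves,
#'   and with no measurement layer the increments of D are exactly i.i.d.
#'   draws from the innovation-difference convolution. Nonzero values add an
#'   MA(1) measurement component to the increments, which slightly inflates
#'   the Gaussian-innovation rejection rate above the nominal level.
#' @param reps replicates per grid point.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return an \code{"mc_study"} with metrics
#'   \code{power_levels_T<h>} and \code{power_increments_T<h>}.
#' @export
run_power <- function(T_grid = c(25, 50, 100), s = 1, k = 1, sigma = 0.05,
                      sigma_e = 0, sigma_v = 0, reps = 500,
                      alpha = 0.05, seed = 1) {
  config <- list(T_grid = T_grid, s = s, k = k, sigma = sigma,
                 sigma_e = sigma_e, sigma_v = sigma_v, reps = reps,
                 alpha = alpha, seed = seed)
  logs <- list(); metrics <- list()
  for (gi in seq_along(T_grid)) {
    T <- T_grid[gi]
    scn <- make_scenario("divergent_walks",
                         list(T = T, s = s, k = k, sigma = sigma,
                              sigma_e = sigma_e, sigma_v = sigma_v))
    log <- dplyr::bind_rows(lapply(seq_len(reps), function(i) {
      sim <- simulate_scenario(scn, replicate_seed(seed, (gi - 1) * reps + i))
      d <- sim$X - sim$Y
      tibble::tibble(T = T, rep = i,
                     rej_levels = shapiro_wilk(d)$p < alpha,
                     rej_increments = shapiro_wilk(diff(d))$p < alpha)
    }))
    logs[[gi]] <- log
    metrics[[gi]] <- dplyr::bind_rows(
      rate_row(sprintf("power_levels_T%d", T), sum(log$rej_levels), reps),
      rate_row(sprintf("power_increments_T%d", T),
               sum(log$rej_increments), reps))
  }
  new_mc_study("power", dplyr::bind_rows(metrics), dplyr::bind_rows(logs),
               config)
}

#' Quadrature density of the innovation difference
#'
#' Numeric convolution oracle for \eqn{\delta = \epsilon^x - \epsilon^y}:
#' \deqn{f_\delta(d) = \int f_{\epsilon^x}(e)\, f_{\epsilon^y}(e - d)\, de,}
#' evaluated by discretising both skewed-GED densities on a common uniform
#' grid (tail mass cut at \code{p_tail} per side) and convolving via FFT.
#' Serves as the independent check that sampled innovation differences follow
#' the theoretical convolution law.
#'
#' @param spec_x,spec_y \code{\link{innovation_spec}}s of the two innovation
#'   streams.
#' @param n_grid points per input density grid (the output grid has
#'   \code{2 n_grid - 1}).
#' @param p_tail one-sided tail probability cut when choosing grid limits.
#' @return object of class \code{"delta_density"}: list with \code{delta}
#'   (grid), \code{density}, \code{cdf}, \code{mass}, \code{mean},
#'   \code{var}. Errors if the covered mass is below \eqn{1 - 10^{-6}}.
#' @export
delta_convolution_oracle <- function(spec_x, spec_y, n_grid = 8192L,
                                     p_tail = 1e-9) {
  spec_x <- check_sged_spec(spec_x); spec_y <- check_sged_spec(spec_y)
  ax <- qsged(c(p_tail, 1 - p_tail), spec_x)
  ay <- qsged(c(p_tail, 1 - p_tail), spec_y)
  h <- max(ax[2] - ax[1], ay[2] - ay[1]) / (n_grid - 1)
  gx <- seq(ax[1], by = h, length.out = n_grid)
  gy <- seq(ay[1], by = h, length.out = n_grid)
  fx <- dsged(gx, spec_x); fy <- dsged(gy, spec_y)
  m <- 2L * n_grid - 1L
  # polynomial convolution of fx with reversed fy gives the density of x - y
  fxp <- c(fx, rep(0, m - n_grid)); fyp <- c(rev(fy), rep(0, m - n_grid))
  conv <- Re(stats::fft(stats::fft(fxp) * stats::fft(fyp), inverse = TRUE)) / m
  dens <- pmax(conv * h, 0)
  delta <- (gx[1] - gy[n_grid]) + (seq_len(m) - 1L) * h
  # exact coverage of the input grids (the convolution covers the difference
  # range whenever both components are covered)
  cov_x <- diff(psged(gx[c(1L, n_grid)], spec_x))
  cov_y <- diff(psged(gy[c(1L, n_grid)], spec_y))
  if (cov_x * cov_y < 1 - 1e-6)
    stop(sprintf("grid too narrow: covered probability mass %.8f < 1 - 1e-6",
                 cov_x * cov_y), call. = FALSE)
  mass <- trapz(delta, dens)
  cdf <- cumsum(c(0, diff(delta) * (utils::head(dens, -1) +
                                      utils::tail(dens, -1)) / 2)) / mass
  mu <- trapz(delta, delta * dens) / mass
  v <- trapz(delta, (delta - mu)^2 * dens) / mass
  structure(list(delta = delta, density = dens / mass, cdf = pmin(cdf, 1),
                 mass = mass, mean = mu, var = v,
                 spec_x = spec_x, spec_y = spec_y),
            class = "delta_density")
}

#' Kolmogorov-Smirnov distance between sampled differences and the oracle
#'
#' @param oracle a \code{\link{delta_convolution_oracle}} result.
#' @param samples numeric vector of sampled \eqn{\delta} values.
#' @return the KS statistic \eqn{\sup_x |\hat F_n(x) - F(x)|} evaluated at
#'   the sample points.
#' @export
ks_distance <- function(oracle, samples) {
  stopifnot(inherits(oracle, "delta_density"))
  xs <- sort(samples)
  Fx <- stats::approx(oracle$delta, oracle$cdf, xout = xs, rule = 2)$y
  n <- length(xs)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

#' Recovery of a fixed markup
#'
#' Under the fixed-markup scenario the difference sequence is
#' \eqn{D_t = \tau + e_t - v_t} (the shared latent walk cancels exactly), so
#' \eqn{\bar D} estimates \eqn{\tau} without bias, the paired t-test at the
#' true \eqn{\tau} rejects at the nominal rate, and the test at \eqn{\tau = 0}
#' has high power once \eqn{\tau} exceeds the measurement-noise scale.
#'
#' @param tau true markup (log units).
#' @param T periods per replicate.
#' @param sigma_e,sigma_v measurement-error sds.
#' @param reps replicates.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return an \code{"mc_study"} with metrics \code{dbar_bias} (mean
#'   \eqn{\bar D - \tau} with normal interval), \code{t_true_tau_rate} and
#'   \code{t_tau0_power}.
#' @export
run_markup_recovery <- function(tau = 0.1, T = 27, sigma_e = 0.02,
                                sigma_v = 0.02, reps = 1000, alpha = 0.05,
                                seed = 1) {
  scn <- make_scenario("fixed_markup",
                       list(T = T, tau = tau,
                            sigma_e = sigma_e, sigma_v = sigma_v))
  config <- list(tau = tau, T = T, sigma_e = sigma_e, sigma_v = sigma_v,
                 reps = reps, alpha = alpha, seed = seed)
  log <- dplyr::bind_rows(lapply(seq_len(reps), function(i) {
    sim <- simulate_scenario(scn, replicate_seed(seed, i))
    d <- sim$X - sim$Y
    tibble::tibble(rep = i, dbar = mean(d),
                   rej_true = paired_t(d, tau = tau)$p < alpha,
                   rej_zero = paired_t(d, tau = 0)$p < alpha)
  }))
  metrics <- dplyr::bind_rows(
    mean_row("dbar_bias", log$dbar - tau),
    rate_row("t_true_tau_rate", sum(log$rej_true), reps),
    rate_row("t_tau0_power", sum(log$rej_zero), reps))
  new_mc_study("markup_recovery", metrics, log, config)
}

#' Aggregation-improves-correlation effect
#'
#' Simulates two crowd-style sources observing the same daily latent walk
#' with many noisy submissions per day, runs the full record pipeline
#' (per-kg standardisation and daily/weekly/monthly aggregation), and
#' reports the mean Pearson correlation between the two sources' aggregate
#' series at each frequency. Averaging more submissions per period shrinks
#' the measurement-noise share of the variance, so the expected correlation
#' is ordered daily <= weekly <= monthly.
#'
#' @param days daily horizon per replicate.
#' @param intensity mean submissions per day per source.
#' @param sigma_e,sigma_v per-submission log-scale noise sds.
#' @param drift,sigma_innov daily drift and innovation scale of the latent
#'   walk.
#' @param reps replicates.
#' @param seed master seed.
#' @param start first calendar day.
#' @return an \code{"mc_study"} with metrics \code{r_daily}, \code{r_weekly},
#'   \code{r_monthly} (means with normal intervals).
#' @export
run_aggregation_effect <- function(days = 365, intensity = 20,
                                   sigma_e = 0.35, sigma_v = 0.35,
                                   drift = 0.001, sigma_innov = 0.02,
                                   reps = 200, seed = 1,
                                   start = as.Date("2021-01-01")) {
  dates <- start + seq_len(days) - 1
  walk <- latent_process_spec(days, log(500), drift,
                              innovation_spec(0, sigma_innov))
  obs_x <- observation_spec("crowd", intensity = intensity, sigma_e = sigma_e)
  obs_y <- observation_spec("crowd", intensity = intensity, sigma_e = sigma_v)
  config <- list(days = days, intensity = intensity, sigma_e = sigma_e,
                 sigma_v = sigma_v, drift = drift, sigma_innov = sigma_innov,
                 reps = reps, seed = seed)
  one_rep <- function(i) {
    x <- simulate_latent_walk(walk, replicate_seed(seed, 3L * i))
    rec_x <- generate_observations(x, obs_x, dates,
                                   seed = replicate_seed(seed, 3L * i + 1L))
    rec_y <- generate_observations(x, obs_y, dates,
                                   seed = replicate_seed(seed, 3L * i + 2L))
    sx <- to_price_per_kg(rec_x)$records
    sy <- to_price_per_kg(rec_y)$records
    r_at <- function(freq) {
      ax <- aggregate_prices(sx, freq)
      ay <- aggregate_prices(sy, freq)
      pearson_concordance(align_pairs(ax, ay))$r
    }
    tibble::tibble(rep = i, r_daily = r_at("daily"),
                   r_weekly = r_at("weekly"), r_monthly = r_at("monthly"))
  }
  log <- dplyr::bind_rows(lapply(seq_len(reps), one_rep))
  metrics <- dplyr::bind_rows(
    mean_row("r_daily", log$r_daily),
    mean_row("r_weekly", log$r_weekly),
    mean_row("r_monthly", log$r_monthly))
  new_mc_study("aggregation_effect", metrics, log, config)
}
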