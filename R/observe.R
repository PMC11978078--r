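#' Observation layer specification for one price source
#'
#' Describes how one data source (trained enumerator, crowdsourcing app, or a
#' model-imputed feed) observes a latent log-price path: how many submissions
#' arrive per period, how noisy each is, whether the source carries a fixed
#' markup, how often gross outliers occur, and which packaging units
#' submissions are quoted in.
#'
#' Measurement error is additive on the log scale by default (keeping prices
#' positive and matching log-scale testing); set \code{error_scale = "level"}
#' for additive error in NGN/kg.
#'
#' @param source one of \code{"enumerator"}, \code{"crowd"}, \code{"ai"}.
#' @param intensity mean number of submissions per period (>= 0). Counts are
#'   Poisson; enumerator-style sources typically use 1.
#' @param sigma_e measurement-error sd (log-price units, >= 0).
#' @param tau fixed markup added to the latent log price (log units; e.g.
#'   \code{log(1.1)} for a systematic 10\% premium).
#' @param outlier_rate probability a submission is a gross outlier in [0, 1].
#' @param outlier_magnitude multiplicative factor (> 1) applied in level space
#'   to contaminated submissions (misplaced digits, wrong units).
#' @param unit_mix named numeric vector of probabilities over packaging units;
#'   names must appear in the unit table used at generation time. Probabilities
#'   are normalised and must sum to 1 up to numerical tolerance.
#' @param error_scale \code{"log"} (default) or \code{"level"}.
#' @return an object of class \code{"observation_spec"}.
#' @export
observation_spec <- function(source = c("crowd", "enumerator", "ai"),
                             intensity = 1, sigma_e = 0, tau = 0,
                             outlier_rate = 0, outlier_magnitude = 10,
                             unit_mix = c(kg = 1),
                             error_scale = c("log", "level")) {
  source <- match.arg(source)
  error_scale <- match.arg(error_scale)
  stopifnot(intensity >= 0, sigma_e >= 0, outlier_magnitude > 1)
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("`outlier_rate` must be in [0, 1]", call. = FALSE)
  if (is.null(names(unit_mix)) || any(!nzchar(names(unit_mix))))
    stop("`unit_mix` must be a named probability vector", call. = FALSE)
  if (any(unit_mix < 0) || abs(sum(unit_mix) - 1) > 1e-8)
    stop("`unit_mix` probabilities must be >= 0 and sum to 1", call. = FALSE)
  structure(list(source = source, intensity = intensity, sigma_e = sigma_e,
                 tau = tau, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 unit_mix = unit_mix / sum(unit_mix),
                 error_scale = error_scale),
            class = "observation_spec")
}

#' Bundled market geography and packaging-unit tables
#'
#' \code{default_markets()} returns a small synthetic table of market
#' locations in northern Nigeria (ids, WGS84 coordinates, admin1/admin2
#' labels, and segment). The coordinates are illustrative, not surveyed.
#' \code{default_unit_table()} maps packaging-unit names to weights in kg.
#'
#' @return a tibble (markets: \code{market_id}, \code{lat}, \code{lon},
#'   \code{admin1}, \code{admin2}, \code{segment}; units: \code{unit},
#'   \code{weight_kg}).
#' @export
default_markets <- function() {
  tibble::tibble(
    market_id = sprintf("M%02d", 1:8),
    lat  = c(12.00, 11.96, 12.15, 11.08, 10.52, 12.99, 11.75, 10.31),
    lon  = c(8.52, 8.59, 8.30, 7.72, 7.44, 7.60, 8.90, 9.84),
    admin1 = c("Kano", "Kano", "Kano", "Kaduna", "Kaduna",
               "Katsina", "Jigawa", "Bauchi"),
    admin2 = c("Kano Municipal", "Tarauni", "Dawakin Tofa", "Zaria", "Kaduna South",
               "Katsina", "Dutse", "Bauchi"),
    segment = c("retail", "wholesale", "farmgate", "retail", "retail",
                "wholesale", "retail", "farmgate")
  )
}

#' @rdname default_markets
#' @export
default_unit_table <- function() {
  tibble::tibble(
    unit = c("kg", "mudu", "bag_5kg", "bag_25kg", "bag_50kg", "bag_100kg"),
    weight_kg = c(1, 1.3, 5, 25, 50, 100)
  )
}

#' Generate observed price submissions from a latent path
#'
#' Applies an observation layer to a latent daily/weekly/monthly log-price
#' path: per period a Poisson number of submissions arrive; each submission's
#' per-kg log price is \eqn{x_t + \tau + e}, \eqn{e \sim N(0, \sigma_e^2)};
#' a fraction \code{outlier_rate} of submissions is multiplied in level space
#' by \code{outlier_magnitude}; each record draws a market, packaging unit and
#' quantity, and reports the total transaction price
#' (per-kg price x quantity x unit weight).
#'
#' @param latent numeric log-price path.
#' @param obs an \code{\link{observation_spec}}.
#' @param dates vector of \code{Date}s, one per latent period.
#' @param markets market table as from \code{\link{default_markets}}.
#' @param units unit table as from \code{\link{default_unit_table}}.
#' @param commodity,subtype character labels stamped on every record.
#' @param seed optional integer.
#' @return tibble of price records with columns \code{date}, \code{market_id},
#'   \code{lat}, \code{lon}, \code{admin1}, \code{admin2}, \code{segment},
#'   \code{commodity}, \code{subtype}, \code{source}, \code{contributor_id},
#'   \code{quantity}, \code{unit}, \code{price_total_ngn}.
#' @export
generate_observations <- function(latent, obs, dates,
                                  markets = default_markets(),
                                  units = default_unit_table(),
                                  commodity = "maize", subtype = "white maize",
                                  seed = NULL) {
  if (!inherits(obs, "observation_spec"))
    stop("`obs` must be an observation_spec()", call. = FALSE)
  if (length(latent) != length(dates))
    stop("`latent` and `dates` must have equal length", call. = FALSE)
  if (nrow(markets) == 0)
    stop("empty market table: at least one market location is required",
         call. = FALSE)
  miss <- setdiff(names(obs$unit_mix), units$unit)
  if (length(miss))
    stop("unit_mix names absent from unit table: ",
         paste(miss, collapse = ", "), call. = FALSE)

  gen <- function() {
    counts <- stats::rpois(length(latent), obs$intensity)
    n <- sum(counts)
    if (n == 0) return(empty_records())
    idx <- rep(seq_along(latent), counts)
    e <- stats::rnorm(n, 0, obs$sigma_e)
    perkg <- if (obs$error_scale == "log") {
      exp(latent[idx] + obs$tau + e)
    } else {
      pmax(exp(latent[idx] + obs$tau) + e, .Machine$double.eps)
    }
    contam <- stats::runif(n) < obs$outlier_rate
    perkg[contam] <- perkg[contam] * obs$outlier_magnitude
    mkt <- markets[sample.int(nrow(markets), n, replace = TRUE), ]
    unit <- sample(names(obs$unit_mix), n, replace = TRUE,
                   prob = obs$unit_mix)
    wt <- units$weight_kg[match(unit, units$unit)]
    qty <- sample(1:3, n, replace = TRUE, prob = c(0.8, 0.15, 0.05))
    tibble::tibble(
      date = dates[idx],
      market_id = mkt$market_id, lat = mkt$lat, lon = mkt$lon,
      admin1 = mkt$admin1, admin2 = mkt$admin2, segment = mkt$segment,
      commodity = commodity, subtype = subtype, source = obs$source,
      contributor_id = sprintf("%s%05d", substr(obs$source, 1, 1),
                               sample.int(99999, n, replace = TRUE)),
      quantity = qty, unit = unit,
      price_total_ngn = perkg * qty * wt
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

empty_records <- function() {
  tibble::tibble(
    date = as.Date(character()), market_id = character(), lat = numeric(),
    lon = numeric(), admin1 = character(), admin2 = character(),
    segment = character(), commodity = character(), subtype = character(),
    source = character(), contributor_id = character(), quantity = integer(),
    unit = character(), price_total_ngn = numeric()
  )
}

#' Monthly OHLC summary of a noised daily price path
#'
#' Emulates a model-imputed monthly price product: the daily latent log path
#' is observed with optional Gaussian log-scale noise, exponentiated to NGN/kg
#' levels, and summarised per complete calendar month as open (first day),
#' high (max), low (min) and close (last day). Only the close is typically
#' analysed downstream.
#'
#' @param latent daily log-price path.
#' @param dates daily \code{Date} vector matching \code{latent}.
#' @param error_sd log-scale observation noise sd (>= 0).
#' @param seed optional integer.
#' @return tibble with \code{month} ("YYYY-MM"), \code{open}, \code{high},
#'   \code{low}, \code{close}; one row per complete calendar month.
#' @export
generate_ai_series <- function(latent, dates, error_sd = 0, seed = NULL) {
  if (length(latent) != length(dates))
    stop("`latent` and `dates` must have equal length", call. = FALSE)
  gen <- function() {
    xn <- latent + stats::rnorm(length(latent), 0, error_sd)
    lev <- exp(xn)
    mon <- format(dates, "%Y-%m")
    ndays <- lubridate::days_in_month(dates)
    full <- tapply(dates, mon, length) ==
      tapply(as.integer(ndays), mon, function(d) d[1])
    keep_months <- names(full)[full]
    if (length(keep_months) == 0)
      stop("series shorter than one complete calendar month", call. = FALSE)
    ord <- order(dates)
    lev <- lev[ord]; mon <- mon[ord]
    sel <- mon %in% keep_months
    lev <- lev[sel]; mon <- mon[sel]
    sp <- split(lev, mon)
    tibble::tibble(
      month = names(sp),
      open  = unname(vapply(sp, function(v) v[1], numeric(1))),
      high  = unname(vapply(sp, max, numeric(1))),
      low   = unname(vapply(sp, min, numeric(1))),
      close = unname(vapply(sp, function(v) v[length(v)], numeric(1)))
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
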