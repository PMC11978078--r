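#' Pearson concordance between two price series
#'
#' Pearson correlation of the paired values with the coefficient of
#' determination and a two-sided p-value from the exact t transform with
#' n - 2 degrees of freedom. Because the Pearson coefficient is invariant to
#' affine rescaling, it is unaffected by fixed markups, transport costs or
#' packaging-size offsets between the two sources; it measures co-movement,
#' not equality (that is the job of \code{\link{equivalence_report}}).
#'
#' @param pair a \code{\link{paired_series}} / \code{\link{align_pairs}}
#'   tibble, or a numeric vector (then \code{y} must be given).
#' @param y optional numeric vector when \code{pair} is a vector.
#' @return one-row tibble with \code{r}, \code{r2}, \code{n}, \code{p}.
#' @examples
#' pearson_concordance(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson_concordance <- function(pair, y = NULL) {
  if (is.numeric(pair) && !is.null(y)) {
    x <- pair
  } else {
    stopifnot(all(c("x", "y") %in% names(pair)))
    x <- pair$x; y <- pair$y
  }
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3)
    stop("need at least 3 paired observations, got ", n, call. = FALSE)
  if (stats::sd(x) == 0)
    stop("undefined correlation: side x is constant", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("undefined correlation: side y is constant", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  tibble::tibble(r = r, r2 = r^2, n = n, p = ct$p.value)
}

#' Lead-lag correlation profile between two aggregate series
#'
#' Correlates \code{a(t)} with \code{b(t + s)} for every shift
#' \code{s = -max_lag .. +max_lag} on the overlapping period window.
#' Sign convention: positive \code{s} means \code{b} lags \code{a} (values of
#' \code{b} recorded \code{s} periods later are matched with \code{a}).
#' A shift with fewer than 3 overlapping periods, or a constant side, is
#' reported with its \code{n} and \code{NA} results rather than failing.
#'
#' @param a,b single-group aggregate series (see
#'   \code{\link{aggregate_prices}}) of the same frequency.
#' @param max_lag maximum shift in periods (>= 1).
#' @return tibble with \code{lag}, \code{r}, \code{r2}, \code{n}, \code{p};
#'   the \code{lag = 0} row equals \code{pearson_concordance(align_pairs(a, b))}.
#' @export
lag_profile <- function(a, b, max_lag = 5) {
  stopifnot(max_lag >= 1)
  fa <- unique(a$frequency); fb <- unique(b$frequency)
  if (length(fa) != 1L || length(fb) != 1L || fa != fb)
    stop("frequency mismatch between the two series", call. = FALSE)
  ia <- period_index(a$period_start, fa)
  ib <- period_index(b$period_start, fb)
  one_lag <- function(s) {
    m <- match(ia + s, ib)
    ok <- !is.na(m)
    x <- a$mean_price[ok]; y <- b$mean_price[m[ok]]
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(tibble::tibble(lag = s, r = NA_real_, r2 = NA_real_,
                            n = n, p = NA_real_))
    res <- pearson_concordance(x, y)
    tibble::tibble(lag = s, r = res$r, r2 = res$r2, n = n, p = res$p)
  }
  dplyr::bind_rows(lapply(seq(-max_lag, max_lag), one_lag))
}

#' Nearest market by great-circle distance
#'
#' Finds the market minimising the haversine distance to a query point, the
#' matching rule used to attach model-imputed market series to administrative
#' units. Exact distance ties are broken by the lexicographically smallest
#' \code{market_id}.
#'
#' @param lat,lon query point in decimal degrees (WGS84).
#' @param markets market table (see \code{\link{default_markets}}).
#' @return the \code{market_id} of the nearest market (length-1 character).
#' @export
nearest_market <- function(lat, lon, markets) {
  if (nrow(markets) == 0) stop("empty market list", call. = FALSE)
  if (!is.finite(lat) || !is.finite(lon) || abs(lat) > 90 || abs(lon) > 180)
    stop("invalid coordinates: lat must be in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  d <- geosphere::distHaversine(c(lon, lat), cbind(markets$lon, markets$lat))
  best <- d <= min(d) * (1 + 1e-12)
  min(markets$market_id[best])
}

#' Planar centroid of a set of coordinates
#'
#' Arithmetic mean of latitudes and longitudes — a planar approximation of an
#' administrative-boundary centroid, adequate at the sub-national scales the
#' spatial matching operates on (no boundary polygons are carried).
#'
#' @param lat,lon numeric vectors of equal positive length.
#' @return named numeric vector \code{c(lat = , lon = )}.
#' @export
admin_centroid <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  if (length(lat) == 0) stop("no coordinates supplied", call. = FALSE)
  c(lat = mean(lat), lon = mean(lon))
}
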