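# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quartiles and fences are recomputed from first
# principles, distances with an explicitly written haversine formula.

# type-7 quartile (the stats::quantile default), written out by hand
oracle_quartile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
}

oracle_fence_keep <- function(v, k) {
  q1 <- oracle_quartile(v, 0.25)
  q3 <- oracle_quartile(v, 0.75)
  v >= q1 - k * (q3 - q1) & v <= q3 + k * (q3 - q1)
}

# great-circle distance (haversine), radius in metres
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# small aggregate-series tibble for pairing tests
toy_series <- function(starts, prices, frequency = "monthly") {
  tibble::tibble(frequency = frequency,
                 period = format(starts, "%Y-%m"),
                 period_start = starts,
                 mean_price = prices,
                 n = 1L, sd = NA_real_)
}
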