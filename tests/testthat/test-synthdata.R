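test_that("noiseless walk is the straight drift line", {
  spec <- latent_process_spec(20, x0 = 1, drift = 0.1,
                              innovations = innovation_spec(0, 0))
  expect_equal(simulate_latent_walk(spec), 1 + 0.1 * (1:20))
})

test_that("a common drift cancels exactly in the walk difference", {
  drift <- drift_seasonal(60, base = 0.01, amplitude = 0.05, period = 12)
  inn <- innovation_spec(0, 0.05, s = 1.6, k = 1.2)
  wx <- latent_process_spec(60, 0, drift, inn)
  wy <- latent_process_spec(60, 0, drift, inn)
  x <- simulate_latent_walk(wx, seed = 11)
  y <- simulate_latent_walk(wy, seed = 12)
  ex <- rsged(60, inn, seed = 11)
  ey <- rsged(60, inn, seed = 12)
  d <- x - y
  expect_equal(diff(d), (ex - ey)[-1], tolerance = 1e-12)
})

test_that("increment variance matches quadrature of the innovation density", {
  inn <- innovation_spec(0, 0.3, s = 1.5, k = 1.4)
  spec <- latent_process_spec(1e4, 0, drift = 0.002, innovations = inn)
  x <- simulate_latent_walk(spec, seed = 4)
  f <- function(z) dsged(z, inn)
  m1 <- integrate(function(z) z * f(z), -Inf, Inf)$value
  m2 <- integrate(function(z) z^2 * f(z), -Inf, Inf)$value
  expect_equal(var(diff(x)), m2 - m1^2, tolerance = 0.05)
})

test_that("drift length and horizon are validated", {
  expect_error(latent_process_spec(1), "T")
  expect_error(latent_process_spec(10, drift = c(0, 0)), "length")
})

test_that("noiseless observation recovers the latent price exactly", {
  dates <- as.Date("2022-03-01") + 0:29
  x <- seq(log(400), log(450), length.out = 30)
  obs <- observation_spec("enumerator", intensity = 3, sigma_e = 0)
  rec <- generate_observations(x, obs, dates, seed = 5)
  perkg <- to_price_per_kg(rec)$records
  expect_equal(perkg$price_per_kg,
               exp(x[match(perkg$date, dates)]), tolerance = 1e-12)
})

test_that("a fixed markup scales per-kg prices uniformly", {
  dates <- as.Date("2022-03-01") + 0:19
  x <- rep(log(500), 20)
  base <- generate_observations(x, observation_spec("crowd", intensity = 4),
                                dates, seed = 6)
  marked <- generate_observations(
    x, observation_spec("crowd", intensity = 4, tau = log(1.1)),
    dates, seed = 6)
  expect_equal(marked$price_total_ngn, base$price_total_ngn * 1.1,
               tolerance = 1e-12)
})

test_that("planted outliers appear at the configured rate", {
  dates <- as.Date("2022-01-01") + 0:499
  x <- rep(log(500), 500)
  obs <- observation_spec("crowd", intensity = 20, sigma_e = 0,
                          outlier_rate = 0.05, outlier_magnitude = 10)
  rec <- generate_observations(x, obs, dates, seed = 7)
  perkg <- to_price_per_kg(rec)$records$price_per_kg
  hits <- sum(abs(perkg - 5000) < 1e-6)
  n <- length(perkg)
  expect_gte(hits, qbinom(0.005, n, 0.05))
  expect_lte(hits, qbinom(0.995, n, 0.05))
})

test_that("observation-layer validation catches bad configuration", {
  expect_error(observation_spec("crowd", outlier_rate = 1.5), "outlier_rate")
  expect_error(observation_spec("crowd", unit_mix = c(kg = 0.5, mudu = 0.2)),
               "sum to 1")
  dates <- as.Date("2022-01-01") + 0:4
  expect_error(
    generate_observations(rep(6, 5), observation_spec("crowd"), dates,
                          markets = default_markets()[0, ]),
    "empty market")
  expect_error(
    generate_observations(rep(6, 5),
                          observation_spec("crowd",
                                           unit_mix = c(derica = 1)),
                          dates),
    "absent from unit table")
})

test_that("monthly OHLC summarises the noised daily path correctly", {
  dates <- seq(as.Date("2022-01-01"), as.Date("2022-04-15"), by = "day")
  flat <- rep(log(500), length(dates))
  ohlc <- generate_ai_series(flat, dates, error_sd = 0)
  expect_equal(ohlc$month, c("2022-01", "2022-02", "2022-03"))  # April partial
  for (col in c("open", "high", "low", "close"))
    expect_equal(ohlc[[col]], rep(500, 3), tolerance = 1e-12)

  rising <- seq(log(400), log(600), length.out = length(dates))
  o2 <- generate_ai_series(rising, dates, error_sd = 0)
  expect_equal(o2$close, o2$high, tolerance = 1e-12)
  # close is the last-day subsample of the (here noiseless) daily path
  last_days <- as.Date(paste0(o2$month, "-01"))
  lubridate::day(last_days) <- lubridate::days_in_month(last_days)
  expect_equal(o2$close, exp(rising[match(last_days, dates)]),
               tolerance = 1e-12)

  noisy <- generate_ai_series(rising, dates, error_sd = 0.05, seed = 8)
  expect_true(all(noisy$high >= pmax(noisy$open, noisy$close)))
  expect_true(all(noisy$low <= pmin(noisy$open, noisy$close)))
  expect_error(generate_ai_series(rep(6, 10), as.Date("2022-01-05") + 0:9),
               "complete calendar month")
})

test_that("scenario presets encode their regimes", {
  null <- make_scenario("null_same_process")
  expect_true(null$share_latent)
  expect_identical(null$sigma_e, null$sigma_v)
  expect_identical(null$tau, 0)

  mk <- make_scenario("fixed_markup")
  expect_gt(mk$tau, 0)

  uv <- make_scenario("unequal_variance")
  expect_true(uv$sigma_e != uv$sigma_v)

  dv <- make_scenario("divergent_walks")
  expect_false(dv$share_latent)
  expect_identical(dv$walk_x$drift, dv$walk_y$drift)
  expect_lt(dv$walk_x$innovations$k, 2)

  expect_error(make_scenario("nope"), "null_same_process.*divergent_walks")
  expect_identical(make_scenario("null_same_process", list(T = 35))$walk_x$T,
                   35L)
})

test_that("scenario simulation is bit-reproducible given a seed", {
  scn <- make_scenario("divergent_walks", list(T = 40))
  expect_identical(simulate_scenario(scn, seed = 5),
                   simulate_scenario(scn, seed = 5))
  sim <- simulate_scenario(scn, seed = 5)
  expect_named(sim, c("period", "x", "y", "X", "Y"))
  expect_identical(nrow(sim), 40L)
})

test_that("record generation is bit-reproducible given a seed", {
  dates <- as.Date("2022-01-01") + 0:59
  x <- simulate_latent_walk(latent_process_spec(60), seed = 1)
  obs <- observation_spec("crowd", intensity = 5, sigma_e = 0.2,
                          outlier_rate = 0.02)
  expect_identical(generate_observations(x, obs, dates, seed = 2),
                   generate_observations(x, obs, dates, seed = 2))
})
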