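make_records <- function(price_total, quantity = 1, unit = "kg",
                         date = as.Date("2022-01-01")) {
  n <- max(length(price_total), length(quantity), length(unit))
  tibble::tibble(
    date = rep_len(date, n), market_id = "M01", lat = 12, lon = 8.5,
    admin1 = "Kano", admin2 = "Kano Municipal", segment = "retail",
    commodity = "maize", subtype = "white maize", source = "crowd",
    contributor_id = sprintf("c%03d", seq_len(n)),
    quantity = rep_len(quantity, n), unit = rep_len(unit, n),
    price_total_ngn = rep_len(price_total, n))
}

test_that("per-kg standardisation divides by quantity times unit weight", {
  rec <- make_records(c(1000, 23000), quantity = 1,
                      unit = c("bag_5kg", "bag_100kg"))
  out <- to_price_per_kg(rec)
  expect_equal(out$records$price_per_kg, c(200, 230))
  expect_identical(nrow(out$rejects), 0L)
  # quantity multiplies the weight
  rec2 <- make_records(1000, quantity = 2, unit = "bag_5kg")
  expect_equal(to_price_per_kg(rec2)$records$price_per_kg, 100)
})

test_that("unknown units and bad values are routed to rejects, not dropped", {
  rec <- make_records(c(500, 800, -10, 300),
                      unit = c("kg", "derica", "kg", "kg"))
  rec$quantity[4] <- 0
  out <- to_price_per_kg(rec)
  expect_identical(nrow(out$records) + nrow(out$rejects), nrow(rec))
  expect_setequal(out$rejects$reason,
                  c("unknown_unit", "nonpositive_price",
                    "nonpositive_quantity"))
})

test_that("tukey_screen matches its definition on edge cases", {
  expect_true(all(tukey_screen(rep(250, 10))))          # IQR 0: all kept
  v <- c(rep(200, 99), 2000)
  expect_identical(which(!tukey_screen(v, k = 1.5)), 100L)
  expect_true(all(tukey_screen(v, k = Inf)))            # fence limit
  expect_error(tukey_screen(v, k = -1), "k")
  # under 4 values the fences are skipped, bounds still apply
  expect_true(all(tukey_screen(c(1, 1000, 1e6))))
  expect_identical(tukey_screen(c(1, 1000, 1e6), bounds = c(10, 1e5)),
                   c(FALSE, TRUE, FALSE))
})

test_that("tukey_screen agrees with a brute-force quartile-and-fence oracle", {
  set.seed(31)
  v <- c(rlnorm(95, log(300), 0.3), runif(5, 2000, 9000))
  for (k in c(0.5, 1.5, 3)) {
    expect_identical(tukey_screen(v, k = k), oracle_fence_keep(v, k))
  }
})

test_that("screen_prices flags bounds before fences and conserves rows", {
  rec <- make_records(c(rep(300, 50), 9000, 2))
  out <- to_price_per_kg(rec)$records
  scr <- screen_prices(out, k = 1.5, bounds = c(10, 20000))
  expect_identical(nrow(scr), nrow(out))
  expect_identical(sum(scr$screen_flag == "kept"), 50L)
  expect_identical(scr$screen_flag[51], "tukey_removed")   # inside bounds
  expect_identical(scr$screen_flag[52], "bounds_removed")  # outside bounds
})

test_that("screening removes a planted contamination fraction", {
  dates <- as.Date("2022-01-01") + 0:199
  x <- simulate_latent_walk(
    latent_process_spec(200, log(500), 0.001, innovation_spec(0, 0.02)),
    seed = 21)
  obs <- observation_spec("crowd", intensity = 10, sigma_e = 0.1,
                          outlier_rate = 0.03, outlier_magnitude = 10)
  rec <- generate_observations(x, obs, dates, seed = 22)
  scr <- screen_prices(to_price_per_kg(rec)$records)
  frac <- mean(scr$screen_flag != "kept")
  expect_gt(frac, 0.02)   # catches (most of) the planted 3%
  expect_lt(frac, 0.08)   # without gutting the clean data
})

test_that("aggregation reproduces hand-computed and oracle means", {
  # one record per day at a constant price
  rec <- make_records(rep(420, 7), date = as.Date("2022-05-01") + 0:6)
  agg <- aggregate_prices(to_price_per_kg(rec)$records, "daily")
  expect_equal(agg$mean_price, rep(420, 7))
  expect_identical(agg$n, rep(1L, 7))

  # two records in one month
  rec2 <- make_records(c(100, 300), date = as.Date("2022-05-03"))
  agg2 <- aggregate_prices(to_price_per_kg(rec2)$records, "monthly")
  expect_equal(agg2$mean_price, 200)
  expect_identical(agg2$n, 2L)
  expect_equal(agg2$sd, sd(c(100, 300)))

  # random fixture vs an independent groupby oracle
  set.seed(41)
  n <- 300
  rec3 <- make_records(rlnorm(n, log(400), 0.4),
                       date = sample(as.Date("2022-01-01") + 0:89, n,
                                     replace = TRUE))
  std <- to_price_per_kg(rec3)$records
  agg3 <- aggregate_prices(std, "monthly")
  key <- format(std$date, "%Y-%m")
  oracle <- tapply(std$price_per_kg, key, mean)
  expect_equal(agg3$mean_price, as.numeric(oracle[agg3$period]))
  expect_identical(agg3$n,
                   unname(as.integer(table(key)[agg3$period])))
})

test_that("aggregation is invariant to record order and honours min_n", {
  set.seed(42)
  rec <- make_records(rlnorm(100, log(400), 0.3),
                      date = sample(as.Date("2022-01-01") + 0:27, 100,
                                    replace = TRUE))
  std <- to_price_per_kg(rec)$records
  shuffled <- std[sample.int(nrow(std)), ]
  expect_equal(aggregate_prices(std, "weekly"),
               aggregate_prices(shuffled, "weekly"))
  agg <- aggregate_prices(std, "daily", min_n = 5)
  expect_true(all(agg$n >= 5))
  expect_identical(nrow(aggregate_prices(std[0, ], "daily")), 0L)
})

test_that("pairing joins on common periods and checks frequency", {
  m <- seq(as.Date("2021-01-01"), by = "month", length.out = 36)
  a <- toy_series(m, 500 + 1:36)
  # two gaps of 4 and 6 months leave 26 common months
  b <- toy_series(m[-c(3:6, 20:25)], 400 + seq_len(26))
  paired <- align_pairs(a, b)
  expect_identical(nrow(paired), 26L)
  expect_identical(attr(paired, "frequency"), "monthly")

  expect_identical(nrow(align_pairs(a, a)), 36L)
  disjoint <- toy_series(seq(as.Date("2030-01-01"), by = "month",
                             length.out = 5), 1:5)
  expect_identical(nrow(align_pairs(a, disjoint)), 0L)

  wk <- toy_series(m, 1:36); wk$frequency <- "weekly"
  expect_error(align_pairs(a, wk), "frequency mismatch")
  dup <- rbind(a, a[1, ])
  expect_error(align_pairs(dup, b), "single series")
})
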