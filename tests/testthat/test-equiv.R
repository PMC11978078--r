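test_that("difference series reproduces identities and recomputation", {
  p <- paired_series(c(100, 200, 300), c(100, 200, 300))
  d0 <- difference_series(p)
  expect_equal(d0$d, rep(0, 3))
  expect_equal(d0$mean, 0)

  tau <- 0.25
  x <- c(120, 340, 515, 420)
  p2 <- paired_series(x, x * exp(-tau))
  d2 <- difference_series(p2, use_log = TRUE)
  expect_equal(d2$d, rep(tau, 4), tolerance = 1e-12)

  set.seed(61)
  a <- rlnorm(30, log(500), 0.2); b <- rlnorm(30, log(480), 0.2)
  d3 <- difference_series(paired_series(a, b))
  expect_equal(d3$mean, mean(log(a) - log(b)))
  expect_equal(d3$sd, sd(log(a) - log(b)))
  expect_equal(difference_series(paired_series(a, b), use_log = FALSE)$d,
               a - b)

  bad <- paired_series(c(100, -5, 300), c(90, 80, 70),
                       period_start = as.Date("2022-01-01") + 0:2)
  expect_error(difference_series(bad), "2022-01-02")
})

test_that("shapiro_wilk enforces its domain and matches AS R94", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 5000")
  expect_error(shapiro_wilk(rnorm(5001)), "3 <= n <= 5000")
  expect_error(shapiro_wilk(rep(4, 10)), "identical")
  # frozen cross-implementation reference: the same seeded Laplace sample
  # evaluated with SciPy's shapiro (an independent AS R94 implementation)
  # gives W = 0.9584656974, p = 1.15606e-10
  set.seed(424242)
  x <- rexp(500, 2) - rexp(500, 2)
  res <- shapiro_wilk(x)
  expect_equal(res$W, 0.9584656974, tolerance = 1e-6)
  expect_lt(res$p, 0.01)
})

test_that("shapiro_wilk p-values are calibrated for normal samples", {
  rej <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    shapiro_wilk(rnorm(60))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), qbinom(0.025, 200, 0.05) / 200)
  expect_lte(mean(rej), qbinom(0.975, 200, 0.05) / 200)
})

test_that("paired t statistic follows its definition", {
  d <- c(1, 2, 3)
  res <- paired_t(d, tau = 0)
  expect_equal(res$t, 2 * sqrt(3))   # mean 2, sd 1, n 3
  expect_equal(paired_t(d, tau = 2)$t, 0)
  expect_equal(paired_t(d, tau = 2)$p, 1)
  expect_error(paired_t(rep(0.4, 6)), "s_D = 0")
  expect_error(paired_t(3), "at least 2")
  # cross-check against the reference implementation
  set.seed(62)
  dd <- rnorm(25, 0.1, 0.3)
  ref <- t.test(dd, mu = 0.05)
  mine <- paired_t(dd, tau = 0.05)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})

test_that("variance ratio follows its definition, two-sided", {
  p <- paired_series(c(0, 2, 4), c(0, 1, 2))
  res <- variance_ratio(p, use_log = FALSE)
  expect_equal(res$F, 4)
  expect_equal(variance_ratio(c(1, 2, 3), c(5, 6, 7), use_log = FALSE)$F, 1)
  expect_error(variance_ratio(c(1, 2, 3), c(4, 4, 4), use_log = FALSE),
               "zero variance")
  set.seed(63)
  x <- rnorm(30, 0, 1.4); y <- rnorm(30)
  ref <- var.test(x, y)
  mine <- variance_ratio(x, y, use_log = FALSE)
  expect_equal(mine$F, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})

test_that("innovation normality flags heavy-tailed walks, not Gaussian ones", {
  # Gaussian-increment walk: rejection at roughly the nominal rate
  rej_g <- vapply(1:150, function(i) {
    w <- latent_process_spec(100, 6, 0.002, innovation_spec(0, 0.05))
    innovation_normality(exp(simulate_latent_walk(w, seed = 800 + i)))$p < 0.05
  }, logical(1))
  expect_lt(mean(rej_g), 0.12)
  # Laplace-increment walk at n = 150: high rejection
  rej_l <- vapply(1:60, function(i) {
    w <- latent_process_spec(150, 6, 0.002,
                             innovation_spec(0, 0.05, s = 1, k = 1))
    innovation_normality(exp(simulate_latent_walk(w, seed = 900 + i)))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej_l), 0.5)
  expect_error(innovation_normality(rep(100, 10)), "identical")
  expect_error(innovation_normality(c(100, 101, 102)), "at least 4")
})

test_that("the agreement decision table is exhaustive and pure", {
  nn <- c(0.001, 0.02)   # non-normal innovations confirmed
  expect_identical(classify_agreement(0.5, 0.5, 0.5, nn), "full_equivalence")
  expect_identical(classify_agreement(0.5, 0.5, 0.01, nn),
                   "equivalence_unequal_variance")
  expect_identical(classify_agreement(0.5, 0.01, 0.5, nn),
                   "equivalence_fixed_markup")
  expect_identical(classify_agreement(0.5, 0.01, 0.01, nn),
                   "equivalence_markup_and_variance")
  expect_identical(classify_agreement(0.01, 0.5, 0.5, nn), "not_equivalent")
  expect_identical(classify_agreement(0.5, 0.01, 0.01, c(0.3, 0.6)),
                   "inconclusive_normal_innovations")
  # one non-normal side is enough to keep the criterion informative
  expect_identical(classify_agreement(0.5, 0.5, 0.5, c(0.3, 0.01)),
                   "full_equivalence")
  # the SW strictness threshold is separate from alpha
  expect_identical(classify_agreement(0.08, 0.5, 0.5, nn, sw_alpha = 0.10),
                   "not_equivalent")
  expect_error(classify_agreement(NA, 0.5, 0.5, nn), "present")
  expect_error(classify_agreement(0.5, 1.2, 0.5, nn), "\\[0, 1\\]")
})

test_that("equivalence_report classifies constructed regimes correctly", {
  # heavy-tailed shared walk, small equal noise: equivalence should hold
  w <- latent_process_spec(120, log(500), 0.002,
                           innovation_spec(0, 0.06, s = 1.4, k = 1))
  x <- simulate_latent_walk(w, seed = 71)
  X <- exp(x + withr::with_seed(72, rnorm(120, 0, 0.02)))
  Y <- exp(x + withr::with_seed(73, rnorm(120, 0, 0.02)))
  rep0 <- equivalence_report(paired_series(X, Y))
  expect_identical(rep0$classification, "full_equivalence")

  # same walk plus a clear markup on X
  repm <- equivalence_report(paired_series(X * exp(0.2), Y))
  expect_identical(repm$classification, "equivalence_fixed_markup")
  # testing at the true markup restores full equivalence
  expect_identical(
    equivalence_report(paired_series(X * exp(0.2), Y), tau = 0.2)$classification,
    "full_equivalence")

  # two independent heavy-tailed walks: D inherits the non-normality
  scn <- make_scenario("divergent_walks", list(T = 150, sigma = 0.08))
  sim <- simulate_scenario(scn, seed = 74)
  repd <- equivalence_report(paired_series(exp(sim$X), exp(sim$Y)))
  expect_identical(repd$classification, "not_equivalent")
})
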