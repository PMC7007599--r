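test_that("Lincoln-Petersen evaluates the closed-form exactly", {
  expect_equal(lincoln_petersen(10, 10, 5), 11 * 11 / 6 - 1)
  expect_equal(lincoln_petersen(100, 100, 100), 100)
  # national sample sizes of the two two-week windows, exact evaluation
  expect_equal(lincoln_petersen(2449493, 2474293, 1332632),
               4547964.049069024, tolerance = 1e-12)
  expect_warning(est <- lincoln_petersen(5, 5, 0), "unstable")
  expect_equal(est, 35)
  expect_error(lincoln_petersen(5, 5, 6), "exceed")
  expect_error(lincoln_petersen(-1, 5, 0), "whole numbers")
  expect_error(lincoln_petersen(2.5, 5, 1), "whole numbers")
})

test_that("Chapman variance matches the closed form and is non-negative", {
  expect_equal(chapman_variance(10, 10, 10), 0)
  expect_equal(chapman_variance(10, 10, 5), 121 * 5 * 5 / (36 * 7))
  set.seed(1)
  for (i in 1:50) {
    m <- sample(0:200, 1); n <- sample(0:200, 1)
    k <- sample(0:min(m, n), 1)
    expect_gte(chapman_variance(m, n, k), 0)
  }
})

test_that("penetration adjustment reproduces published provincial rows", {
  expect_equal(adjust_by_penetration(516113, 0.740), 697450)  # Guangdong
  expect_equal(adjust_by_penetration(248679, 0.436), 570365)  # Sichuan
  expect_equal(adjust_by_penetration(11565, 0.461), 25087)    # Tibet
  expect_equal(adjust_by_penetration(123.4, 1), 123)
  expect_error(adjust_by_penetration(100, 0), "penetration")
  expect_error(adjust_by_penetration(100, 1.2), "penetration")
  # scale consistency before rounding: halving penetration doubles the scale
  expect_equal(1000 / 0.25, 2 * (1000 / 0.5))
  expect_equal(adjust_by_penetration(1000, 0.25),
               2 * adjust_by_penetration(1000, 0.5))
})

test_that("estimate respects its order bounds and decreases in k", {
  set.seed(2)
  for (i in 1:50) {
    m <- sample(1:500, 1); n <- sample(1:500, 1)
    k <- sample(1:min(m, n), 1)
    est <- lincoln_petersen(m, n, k)
    expect_gte(est, max(m, n))
    if (k > 1) expect_gt(lincoln_petersen(m, n, k - 1), est)
  }
})

test_that("simulated estimator mean matches exhaustive enumeration on tiny N", {
  N <- 20
  exact <- exact_lp_mean(N, 0.5, 0.4)
  sims <- simulate_crc(N, 0.5, 0.4, replicates = 40000, seed = 3)
  se <- sd(sims$estimate) / sqrt(nrow(sims))
  expect_lt(abs(mean(sims$estimate) - exact), 4 * se)
})

test_that("stratified estimation composes the per-stratum pieces", {
  samples <- tibble::tibble(province = "A", m = 1000L, n = 900L, k = 400L)
  profiles <- tibble::tibble(province = "A", internet_penetration = 0.5,
                             adult_men = 2e5)
  est <- estimate_population(samples, profiles)
  lp <- lincoln_petersen(1000, 900, 400)
  expect_equal(tidy(est)$n_sn_hat, lp)
  expect_equal(tidy(est)$n_total_hat, adjust_by_penetration(lp, 0.5))
  expect_equal(glance(est)$n_total_hat, adjust_by_penetration(lp, 0.5))
  expect_equal(tidy(est)$variance, chapman_variance(1000, 900, 400))
  expect_true(tidy(est)$ci_low <= lp & lp <= tidy(est)$ci_high)
  expect_equal(glance(est)$variance,
               chapman_variance(1000, 900, 400) / 0.5^2)

  expect_error(
    estimate_population(
      tibble::tibble(province = c("A", "Zed"), m = c(10L, 10L),
                     n = c(10L, 10L), k = c(5L, 5L)), profiles),
    "Zed")
})

test_that("national aggregate sums unrounded stratum estimates", {
  samples <- tibble::tibble(province = c("A", "B"), m = c(100L, 200L),
                            n = c(120L, 180L), k = c(60L, 90L))
  profiles <- tibble::tibble(province = c("A", "B"),
                             internet_penetration = c(0.4, 0.8))
  est <- estimate_population(samples, profiles)
  raw <- lincoln_petersen(samples$m, samples$n, samples$k) /
    profiles$internet_penetration
  expect_equal(glance(est)$n_total_hat, round_half_away(sum(raw)))
  expect_equal(
    glance(est)$variance,
    sum(chapman_variance(samples$m, samples$n, samples$k) /
          profiles$internet_penetration^2))
})

test_that("capture samples tabulate marked, caught and recaptured users per stratum", {
  r1 <- tibble::tibble(
    user_id = c("u1", "u2", "u3", "u4"),
    date = as.Date("2018-03-12"),
    province = c("A", "A", "B", "B"))
  r2 <- tibble::tibble(
    user_id = c("u1", "u3", "u5"),
    date = as.Date("2018-10-22"),
    province = c("A", "B", "A"))
  s <- capture_samples(r1, r2)
  expect_equal(s$province, c("A", "B"))
  expect_equal(s$m, c(2L, 2L))
  expect_equal(s$n, c(2L, 1L))
  expect_equal(s$k, c(1L, 1L))
  expect_true(all(s$k <= pmin(s$m, s$n)))
})
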