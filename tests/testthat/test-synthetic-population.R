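test_that("population sizes are an exact function of the configuration", {
  prof <- tibble::tibble(province = "X", adult_men = 100000,
                         internet_penetration = 0.6, msm_prevalence = 0.02,
                         x_km = 0, y_km = 0)
  cfg <- sim_config(prof, seed = 3)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 2000)

  cfg3 <- tiny_config(seed = 5)
  pop3 <- generate_population(cfg3)
  truth <- ground_truth(cfg3)
  expect_equal(as.integer(table(pop3$home_province)[truth$province]),
               as.integer(truth$n_true))
  expect_equal(attr(truth, "total"), sum(truth$n_true))
})

test_that("app adoption follows internet penetration", {
  prof <- tiny_profiles()
  prof$internet_penetration <- c(1, 1, 1)
  pop <- generate_population(sim_config(prof, seed = 2))
  expect_true(all(pop$uses_app))

  cfg <- tiny_config(seed = 11)
  pop <- generate_population(cfg)
  expect_true(all(pop$p_online[!pop$uses_app] == 0))
  # adoption rate within 4 binomial SDs per province
  for (p in tiny_profiles()$province) {
    sub <- pop[pop$home_province == p, ]
    pen <- tiny_profiles()$internet_penetration[tiny_profiles()$province == p]
    tol <- 4 * sqrt(pen * (1 - pen) / nrow(sub))
    expect_lt(abs(mean(sub$uses_app) - pen), tol)
  }
})

test_that("a fixed seed reproduces the population byte for byte", {
  cfg <- tiny_config(seed = 7)
  expect_identical(generate_population(cfg), generate_population(cfg))
})

test_that("migrant assignment hits the configured share with valid destinations", {
  cfg <- tiny_config(seed = 4, migrant_fraction = 0.25)
  pop <- generate_population(cfg)
  n_mig <- sum(pop$work_province != pop$home_province)
  expect_equal(n_mig, round_half_away(0.25 * nrow(pop)))
  expect_true(all(pop$work_province %in% tiny_profiles()$province))

  cfg0 <- tiny_config(seed = 4, migrant_fraction = 0)
  pop0 <- generate_population(cfg0)
  expect_true(all(pop0$work_province == pop0$home_province))
})

test_that("configuration validation rejects invalid inputs", {
  prof <- tiny_profiles()
  expect_error(sim_config(prof[0, ]), "non-empty")
  expect_error(sim_config(prof, migrant_fraction = 1.5), "migrant_fraction")
  expect_error(sim_config(prof, n_days_holiday = 0), "n_days_holiday")
  expect_error(sim_config(prof, grid_spacing_km = -1), "grid_spacing_km")
  bad <- prof
  bad$internet_penetration[1] <- 0
  expect_error(sim_config(bad), "internet_penetration")
})

test_that("online appearance is Bernoulli per agent-day", {
  # certain event: p_online = 1 puts every app user online every day
  cfg <- tiny_config(seed = 6, p_online = 1)
  pop <- generate_population(cfg)
  roster <- simulate_period(pop, cfg, "nonholiday", seed = 8)
  n_app <- sum(pop$uses_app)
  expect_equal(nrow(roster), n_app * cfg$n_days_nonholiday)
  expect_equal(dplyr::n_distinct(roster$user_id), n_app)

  # p = 0.5: single-day counts stay within 4 binomial SDs across seeds and
  # their mean within 3 standard errors
  cfg2 <- tiny_config(seed = 6, p_online = 0.5)
  pop2 <- generate_population(cfg2)
  pop2 <- pop2[pop2$uses_app, ][seq_len(1000), ]
  counts <- vapply(1:10, function(s) {
    nrow(simulate_period(pop2, cfg2, "nonholiday", seed = s, n_days = 1))
  }, numeric(1))
  expect_true(all(abs(counts - 500) < 4 * sqrt(1000 * 0.25)))
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(1000 * 0.25 / 10))
})

test_that("agents sit at home during holidays and at work otherwise", {
  cfg <- tiny_config(seed = 9, migrant_fraction = 0.5, p_online = 1)
  pop <- generate_population(cfg)
  hol <- simulate_period(pop, cfg, "holiday", seed = 1)
  non <- simulate_period(pop, cfg, "nonholiday", seed = 1)
  mig <- pop[pop$work_province != pop$home_province & pop$uses_app, ][1, ]
  expect_equal(unique(hol$province[hol$user_id == mig$id]),
               mig$home_province)
  expect_equal(unique(non$province[non$user_id == mig$id]),
               mig$work_province)
  # closed population: the same agents exist in both windows
  expect_true(all(non$user_id %in% pop$id))
  expect_true(all(hol$user_id %in% pop$id))
  expect_error(simulate_period(pop, cfg, "holiday", seed = 1, n_days = 0),
               "n_days")
})

test_that("profile and roster CSV round-trips preserve content", {
  dir <- withr::local_tempdir()
  prof <- tiny_profiles()
  write_province_profiles(prof, file.path(dir, "prof.csv"))
  expect_equal(as.data.frame(read_province_profiles(file.path(dir, "prof.csv"))),
               as.data.frame(prof))
  cfg <- tiny_config(seed = 2)
  roster <- simulate_period(generate_population(cfg), cfg, "holiday",
                            seed = 3)
  write_roster(roster, file.path(dir, "r.csv"))
  back <- read_roster(file.path(dir, "r.csv"))
  expect_equal(as.data.frame(back[, c("user_id", "date", "province", "cell_id")]),
               as.data.frame(roster[, c("user_id", "date", "province", "cell_id")]))
})
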