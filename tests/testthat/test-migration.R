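roster_row <- function(user, dates, prov) {
  tibble::tibble(user_id = user, date = as.Date("2018-02-16") + dates,
                 province = prov)
}

test_that("period province is the mode with deterministic tie-breaking", {
  expect_equal(assign_period_province(roster_row("u1", 0:4, "A"), "u1"), "A")
  expect_equal(
    assign_period_province(
      roster_row("u1", 0:4, c("A", "B", "A", "B", "A")), "u1"), "A")
  # 2-2 tie: earliest observation wins (B seen first)
  expect_equal(
    assign_period_province(
      roster_row("u1", 0:3, c("B", "B", "A", "A")), "u1"), "B")
  # full tie on days and dates: lexicographic province
  both <- dplyr::bind_rows(roster_row("u1", 0:1, "B"),
                           roster_row("u1", 0:1, "A"))
  expect_equal(assign_period_province(both, "u1"), "A")
  expect_error(assign_period_province(roster_row("u1", 0, "A"), "ghost"),
               "not present")
  # duplicate same-day sightings do not inflate the day count
  dup <- dplyr::bind_rows(roster_row("u1", c(0, 0, 0), "A"),
                          roster_row("u1", 1:2, "B"))
  expect_equal(assign_period_province(dup, "u1"), "B")
})

test_that("co-occurrence is the roster intersection with both assignments", {
  hol <- roster_row(c("u1", "u2"), c(0, 0), c("A", "B"))
  non <- roster_row(c("u3", "u4"), c(30, 30), c("A", "B"))
  expect_equal(nrow(co_occurring_users(hol, non)), 0)
  same <- roster_row(c("u1", "u2", "u3"), c(0, 0, 0), c("A", "B", "A"))
  co <- co_occurring_users(same, same)
  expect_equal(nrow(co), 3)
  expect_true(all(!co$migrant))
})

test_that("OD matrix counts flows and migrants correctly", {
  a <- tibble::tibble(user_id = c("u1", "u2", "u3"),
                      holiday_province = c("A", "A", "B"),
                      nonholiday_province = c("A", "B", "A"))
  od <- build_od_matrix(a)
  expect_equal(unclass(od)[cbind(c("A", "A", "B"), c("A", "B", "A"))],
               c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(od), 3)
  expect_equal(migrant_count(od), 2)
  expect_equal(unclass(od), oracle_od(a, c("A", "B")), ignore_attr = TRUE)

  stay <- tibble::tibble(user_id = c("u1", "u2"),
                         holiday_province = c("A", "B"),
                         nonholiday_province = c("A", "B"))
  od0 <- build_od_matrix(stay)
  expect_equal(migrant_count(od0), 0)
  expect_true(all(od0 == diag(diag(od0))))
  expect_error(build_od_matrix(a, provinces = "A"), "unknown province")

  # tidy long view round-trips the counts
  long <- tidy(od)
  expect_equal(sum(long$n), 3)
  expect_equal(long$n[long$origin == "A" & long$destination == "B"], 1L)
})

test_that("OD construction matches the brute-force oracle on random inputs", {
  set.seed(14)
  provs <- c("A", "B", "C", "D")
  for (i in 1:100) {
    n <- sample(1:6, 1)
    a <- tibble::tibble(user_id = sprintf("u%d", seq_len(n)),
                        holiday_province = sample(provs, n, TRUE),
                        nonholiday_province = sample(provs, n, TRUE))
    od <- build_od_matrix(a, provinces = provs)
    expect_equal(unclass(od), oracle_od(a, provs), ignore_attr = TRUE)
    # conservation: margins equal period counts
    expect_equal(as.vector(rowSums(od)),
                 as.vector(table(factor(a$holiday_province, provs))))
    expect_equal(as.vector(colSums(od)),
                 as.vector(table(factor(a$nonholiday_province, provs))))
  }
})

test_that("destination shares and source composition normalise to 100%", {
  a <- tibble::tibble(
    user_id = sprintf("u%d", 1:60),
    holiday_province = rep(c("A", "B", "C", "D"), c(30, 20, 10, 0)),
    nonholiday_province = c(rep("D", 30), rep("C", 20), rep("B", 10)))
  od <- build_od_matrix(a, provinces = c("A", "B", "C", "D"))
  ds <- destination_shares(od)
  expect_equal(ds$province[1:3], c("D", "C", "B"))
  expect_equal(ds$share_pct[1:3], c(50, 33.33, 16.67))
  expect_lt(abs(sum(ds$share_pct) - 100), 0.01)
  expect_equal(nrow(destination_shares(od, top = 2)), 2)
  expect_equal(nrow(destination_shares(od, min_flow = 15)), 2)

  sc <- source_composition(od, "D")
  expect_equal(sc$share_pct[sc$origin == "A"], 100)
  expect_lt(abs(sum(sc$share_pct) - 100), 0.01)
  expect_error(source_composition(od, "A"), "no migrant inflow")
  expect_error(source_composition(od, "Zed"), "unknown destination")

  one <- build_od_matrix(tibble::tibble(user_id = "u", holiday_province = "A",
                                        nonholiday_province = "B"))
  expect_equal(destination_shares(one)$share_pct[1], 100)
  expect_error(destination_shares(build_od_matrix(
    tibble::tibble(user_id = "u", holiday_province = "A",
                   nonholiday_province = "A"))), "no interprovincial")
})

test_that("holiday surplus is the per-province difference of daily means", {
  d1 <- tibble::tibble(province = c("A", "B"), mean_daily = c(10, 20))
  expect_true(all(holiday_surplus(d1, d1)$surplus == 0))
  d2 <- tibble::tibble(province = c("A", "B"), mean_daily = c(25, 12))
  hs <- holiday_surplus(d1, d2)
  expect_equal(hs$surplus[hs$province == "A"], 15)
  expect_equal(sum(hs$surplus), sum(d2$mean_daily) - sum(d1$mean_daily))
  d3 <- tibble::tibble(province = c("A", "C"), mean_daily = c(1, 2))
  expect_error(holiday_surplus(d1, d3), "differ")
})

test_that("daily mean counts average distinct users over window days", {
  r <- dplyr::bind_rows(
    roster_row(c("u1", "u2"), c(0, 0), "A"),
    roster_row("u1", 1, "A"),
    roster_row("u3", 0, "B"))
  dm <- daily_mean_counts(r)
  expect_equal(dm$mean_daily[dm$province == "A"], 1.5)
  expect_equal(dm$mean_daily[dm$province == "B"], 0.5)
})

test_that("simulated migrant share is recovered among co-occurring users", {
  cfg <- tiny_config(seed = 21, migrant_fraction = 0.3, p_online = 0.7)
  pop <- generate_population(cfg)
  hol <- simulate_period(pop, cfg, "holiday", seed = 31)
  non <- simulate_period(pop, cfg, "nonholiday", seed = 32)
  co <- co_occurring_users(hol, non)
  expect_gt(nrow(co), 500)
  tol <- 3 * sqrt(0.3 * 0.7 / nrow(co))
  expect_lt(abs(mean(co$migrant) - 0.3), tol)
  od <- build_od_matrix(co, provinces = cfg$provinces$province)
  expect_equal(sum(od), nrow(co))
  # margins match the period assignments of co-occurring users
  expect_equal(as.vector(rowSums(od)),
               as.vector(table(factor(co$holiday_province,
                                      cfg$provinces$province))))
})
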