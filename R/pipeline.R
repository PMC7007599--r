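#' Run the full synthetic study end to end
#'
#' Composes the stages: generate the closed agent population, simulate the
#' holiday window and the two nonholiday capture windows, enumerate each
#' day's online users over the masked grid, estimate provincial and national
#' population sizes by capture-recapture with penetration adjustment,
#' compute the heterogeneity statistics, and build the holiday-vs-nonholiday
#' origin-destination migration flows. Identical `config` (including its
#' seed) gives byte-identical outputs; report files carry no timestamps for
#' exactly that reason, and the manifest logs per-stage record counts
#' instead.
#'
#' @param config A [sim_config()]; see [demo_config()] for a ready-made one.
#' @param stages Character subset of `c("capture", "estimate", "stats",
#'   "migrate")`. The simulation itself always runs; dropping `"capture"`
#'   uses the true online rosters directly instead of grid enumeration.
#' @param K Nearby-list limit per grid query; `Inf` (default) gives complete
#'   coverage, the regime in which the enumeration protocol recovers every
#'   online user.
#' @param out_dir Optional directory; when given, the report bundle is
#'   written as headered CSVs plus a YAML manifest.
#' @return A list of class `appcrc_report` with elements `config`, `truth`,
#'   `samples`, `estimate` (a `crc_estimate`), `daily`, `stats`,
#'   `assignments`, `od`, `destination_shares`, `surplus`, `manifest`
#'   (stages not run are NULL).
#' @examples
#' \donttest{
#' rep <- run_pipeline(demo_config(seed = 1))
#' glance(rep$estimate)
#' }
#' @export
run_pipeline <- function(config,
                         stages = c("capture", "estimate", "stats",
                                    "migrate"),
                         K = Inf, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bad <- setdiff(stages, c("capture", "estimate", "stats", "migrate"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  prov <- config$provinces
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("appcrc")),
                   stages = as.list(stages), K = if (is.finite(K)) K else "Inf",
                   counts = list())

  agents <- generate_population(config)
  rosters <- list(
    holiday = simulate_period(agents, config, "holiday",
                              seed = config$seed + 101L),
    nonholiday = simulate_period(agents, config, "nonholiday",
                                 seed = config$seed + 102L),
    recapture = simulate_period(agents, config, "recapture",
                                seed = config$seed + 103L)
  )
  manifest$counts$agents <- nrow(agents)
  manifest$counts$roster_rows <- lapply(rosters, nrow)

  captured <- rosters
  if ("capture" %in% stages) {
    captured <- lapply(rosters, function(r) {
      enumerate_roster(r, spacing_km = config$grid_spacing_km, K = K)
    })
    manifest$counts$captured_users <- lapply(
      captured, function(r) dplyr::n_distinct(r$user_id))
  }

  out <- list(config = config, truth = ground_truth(config),
              samples = NULL, estimate = NULL, daily = NULL, stats = NULL,
              assignments = NULL, od = NULL, destination_shares = NULL,
              surplus = NULL)

  if ("estimate" %in% stages) {
    out$samples <- capture_samples(captured$nonholiday, captured$recapture)
    out$estimate <- estimate_population(out$samples, prov)
    manifest$counts$recaptured <- sum(out$samples$k)
  }

  if ("stats" %in% stages || "migrate" %in% stages) {
    daily <- lapply(captured[c("holiday", "nonholiday")], function(r) {
      daily_mean_counts(r) |>
        dplyr::right_join(tibble::tibble(province = prov$province),
                          by = "province") |>
        dplyr::mutate(mean_daily = dplyr::coalesce(.data$mean_daily, 0)) |>
        dplyr::arrange(.data$province)
    })
    out$daily <- dplyr::bind_rows(daily, .id = "period")
  }

  if ("stats" %in% stages) {
    adult_men <- prov$adult_men[match(daily$nonholiday$province,
                                      prov$province)]
    sim <- pattern_similarity(daily$holiday$mean_daily,
                              daily$nonholiday$mean_daily,
                              n_strata = min(5, nrow(prov)),
                              seed = config$seed + 104L)
    out$stats <- tibble::tibble(
      statistic = c("gini_nonholiday", "gini_nonholiday_weighted",
                    "gini_holiday", "cv_nonholiday", "cv_holiday",
                    "q_holiday_vs_nonholiday", "q_p_value"),
      value = c(gini(daily$nonholiday$mean_daily),
                gini(daily$nonholiday$mean_daily, adult_men),
                gini(daily$holiday$mean_daily),
                coefficient_of_variation(daily$nonholiday$mean_daily),
                coefficient_of_variation(daily$holiday$mean_daily),
                sim$q, sim$p_value)
    )
  }

  if ("migrate" %in% stages) {
    out$assignments <- co_occurring_users(captured$holiday,
                                          captured$nonholiday)
    out$od <- build_od_matrix(out$assignments, provinces = prov$province)
    out$destination_shares <- destination_shares(out$od)
    out$surplus <- holiday_surplus(daily$holiday, daily$nonholiday)
    manifest$counts$co_occurring <- nrow(out$assignments)
    manifest$counts$migrants <- migrant_count(out$od)
  }

  out$manifest <- manifest
  class(out) <- "appcrc_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

# grid-enumerate every day of a roster and keep only captured observations
enumerate_roster <- function(roster, spacing_km, K) {
  if (nrow(roster) == 0) return(roster)
  pad <- spacing_km
  grid <- build_grid(range(roster$x_km) + c(-pad, pad),
                     range(roster$y_km) + c(-pad, pad), spacing_km)
  grid <- mask_uninhabited(grid, roster)
  kept <- lapply(split(roster, roster$date), function(day) {
    day[day$user_id %in% enumerate_day(grid, day, K), , drop = FALSE]
  })
  dplyr::bind_rows(kept)
}

#' @export
print.appcrc_report <- function(x, ...) {
  cat("appcrc pipeline report (seed", x$config$seed, ")\n")
  cat(" agents:", x$manifest$counts$agents,
      "| stages:", paste(unlist(x$manifest$stages), collapse = ", "), "\n")
  if (!is.null(x$estimate)) {
    g <- glance(x$estimate)
    cat(sprintf(" national estimate: %s (truth %s)\n",
                format(g$n_total_hat, big.mark = ","),
                format(attr(x$truth, "total"), big.mark = ",")))
  }
  if (!is.null(x$od)) {
    cat(sprintf(" co-occurring users: %s, migrants: %s (%.2f%%)\n",
                format(sum(x$od), big.mark = ","),
                format(migrant_count(x$od), big.mark = ","),
                100 * migrant_count(x$od) / sum(x$od)))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(report$estimate)) {
    tab <- tidy(report$estimate) |>
      dplyr::transmute(
        province = .data$province,
        internet_penetration = .data$internet_penetration,
        social_networking_msm = round_half_away(.data$n_sn_hat),
        msm_estimate = .data$n_total_hat,
        msm_ci_low = .data$n_total_ci_low,
        msm_ci_high = .data$n_total_ci_high,
        pct_adult_men = if ("pct_adult_men" %in% names(report$estimate$strata))
          .data$pct_adult_men else NA_real_)
    readr::write_csv(tab, p("estimates.csv"))
  }
  if (!is.null(report$daily)) readr::write_csv(report$daily,
                                               p("daily_summary.csv"))
  if (!is.null(report$stats)) readr::write_csv(report$stats, p("stats.csv"))
  if (!is.null(report$od)) {
    od_df <- cbind(data.frame(origin = rownames(report$od)),
                   as.data.frame(unclass(report$od)))
    readr::write_csv(od_df, p("od_matrix.csv"))
    readr::write_csv(report$destination_shares,
                     p("destination_shares.csv"))
    readr::write_csv(report$surplus, p("holiday_surplus.csv"))
  }
  yaml::write_yaml(report$manifest, p("manifest.yaml"))
  invisible(report)
}

#' Path to the bundled provincial estimation table
#'
#' The published provincial table (internet penetration in percent,
#' app-enumerated social-networking population, published population
#' estimate and percentage of adult men) shipped as plain CSV, used to
#' reproduce the headline reconstruction without any download.
#'
#' @return File path to `table1.csv` in the installed package.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.csv", package = "appcrc",
              mustWork = TRUE)
}

#' Reconstruct the provincial estimation table
#'
#' Recomputes every provincial population estimate as
#' `round(social_networking_msm / (internet_penetration / 100))` (half away
#' from zero) and the national total as the rounded sum of the unrounded
#' provincial quotients. When the input carries the published `msm_n`
#' column, each reconstruction is checked against it.
#'
#' @param table1 A data frame with columns `province`,
#'   `internet_penetration` (percent), `social_networking_msm`, optionally
#'   `msm_n`; or a CSV path; or NULL for the bundled table.
#' @return Tibble with `msm_estimate` and (when expectations are present)
#'   `matched`, plus attributes `national_sum`, `national_mean`,
#'   `n_matched`.
#' @examples
#' recon <- reproduce_table1()
#' attr(recon, "national_sum")
#' @export
reproduce_table1 <- function(table1 = NULL) {
  if (is.null(table1)) table1 <- table1_path()
  if (is.character(table1)) {
    table1 <- readr::read_csv(table1, show_col_types = FALSE)
  }
  needed <- c("province", "internet_penetration", "social_networking_msm")
  missing <- setdiff(needed, names(table1))
  if (length(missing)) {
    stop("table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(table1$internet_penetration) |
                 table1$internet_penetration <= 0 |
                 table1$internet_penetration > 100 |
                 !is.finite(table1$social_networking_msm))
  if (length(bad)) {
    stop("malformed row(s) at line ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(table1) |>
    dplyr::mutate(msm_estimate = adjust_by_penetration(
      .data$social_networking_msm, .data$internet_penetration / 100))
  raw_sum <- sum(out$social_networking_msm /
                   (out$internet_penetration / 100))
  attr(out, "national_sum") <- round_half_away(raw_sum)
  attr(out, "national_mean") <- round_half_away(raw_sum / nrow(out))
  if ("msm_n" %in% names(out)) {
    out$matched <- out$msm_estimate == out$msm_n
    attr(out, "n_matched") <- sum(out$matched)
  }
  out
}
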