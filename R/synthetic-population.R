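#' Synthetic province profiles
#'
#' Generates an abstract set of provinces (strata) with adult-male
#' populations, internet penetration, a ground-truth MSM prevalence, and
#' planar centroids. Provinces are laid out on a jittered lattice in km
#' coordinates; no real geography is used. The adult-male counts are scaled
#' so that the ground-truth MSM population, `sum(round(adult_men *
#' msm_prevalence))`, is close to `total_agents`.
#'
#' @param n_provinces Number of provinces to generate.
#' @param total_agents Approximate ground-truth total MSM population across
#'   all provinces.
#' @param seed Integer seed; fixed seed gives identical profiles.
#' @return A tibble with columns `province`, `adult_men`,
#'   `internet_penetration`, `msm_prevalence`, `x_km`, `y_km`.
#' @examples
#' synthetic_provinces(n_provinces = 5, total_agents = 1000, seed = 1)
#' @export
synthetic_provinces <- function(n_provinces = 10, total_agents = 50000,
                                seed = 1) {
  stopifnot(n_provinces >= 1, total_agents >= n_provinces)
  set.seed(seed)
  w <- stats::rlnorm(n_provinces, meanlog = 0, sdlog = 0.7)
  prevalence <- stats::runif(n_provinces, 0.015, 0.025)
  adult_men <- round_half_away(w / sum(w) * total_agents / prevalence)
  penetration <- stats::runif(n_provinces, 0.4, 0.8)
  ncol_grid <- ceiling(sqrt(n_provinces))
  idx <- seq_len(n_provinces) - 1L
  tibble::tibble(
    province = sprintf("P%02d", seq_len(n_provinces)),
    adult_men = as.numeric(adult_men),
    internet_penetration = penetration,
    msm_prevalence = prevalence,
    x_km = (idx %% ncol_grid) * 300 + stats::runif(n_provinces, -50, 50),
    y_km = (idx %/% ncol_grid) * 300 + stats::runif(n_provinces, -50, 50)
  )
}

validate_profiles <- function(provinces) {
  if (!is.data.frame(provinces) || nrow(provinces) == 0) {
    stop("`provinces` must be a non-empty data frame of province profiles",
         call. = FALSE)
  }
  needed <- c("province", "internet_penetration")
  missing <- setdiff(needed, names(provinces))
  if (length(missing)) {
    stop("province profiles lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(provinces$province)) {
    stop("province names must be unique", call. = FALSE)
  }
  if ("adult_men" %in% names(provinces) && any(provinces$adult_men <= 0)) {
    stop("`adult_men` must be positive", call. = FALSE)
  }
  check_fraction(provinces$internet_penetration, "internet_penetration")
  if ("msm_prevalence" %in% names(provinces)) {
    check_fraction(provinces$msm_prevalence, "msm_prevalence",
                   max_closed = FALSE)
  }
  invisible(provinces)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: the province profiles, the two
#' observation windows (a holiday window during which agents sit in their
#' home province, and nonholiday windows during which they sit in their work
#' province), the migrant share, the daily online-probability model, and the
#' enumeration grid spacing. A fixed `seed` makes the whole simulation
#' reproducible byte for byte.
#'
#' @param provinces Province profile data frame (see [synthetic_provinces()]);
#'   must include a `msm_prevalence` column for ground-truth sizes and
#'   `x_km`/`y_km` centroids.
#' @param seed Integer master seed.
#' @param n_days_holiday,n_days_nonholiday,n_days_recapture Window lengths in
#'   days. Defaults mirror a 5-day holiday, a 17-day working window used as
#'   the first capture sample, and a 14-day second capture sample months
#'   later.
#' @param migrant_fraction Share of agents whose work province differs from
#'   their home province.
#' @param grid_spacing_km Enumeration lattice spacing (km).
#' @param p_online Daily online probability for app-using agents: a single
#'   number for constant catchability (the estimator's assumption), or two
#'   positive Beta shape parameters for per-agent heterogeneity (default
#'   `c(2, 6)`, mean 0.25).
#' @param location_sd_km Standard deviation of the isotropic Gaussian that
#'   scatters agents around their province centroid.
#' @param holiday_start,nonholiday_start,recapture_start ISO-8601 first days
#'   of the three windows.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(synthetic_provinces(3, 500, seed = 1), seed = 1)
#' @export
sim_config <- function(provinces, seed = 1L,
                       n_days_holiday = 5L, n_days_nonholiday = 17L,
                       n_days_recapture = 14L,
                       migrant_fraction = 0.2, grid_spacing_km = 5,
                       p_online = c(2, 6), location_sd_km = 30,
                       holiday_start = "2018-02-16",
                       nonholiday_start = "2018-03-12",
                       recapture_start = "2018-10-22") {
  validate_profiles(provinces)
  if (!all(c("adult_men", "msm_prevalence", "x_km", "y_km") %in%
             names(provinces))) {
    stop(paste("simulation profiles need `adult_men`, `msm_prevalence`",
               "and `x_km`/`y_km` columns"), call. = FALSE)
  }
  check_counts(n_days_holiday = n_days_holiday,
               n_days_nonholiday = n_days_nonholiday,
               n_days_recapture = n_days_recapture, allow_zero = FALSE)
  check_fraction(migrant_fraction, "migrant_fraction", min_open = FALSE)
  if (grid_spacing_km <= 0) stop("`grid_spacing_km` must be positive",
                                 call. = FALSE)
  if (!length(p_online) %in% 1:2 || any(p_online <= 0 & length(p_online) == 2)) {
    stop("`p_online` must be a constant probability or two Beta shapes",
         call. = FALSE)
  }
  if (length(p_online) == 1) check_fraction(p_online, "p_online",
                                            min_open = FALSE)
  if (location_sd_km < 0) stop("`location_sd_km` must be non-negative",
                               call. = FALSE)
  structure(
    list(seed = as.integer(seed), provinces = tibble::as_tibble(provinces),
         n_days_holiday = as.integer(n_days_holiday),
         n_days_nonholiday = as.integer(n_days_nonholiday),
         n_days_recapture = as.integer(n_days_recapture),
         migrant_fraction = migrant_fraction,
         grid_spacing_km = grid_spacing_km,
         p_online = p_online, location_sd_km = location_sd_km,
         holiday_start = as.Date(holiday_start),
         nonholiday_start = as.Date(nonholiday_start),
         recapture_start = as.Date(recapture_start)),
    class = "sim_config"
  )
}

#' Demonstration configuration
#'
#' A scaled-down but fully featured study: 10 synthetic provinces holding
#' about 50,000 agents, a 20% migrant share, constant daily online
#' probability 0.25 (so both capture samples satisfy equal catchability),
#' and shortened 5/7/7-day windows that keep a full pipeline run fast while
#' leaving realistic day-to-day sampling noise.
#'
#' @param seed Integer master seed.
#' @return A `sim_config` object.
#' @export
demo_config <- function(seed = 1L) {
  sim_config(
    provinces = synthetic_provinces(10, 50000, seed = seed),
    seed = seed, n_days_holiday = 5L, n_days_nonholiday = 7L,
    n_days_recapture = 7L, migrant_fraction = 0.2,
    grid_spacing_km = 5, p_online = 0.25, location_sd_km = 30
  )
}

#' Ground-truth population sizes implied by a configuration
#'
#' @param config A `sim_config`.
#' @return Tibble with `province`, `n_true` (agents whose home is that
#'   province) plus the national total as attribute `total`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- dplyr::mutate(
    config$provinces[, c("province", "adult_men", "msm_prevalence")],
    n_true = round_half_away(.data$adult_men * .data$msm_prevalence)
  )[, c("province", "n_true")]
  attr(out, "total") <- sum(out$n_true)
  out
}

#' Generate the closed synthetic agent population
#'
#' Per province `i`, exactly `round(adult_men_i * msm_prevalence_i)` agents
#' are created with that home province (rounding half away from zero). Each
#' agent adopts the app independently with probability equal to the home
#' province's internet penetration — the assumption later inverted by the
#' penetration multiplier. Exactly `round(migrant_fraction * n_agents)`
#' agents, drawn uniformly, receive a work province different from home,
#' with destination probability proportional to the candidate provinces'
#' adult-male counts. App users get a daily online probability (constant or
#' Beta-distributed, see [sim_config()]); non-users have probability 0.
#' Agents keep a fixed Gaussian offset from whichever province centroid they
#' currently occupy, so a migrant's location moves with them between the
#' holiday and nonholiday windows. The population is closed: no agent enters
#' or leaves between windows.
#'
#' @param config A `sim_config`.
#' @return Tibble of agents: `id`, `home_province`, `work_province`,
#'   `uses_app`, `p_online`, `dx_km`, `dy_km` (offset from the occupied
#'   centroid).
#' @examples
#' cfg <- sim_config(synthetic_provinces(3, 300, seed = 2), seed = 2)
#' pop <- generate_population(cfg)
#' table(pop$home_province)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  prov <- config$provinces
  n_per <- round_half_away(prov$adult_men * prov$msm_prevalence)
  if (sum(n_per) == 0) stop("configuration implies an empty population",
                            call. = FALSE)
  n_tot <- sum(n_per)
  home <- rep(prov$province, times = n_per)

  uses_app <- stats::runif(n_tot) <
    rep(prov$internet_penetration, times = n_per)
  p_online <- if (length(config$p_online) == 1) {
    rep(config$p_online, n_tot)
  } else {
    stats::rbeta(n_tot, config$p_online[1], config$p_online[2])
  }
  p_online[!uses_app] <- 0

  work <- home
  n_mig <- round_half_away(config$migrant_fraction * n_tot)
  if (n_mig > 0 && nrow(prov) > 1) {
    movers <- sample.int(n_tot, n_mig)
    w <- prov$adult_men
    names(w) <- prov$province
    # destination weights proportional to adult men, excluding the home province
    work[movers] <- vapply(home[movers], function(h) {
      cand <- prov$province[prov$province != h]
      sample(cand, 1L, prob = w[cand])
    }, character(1))
  }

  tibble::tibble(
    id = sprintf("a%07d", seq_len(n_tot)),
    home_province = home, work_province = work,
    uses_app = uses_app, p_online = p_online,
    dx_km = stats::rnorm(n_tot, 0, config$location_sd_km),
    dy_km = stats::rnorm(n_tot, 0, config$location_sd_km)
  )
}

#' Simulate an observation window
#'
#' Each app-using agent appears independently on each day of the window with
#' its daily online probability. During the holiday window an agent sits in
#' its home province; during nonholiday windows, in its work province.
#' Positions are the occupied province centroid plus the agent's fixed
#' offset, and each observation is tagged with the enumeration-lattice cell
#' containing it (lattice anchored at the coordinate origin with the
#' configured spacing).
#'
#' @param agents Agent tibble from [generate_population()].
#' @param config The `sim_config` the agents were generated from (supplies
#'   centroids, window lengths, start dates and grid spacing).
#' @param period `"holiday"`, `"nonholiday"` or `"recapture"` (the second
#'   capture sample, also taken at work locations).
#' @param seed Integer seed for the Bernoulli online draws.
#' @param n_days Optional window-length override.
#' @return An online-roster tibble: `user_id`, `date`, `province`,
#'   `cell_id`, `x_km`, `y_km`, one row per agent-day online.
#' @examples
#' cfg <- sim_config(synthetic_provinces(3, 300, seed = 2), seed = 2,
#'                   p_online = 1)
#' pop <- generate_population(cfg)
#' roster <- simulate_period(pop, cfg, "holiday", seed = 9)
#' @export
simulate_period <- function(agents, config,
                            period = c("holiday", "nonholiday", "recapture"),
                            seed = 1L, n_days = NULL) {
  period <- match.arg(period)
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(agents) || nrow(agents) == 0) {
    stop("`agents` must be a non-empty agent tibble", call. = FALSE)
  }
  n_days <- n_days %||% switch(period,
    holiday = config$n_days_holiday,
    nonholiday = config$n_days_nonholiday,
    recapture = config$n_days_recapture)
  check_counts(n_days = n_days, allow_zero = FALSE)
  start <- switch(period, holiday = config$holiday_start,
                  nonholiday = config$nonholiday_start,
                  recapture = config$recapture_start)

  prov_col <- if (period == "holiday") agents$home_province else
    agents$work_province
  prov <- config$provinces
  ix <- match(prov_col, prov$province)
  x <- prov$x_km[ix] + agents$dx_km
  y <- prov$y_km[ix] + agents$dy_km

  set.seed(seed)
  n <- nrow(agents)
  online <- matrix(stats::runif(n * n_days) < agents$p_online,
                   nrow = n, ncol = n_days)
  hit <- which(online, arr.ind = TRUE)
  s <- config$grid_spacing_km
  tibble::tibble(
    user_id = agents$id[hit[, 1]],
    date = start + (hit[, 2] - 1L),
    province = prov_col[hit[, 1]],
    cell_id = sprintf("c%d_%d", floor(x[hit[, 1]] / s), floor(y[hit[, 1]] / s)),
    x_km = x[hit[, 1]],
    y_km = y[hit[, 1]]
  ) |>
    dplyr::arrange(.data$date, .data$user_id)
}
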