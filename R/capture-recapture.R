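#' Lincoln-Petersen (Chapman) population estimate
#'
#' Two-sample closed-population estimator: with `m` individuals captured and
#' marked in the first sample, `n` in the second, and `k` seen in both, the
#' population size is estimated as `(m + 1) * (n + 1) / (k + 1) - 1`
#' (Chapman's bias-reduced form). Evaluated in full double precision with no
#' intermediate rounding. `k = 0` is admitted but the estimate is then
#' highly unstable; a warning is raised.
#'
#' Requires a closed population, independent samples, and equal capture
#' probability across individuals.
#'
#' @param m,n,k Non-negative integer vectors with `k <= pmin(m, n)`.
#' @return Numeric vector of population-size estimates.
#' @examples
#' lincoln_petersen(10, 10, 5)            # 19.1667
#' lincoln_petersen(2449493, 2474293, 1332632)
#' @export
lincoln_petersen <- function(m, n, k) {
  check_crc_sample(m, n, k)
  if (any(k == 0)) {
    warning("k = 0: Lincoln-Petersen estimate is unstable", call. = FALSE)
  }
  (m + 1) * (n + 1) / (k + 1) - 1
}

#' Chapman variance of the two-sample estimate
#'
#' `(m+1)(n+1)(m-k)(n-k) / ((k+1)^2 (k+2))`; zero when the samples overlap
#' completely. A 95% confidence interval is the estimate plus/minus
#' `1.96 * sqrt(variance)` (normal approximation).
#'
#' @inheritParams lincoln_petersen
#' @return Numeric vector of variances.
#' @examples
#' chapman_variance(10, 10, 5)  # 12.004
#' @export
chapman_variance <- function(m, n, k) {
  check_crc_sample(m, n, k)
  (m + 1) * (n + 1) * (m - k) * (n - k) / ((k + 1)^2 * (k + 2))
}

check_crc_sample <- function(m, n, k) {
  check_counts(m = m, n = n, k = k)
  if (any(k > pmin(m, n))) {
    stop("recaptures `k` cannot exceed either sample size", call. = FALSE)
  }
  invisible(TRUE)
}

#' Scale an app-user estimate to the whole population
#'
#' Divides the estimated app-using (social-networking) population by the
#' internet-penetration fraction — the multiplier assumption that a known
#' share of the target population is reachable online — and rounds half away
#' from zero to a person count.
#'
#' @param n_sn_hat Estimated app-using population (real, persons).
#' @param penetration Internet-penetration fraction in (0, 1].
#' @return Whole-number population estimate(s).
#' @examples
#' adjust_by_penetration(516113, 0.740)  # 697450
#' @export
adjust_by_penetration <- function(n_sn_hat, penetration) {
  check_fraction(penetration, "penetration")
  round_half_away(n_sn_hat / penetration)
}

#' Derive per-stratum capture samples from two enumeration rosters
#'
#' Assigns each user a province per sampling window (modal province over the
#' user's observed days, ties broken by earliest observation, see
#' [assign_period_province()]) and tabulates, per province, the first-sample
#' count `m`, second-sample count `n`, and recaptures `k`. A user seen in
#' both windows counts as a recapture of the province where it was first
#' captured, mirroring physical marking at first capture.
#'
#' @param roster1,roster2 Online rosters (tibbles with `user_id`, `date`,
#'   `province`) for the two sampling windows.
#' @return Tibble with columns `province`, `m`, `n`, `k`.
#' @export
capture_samples <- function(roster1, roster2) {
  a1 <- assign_period_province(roster1)
  a2 <- assign_period_province(roster2)
  recap <- dplyr::semi_join(a1, a2, by = "user_id")
  provinces <- sort(union(a1$province, a2$province))
  tibble::tibble(
    province = provinces,
    m = as.integer(table(factor(a1$province, provinces))),
    n = as.integer(table(factor(a2$province, provinces))),
    k = as.integer(table(factor(recap$province, provinces)))
  )
}

#' Estimate stratum and total population sizes
#'
#' Applies the Lincoln-Petersen estimator with Chapman variance to each
#' province's capture sample, scales the app-user estimates by provincial
#' internet penetration, and aggregates nationally. Provincial person counts
#' are rounded (half away from zero) for reporting, but the national point
#' estimate is the rounded sum of the *unrounded* provincial estimates, so
#' no rounding error accumulates across strata. The national variance is the
#' sum of stratum Chapman variances scaled by `1 / penetration^2`
#' (independent strata; penetration treated as a known constant), and the
#' 95% CI is the normal approximation. When the profiles carry `adult_men`,
#' estimates are also expressed as a percentage of adult men.
#'
#' @param samples Data frame of capture samples: `province`, `m`, `n`, `k`.
#' @param profiles Province profiles with `province`,
#'   `internet_penetration`, and optionally `adult_men`.
#' @return An object of class `crc_estimate`: a list with `strata` (tibble
#'   of per-province estimates) and `national` (point estimate, variance,
#'   CI, and percentage of adult men when available). Use [tidy()],
#'   [glance()] or [autoplot()] on it.
#' @examples
#' samples <- data.frame(province = "A", m = 1000, n = 1000, k = 400)
#' profiles <- data.frame(province = "A", internet_penetration = 0.5,
#'                        adult_men = 2e5)
#' est <- estimate_population(samples, profiles)
#' glance(est)
#' @export
estimate_population <- function(samples, profiles) {
  stopifnot(is.data.frame(samples),
            all(c("province", "m", "n", "k") %in% names(samples)))
  validate_profiles(profiles)
  missing <- setdiff(samples$province, profiles$province)
  if (length(missing)) {
    stop("no province profile for stratum: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  strata <- samples |>
    dplyr::inner_join(profiles, by = "province") |>
    dplyr::mutate(
      n_sn_hat = lincoln_petersen(.data$m, .data$n, .data$k),
      variance = chapman_variance(.data$m, .data$n, .data$k),
      ci_low = .data$n_sn_hat - 1.96 * sqrt(.data$variance),
      ci_high = .data$n_sn_hat + 1.96 * sqrt(.data$variance),
      n_total_raw = .data$n_sn_hat / .data$internet_penetration,
      n_total_hat = round_half_away(.data$n_total_raw),
      n_total_ci_low = round_half_away(.data$ci_low /
                                         .data$internet_penetration),
      n_total_ci_high = round_half_away(.data$ci_high /
                                          .data$internet_penetration)
    )
  if ("adult_men" %in% names(strata)) {
    strata <- dplyr::mutate(
      strata, pct_adult_men = round(100 * .data$n_total_raw /
                                      .data$adult_men, 2))
  }
  nat_var <- sum(strata$variance / strata$internet_penetration^2)
  nat_raw <- sum(strata$n_total_raw)
  national <- list(
    n_total_hat = round_half_away(nat_raw),
    variance = nat_var,
    ci_low = round_half_away(nat_raw - 1.96 * sqrt(nat_var)),
    ci_high = round_half_away(nat_raw + 1.96 * sqrt(nat_var)),
    n_sn_hat = sum(strata$n_sn_hat)
  )
  if ("adult_men" %in% names(strata)) {
    national$pct_adult_men <- round(100 * nat_raw / sum(strata$adult_men), 3)
  }
  keep <- intersect(
    c("province", "m", "n", "k", "internet_penetration", "n_sn_hat",
      "variance", "ci_low", "ci_high", "n_total_hat", "n_total_ci_low",
      "n_total_ci_high", "pct_adult_men"),
    names(strata))
  structure(list(strata = strata[, keep], national = national),
            class = "crc_estimate")
}

#' @export
print.crc_estimate <- function(x, ...) {
  cat("Two-sample capture-recapture estimate,",
      nrow(x$strata), "strata\n")
  cat(sprintf("National total: %s (95%% CI %s-%s)\n",
              format(x$national$n_total_hat, big.mark = ","),
              format(x$national$ci_low, big.mark = ","),
              format(x$national$ci_high, big.mark = ",")))
  print(x$strata, ...)
  invisible(x)
}

#' Tidy a capture-recapture fit
#'
#' @param x A `crc_estimate`.
#' @param ... Unused.
#' @return The per-stratum estimate tibble.
#' @exportS3Method generics::tidy
tidy.crc_estimate <- function(x, ...) tibble::as_tibble(x$strata)

#' One-row national summary of a capture-recapture fit
#'
#' @param x A `crc_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the national point estimate, variance, CI,
#'   app-user estimate and (when available) percentage of adult men.
#' @exportS3Method generics::glance
glance.crc_estimate <- function(x, ...) {
  tibble::as_tibble(x$national[!vapply(x$national, is.null, logical(1))])
}

#' Plot per-stratum population estimates
#'
#' Point estimates with 95% intervals, strata ordered by size.
#'
#' @param object A `crc_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crc_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$province, .data$n_total_hat),
    y = .data$n_total_hat,
    ymin = .data$n_total_ci_low, ymax = .data$n_total_ci_high)) +
    ggplot2::geom_pointrange() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Estimated population",
                  title = "Penetration-adjusted capture-recapture estimates") +
    ggplot2::theme_minimal()
}

#' Simulate repeated two-sample capture experiments
#'
#' Draws `replicates` independent experiments on a closed population of size
#' `N`: each individual enters sample 1 with probability `p1` and sample 2
#' with probability `p2`, independently, so `m ~ Bin(N, p1)`,
#' `n ~ Bin(N, p2)` and `k | m, n` is hypergeometric. Used to study the
#' estimator's bias and confidence-interval coverage.
#'
#' @param N True population size.
#' @param p1,p2 Capture probabilities of the two samples.
#' @param replicates Number of simulated experiments.
#' @param seed Integer seed.
#' @return Tibble with `m`, `n`, `k`, `estimate`, `variance`, `ci_low`,
#'   `ci_high`, `covered` (does the 95% CI contain `N`).
#' @examples
#' sims <- simulate_crc(1000, 0.3, 0.3, replicates = 50, seed = 1)
#' mean(sims$estimate)
#' @export
simulate_crc <- function(N, p1, p2, replicates = 1000, seed = 1L) {
  check_counts(N = N, replicates = replicates, allow_zero = FALSE)
  check_fraction(c(p1, p2), "p1/p2")
  set.seed(seed)
  m <- stats::rbinom(replicates, N, p1)
  n <- stats::rbinom(replicates, N, p2)
  k <- stats::rhyper(replicates, m, N - m, n)
  est <- suppressWarnings(lincoln_petersen(m, n, k))
  v <- chapman_variance(m, n, k)
  half <- 1.96 * sqrt(v)
  tibble::tibble(
    m = m, n = n, k = k, estimate = est, variance = v,
    ci_low = est - half, ci_high = est + half,
    covered = est - half <= N & N <= est + half
  )
}
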