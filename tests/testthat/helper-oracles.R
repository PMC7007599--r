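# Brute-force re-derivations kept deliberately independent of the package's
# implementation paths; used to cross-check every statistic on tiny inputs.

# weighted Gini via the pairwise mean-absolute-difference of per-capita
# values: sum_ij w_i w_j |x_i - x_j| / (2 (sum w)^2 xbar)
oracle_gini <- function(v, w = rep(1, length(v))) {
  x <- v / w
  xbar <- sum(v) / sum(w)
  num <- 0
  for (i in seq_along(v)) {
    for (j in seq_along(v)) num <- num + w[i] * w[j] * abs(x[i] - x[j])
  }
  num / (2 * sum(w)^2 * xbar)
}

# q as between-stratum over total sum of squares
oracle_q <- function(y, strata) {
  strata <- as.character(strata)
  ybar <- mean(y)
  ssb <- 0
  for (s in unique(strata)) {
    idx <- strata == s
    ssb <- ssb + sum(idx) * (mean(y[idx]) - ybar)^2
  }
  ssb / sum((y - ybar)^2)
}

oracle_cv <- function(v) sqrt(sum((v - mean(v))^2) / length(v)) / mean(v)

oracle_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# K nearest users to a point, nearest first, ties by user id
oracle_knn <- function(center, users, K) {
  d <- sqrt((users$x_km - center[1])^2 + (users$y_km - center[2])^2)
  users$user_id[order(d, users$user_id)][seq_len(min(K, nrow(users)))]
}

# OD matrix by explicit double loop
oracle_od <- function(assignments, provinces) {
  m <- matrix(0L, length(provinces), length(provinces),
              dimnames = list(provinces, provinces))
  for (r in seq_len(nrow(assignments))) {
    i <- assignments$holiday_province[r]
    j <- assignments$nonholiday_province[r]
    m[i, j] <- m[i, j] + 1L
  }
  m
}

# exact expectation of the Lincoln-Petersen estimate for a population of N
# under independent Bernoulli capture, summing over all (m, n, k) outcomes
exact_lp_mean <- function(N, p1, p2) {
  tot <- 0
  for (m in 0:N) {
    pm <- dbinom(m, N, p1)
    if (pm < 1e-15) next
    for (n in 0:N) {
      pn <- dbinom(n, N, p2)
      if (pn < 1e-15) next
      ks <- max(0, m + n - N):min(m, n)
      pk <- dhyper(ks, m, N - m, n)
      tot <- tot + pm * pn * sum(pk * ((m + 1) * (n + 1) / (ks + 1) - 1))
    }
  }
  tot
}

# small handmade province set with exact ground-truth sizes
tiny_profiles <- function() {
  tibble::tibble(
    province = c("A", "B", "C"),
    adult_men = c(100000, 50000, 25000),
    internet_penetration = c(0.8, 0.5, 0.6),
    msm_prevalence = c(0.02, 0.02, 0.04),
    x_km = c(0, 300, 0),
    y_km = c(0, 0, 300)
  )
}

tiny_config <- function(seed = 1L, p_online = 0.5, ...) {
  sim_config(tiny_profiles(), seed = seed, n_days_holiday = 3L,
             n_days_nonholiday = 4L, n_days_recapture = 4L,
             p_online = p_online, ...)
}
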