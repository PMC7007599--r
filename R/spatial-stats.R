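#' Gini coefficient via the Lorenz curve
#'
#' Measures how unequally a quantity (e.g. per-province population counts)
#' is distributed, optionally relative to a size weight (e.g. adult men per
#' province): 0 is perfect equality, values approaching 1 indicate extreme
#' concentration. Units are sorted by `values / weights` ascending, weight
#' and value shares accumulated, and the Gini computed from the trapezoidal
#' area under the Lorenz curve: `G = 1 - sum((W_i - W_{i-1}) * (L_i +
#' L_{i-1}))`. Without weights each unit counts equally.
#'
#' @param values Non-negative numeric vector, not all zero.
#' @param weights Optional non-negative weights with positive sum.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' gini(c(0, 0, 0, 1))       # 0.75
#' gini(c(5, 5, 5, 5))       # 0
#' @export
gini <- function(values, weights = NULL) {
  if (!is.numeric(values) || length(values) == 0 || anyNA(values)) {
    stop("`values` must be a numeric vector without NAs", call. = FALSE)
  }
  if (any(values < 0)) stop("`values` must be non-negative", call. = FALSE)
  if (all(values == 0)) stop("`values` are all zero; Gini undefined",
                             call. = FALSE)
  weights <- weights %||% rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("`weights` must be non-negative, match `values`, and sum > 0",
         call. = FALSE)
  }
  ord <- order(values / weights)
  w <- weights[ord] / sum(weights)
  v <- values[ord] / sum(values)
  W <- cumsum(w)
  L <- cumsum(v)
  1 - sum(diff(c(0, W)) * (L + c(0, L[-length(L)])))
}

#' Geographical-detector q statistic
#'
#' Fraction of a variable's spatial variance explained by a stratification:
#' `q = 1 - sum_h(N_h * sigma_h^2) / (N * sigma^2)` with population
#' variances. `q = 1` when the variable is constant within every stratum
#' but differs between strata; `q = 0` when the stratification explains
#' nothing.
#'
#' @param y Numeric vector, one value per unit.
#' @param strata Stratum label per unit (coerced to factor); every stratum
#'   must be non-empty.
#' @return q in `[0, 1]`.
#' @examples
#' geodetector_q(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # 0.8
#' @export
geodetector_q <- function(y, strata) {
  if (length(y) < 2 || length(strata) != length(y)) {
    stop("need >= 2 units and one stratum label per unit", call. = FALSE)
  }
  if (anyNA(y) || anyNA(strata)) stop("NAs not allowed", call. = FALSE)
  strata <- droplevels(factor(strata))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("total variance is zero; q undefined", call. = FALSE)
  ssw <- sum(tapply(y, strata, function(v) sum((v - mean(v))^2)))
  1 - ssw / sst
}

#' Similarity of two spatial patterns
#'
#' Adapts the geographical-detector q statistic to compare two continuous
#' distributions over the same units: the first pattern is discretized into
#' `n_strata` equal-size quantile classes (ties resolved by rank order), and
#' q measures how much of the second pattern's variance those classes
#' explain. A permutation p-value (unit labels shuffled) tests the null of
#' no association; under the null the expected q is approximately
#' `(n_strata - 1) / (n - 1)`.
#'
#' @param y1,y2 Numeric vectors over the same units, `length >= n_strata`.
#' @param n_strata Number of quantile classes for `y1`.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: `q`, `p_value`, `n_strata`, `n_perm`.
#' @examples
#' set.seed(1)
#' a <- rgamma(31, 2); b <- a * 2 + rnorm(31, 0, 0.1)
#' pattern_similarity(a, b, n_strata = 5, n_perm = 199)
#' @export
pattern_similarity <- function(y1, y2, n_strata = 5, n_perm = 999,
                               seed = 1L) {
  if (length(y1) != length(y2)) stop("`y1` and `y2` must match in length",
                                     call. = FALSE)
  if (length(y1) < n_strata) stop("need at least `n_strata` units",
                                  call. = FALSE)
  classes <- dplyr::ntile(rank(y1, ties.method = "first"), n_strata)
  if (length(unique(classes)) < n_strata) {
    warning("degenerate quantiles: fewer classes than requested",
            call. = FALSE)
  }
  q_obs <- geodetector_q(y2, classes)
  set.seed(seed)
  q_perm <- vapply(seq_len(n_perm), function(i) {
    geodetector_q(sample(y2), classes)
  }, numeric(1))
  tibble::tibble(
    q = q_obs,
    p_value = (1 + sum(q_perm >= q_obs)) / (n_perm + 1),
    n_strata = length(unique(classes)),
    n_perm = n_perm
  )
}

#' Percentage share of a subset
#'
#' `100 * sum(values[subset]) / sum(values)`, rounded to two decimals —
#' the "top provinces account for X% of the total" style summary.
#'
#' @param values Numeric vector with positive sum.
#' @param subset Logical or integer index of the subset.
#' @return Percentage rounded to 2 decimal places.
#' @examples
#' share_of_total(c(30, 20, 10), 1)  # 50
#' @export
share_of_total <- function(values, subset) {
  if (!is.numeric(values) || sum(values) <= 0) {
    stop("`values` must have a positive total", call. = FALSE)
  }
  round(100 * sum(values[subset]) / sum(values), 2)
}

#' Coefficient of variation
#'
#' Standard deviation over the mean; the population (divide by n) form is
#' the default, the sample (n - 1) form is available.
#'
#' @param values Numeric vector with positive mean.
#' @param type `"population"` or `"sample"` standard deviation.
#' @return Non-negative scalar.
#' @examples
#' coefficient_of_variation(c(1, 1, 1, 5))  # 0.866
#' @export
coefficient_of_variation <- function(values,
                                     type = c("population", "sample")) {
  type <- match.arg(type)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive", call. = FALSE)
  s <- if (type == "population") {
    sqrt(mean((values - m)^2))
  } else {
    stats::sd(values)
  }
  s / m
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the argument checks the pipeline
#' needs (length >= 3, both vectors non-constant).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Lorenz curve plot
#'
#' Visualises the inequality summarised by [gini()]: cumulative share of
#' `values` against cumulative share of `weights` (population), with the
#' equality diagonal.
#'
#' @inheritParams gini
#' @return A ggplot object.
#' @export
plot_lorenz <- function(values, weights = NULL) {
  weights <- weights %||% rep(1, length(values))
  ord <- order(values / weights)
  df <- tibble::tibble(
    W = c(0, cumsum(weights[ord]) / sum(weights)),
    L = c(0, cumsum(values[ord]) / sum(values))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$W, .data$L)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cumulative population share",
                  y = "Cumulative value share",
                  title = sprintf("Lorenz curve (Gini = %.3f)",
                                  gini(values, weights))) +
    ggplot2::theme_minimal()
}
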