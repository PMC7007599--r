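#' Assign each user a province for an observation window
#'
#' A user observed on several days (possibly in several provinces, e.g.
#' while travelling) is assigned its modal province — the province with the
#' most distinct observed days in the window. Ties are broken by the
#' earliest observation date among the tied provinces, then by lexicographic
#' province name. The rule is deterministic so period assignments are
#' reproducible.
#'
#' @param roster Online-roster tibble with `user_id`, `date`, `province`.
#' @param user_id Optional single user id; if given, returns that user's
#'   assigned province (error when absent from the roster).
#' @return A tibble `user_id`, `province` covering every user in the roster,
#'   or a single province name when `user_id` is supplied.
#' @examples
#' r <- tibble::tibble(user_id = "u1",
#'                     date = as.Date("2018-02-16") + 0:4,
#'                     province = c("A", "A", "B", "A", "B"))
#' assign_period_province(r, "u1")  # "A"
#' @export
assign_period_province <- function(roster, user_id = NULL) {
  stopifnot(is.data.frame(roster),
            all(c("user_id", "date", "province") %in% names(roster)))
  if (!is.null(user_id)) {
    sub <- roster[roster$user_id == user_id, , drop = FALSE]
    if (nrow(sub) == 0) stop("user '", user_id, "' not present in roster",
                             call. = FALSE)
    roster <- sub
  }
  out <- roster |>
    dplyr::distinct(.data$user_id, .data$date, .data$province) |>
    dplyr::summarise(n_days = dplyr::n(), first_date = min(.data$date),
                     .by = c("user_id", "province")) |>
    dplyr::arrange(.data$user_id, dplyr::desc(.data$n_days),
                   .data$first_date, .data$province)
  out <- out[!duplicated(out$user_id), c("user_id", "province")]
  if (!is.null(user_id)) out$province else out
}

#' Users present in both observation windows
#'
#' Intersects the holiday and nonholiday rosters by user id and attaches
#' each co-occurring user's period provinces: the holiday province is read
#' as the user's origin (home) and the nonholiday province as the
#' destination (workplace). A user is a migrant when the two differ.
#'
#' @param holiday,nonholiday Online rosters for the two periods sharing an
#'   id namespace.
#' @return Tibble `user_id`, `holiday_province`, `nonholiday_province`,
#'   `migrant`.
#' @export
co_occurring_users <- function(holiday, nonholiday) {
  a_h <- assign_period_province(holiday)
  a_n <- assign_period_province(nonholiday)
  dplyr::inner_join(
    dplyr::rename(a_h, holiday_province = "province"),
    dplyr::rename(a_n, nonholiday_province = "province"),
    by = "user_id"
  ) |>
    dplyr::mutate(migrant = .data$holiday_province !=
                    .data$nonholiday_province)
}

#' Build the origin-destination matrix
#'
#' Cross-tabulates co-occurring users by holiday province (origin, rows)
#' and nonholiday province (destination, columns). The diagonal holds
#' non-migrants; off-diagonal cells are interprovincial migrant flows.
#'
#' @param assignments Tibble from [co_occurring_users()].
#' @param provinces Optional ordered province labels fixing the matrix
#'   dimensions; assignments naming an unlisted province raise an error.
#' @return Integer matrix of class `od_matrix` with province dimnames
#'   (rows = origins, columns = destinations).
#' @examples
#' a <- tibble::tibble(user_id = c("u1", "u2", "u3"),
#'                     holiday_province = c("A", "A", "B"),
#'                     nonholiday_province = c("A", "B", "A"))
#' build_od_matrix(a)
#' @export
build_od_matrix <- function(assignments, provinces = NULL) {
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0,
            all(c("holiday_province", "nonholiday_province") %in%
                  names(assignments)))
  seen <- union(assignments$holiday_province,
                assignments$nonholiday_province)
  if (is.null(provinces)) {
    provinces <- sort(seen)
  } else {
    unknown <- setdiff(seen, provinces)
    if (length(unknown)) {
      stop("assignments reference unknown province: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  counts <- table(factor(assignments$holiday_province, provinces),
                  factor(assignments$nonholiday_province, provinces))
  m <- matrix(as.integer(counts), nrow = length(provinces),
              dimnames = list(origin = provinces, destination = provinces))
  structure(m, class = c("od_matrix", "matrix", "array"))
}

#' Number of interprovincial migrants in an OD matrix
#'
#' @param od An `od_matrix`.
#' @return Total count minus the diagonal (non-migrants).
#' @export
migrant_count <- function(od) {
  stopifnot(inherits(od, "od_matrix"))
  sum(od) - sum(diag(od))
}

#' Long-format view of an OD matrix
#'
#' @param x An `od_matrix`.
#' @param ... Unused.
#' @return Tibble `origin`, `destination`, `n`, `migrant_flow` (FALSE on
#'   the diagonal).
#' @exportS3Method generics::tidy
tidy.od_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("origin", "destination", "n")
  tibble::as_tibble(df) |>
    dplyr::mutate(n = as.integer(.data$n),
                  migrant_flow = .data$origin != .data$destination) |>
    dplyr::arrange(.data$origin, .data$destination)
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("Origin-destination matrix: %d provinces, %s users, %s migrants (%.2f%%)\n",
              nrow(x), format(sum(x), big.mark = ","),
              format(migrant_count(x), big.mark = ","),
              100 * migrant_count(x) / sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Heatmap of interprovincial flows
#'
#' @param object An `od_matrix`.
#' @param include_diagonal Show non-migrant (diagonal) counts too?
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.od_matrix <- function(object, include_diagonal = FALSE, ...) {
  df <- tidy(object)
  if (!include_diagonal) df <- df[df$migrant_flow, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$destination, .data$origin,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Users") +
    ggplot2::labs(x = "Destination (nonholiday)", y = "Origin (holiday)",
                  title = "Interprovincial migration flows") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Top migrant destinations and their shares
#'
#' Ranks destinations by off-diagonal (migrant) inflow and reports each
#' destination's percentage of all interprovincial migrants.
#'
#' @param od An `od_matrix` with at least one migrant.
#' @param top Optional number of destinations to keep.
#' @param min_flow Optional minimum inflow for a destination to be listed
#'   (reporting filter only; the matrix is untouched).
#' @return Tibble `province`, `inflow`, `share_pct` (descending).
#' @export
destination_shares <- function(od, top = NULL, min_flow = NULL) {
  total <- migrant_count(od)
  if (total == 0) stop("no interprovincial migrants", call. = FALSE)
  inflow <- unname(colSums(od) - diag(od))
  out <- tibble::tibble(province = colnames(od), inflow = as.integer(inflow),
                        share_pct = round(100 * inflow / total, 2)) |>
    dplyr::arrange(dplyr::desc(.data$inflow), .data$province)
  if (!is.null(min_flow)) out <- out[out$inflow >= min_flow, ]
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Source composition of one destination's migrant inflow
#'
#' For a destination province, the percentage of its migrant inflow coming
#' from each origin, largest first.
#'
#' @param od An `od_matrix`.
#' @param destination Destination province name with positive migrant
#'   inflow.
#' @return Tibble `origin`, `n`, `share_pct` (descending).
#' @export
source_composition <- function(od, destination) {
  stopifnot(inherits(od, "od_matrix"))
  if (!destination %in% colnames(od)) {
    stop("unknown destination province '", destination, "'", call. = FALSE)
  }
  inflow <- stats::setNames(as.integer(od[, destination]), rownames(od))
  inflow[destination] <- 0L
  total <- sum(inflow)
  if (total == 0) stop("destination '", destination,
                       "' has no migrant inflow", call. = FALSE)
  tibble::tibble(origin = rownames(od), n = as.integer(inflow),
                 share_pct = round(100 * unname(inflow) / total, 2)) |>
    dplyr::filter(.data$origin != destination) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$origin)
}

#' Mean daily distinct users per province
#'
#' Averages, over the days of an observation window, the number of distinct
#' users seen in each province (days on which a province has no users count
#' as zero).
#'
#' @param roster Online roster (`user_id`, `date`, `province`).
#' @return Tibble `province`, `mean_daily`.
#' @export
daily_mean_counts <- function(roster) {
  stopifnot(is.data.frame(roster), nrow(roster) > 0)
  n_days <- dplyr::n_distinct(roster$date)
  roster |>
    dplyr::distinct(.data$date, .data$province, .data$user_id) |>
    dplyr::count(.data$province, name = "total") |>
    dplyr::mutate(mean_daily = .data$total / n_days) |>
    dplyr::select("province", "mean_daily") |>
    dplyr::arrange(.data$province)
}

#' Nonholiday-minus-holiday surplus per province
#'
#' Signed per-province difference between the nonholiday and holiday mean
#' daily user counts. Positive surplus marks provinces that gain users when
#' people return to work (net destinations); negative surplus marks net
#' origins.
#'
#' @param daily_holiday,daily_nonholiday Tibbles `province`, `mean_daily`
#'   over the same province set (see [daily_mean_counts()]).
#' @return Tibble `province`, `holiday`, `nonholiday`, `surplus`, sorted by
#'   surplus descending.
#' @export
holiday_surplus <- function(daily_holiday, daily_nonholiday) {
  if (!setequal(daily_holiday$province, daily_nonholiday$province)) {
    stop("province sets differ between the two periods", call. = FALSE)
  }
  dplyr::inner_join(
    dplyr::rename(daily_holiday, holiday = "mean_daily"),
    dplyr::rename(daily_nonholiday, nonholiday = "mean_daily"),
    by = "province"
  ) |>
    dplyr::mutate(surplus = .data$nonholiday - .data$holiday) |>
    dplyr::arrange(dplyr::desc(.data$surplus))
}
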