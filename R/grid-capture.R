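#' Build a regular enumeration grid
#'
#' Lays a square lattice over a bounding box, emulating enumeration of app
#' users from virtual positions placed every `spacing_km` across the study
#' region. Cells are half-open `[x, x + spacing) x [y, y + spacing)`
#' intervals anchored at the box's lower-left corner, so every point inside
#' the box belongs to exactly one cell. The number of cells is
#' `ceiling(width / spacing) * ceiling(height / spacing)`.
#'
#' @param xlim,ylim Numeric length-2 extents (km) of the box to cover.
#' @param spacing_km Positive lattice spacing (km).
#' @return A tibble of class `capture_grid` with columns `cell_id`,
#'   `x_center_km`, `y_center_km`, `inhabited` (`NA` until
#'   [mask_uninhabited()] is applied), and attributes `spacing_km` and
#'   `origin`.
#' @examples
#' build_grid(c(0, 12), c(0, 7), spacing_km = 5)  # 3 x 2 = 6 cells
#' @export
build_grid <- function(xlim, ylim, spacing_km) {
  if (spacing_km <= 0) stop("`spacing_km` must be positive", call. = FALSE)
  if (diff(xlim) <= 0 || diff(ylim) <= 0) {
    stop("bounding box must have positive area", call. = FALSE)
  }
  nx <- ceiling(diff(xlim) / spacing_km)
  ny <- ceiling(diff(ylim) / spacing_km)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  out <- tibble::tibble(
    cell_id = sprintf("g%d_%d", ix, iy),
    x_center_km = xlim[1] + (ix + 0.5) * spacing_km,
    y_center_km = ylim[1] + (iy + 0.5) * spacing_km,
    inhabited = NA
  )
  structure(out, spacing_km = spacing_km, origin = c(xlim[1], ylim[1]),
            class = c("capture_grid", class(out)))
}

# half-open cell index of points within a grid; NA for points outside the box
grid_cell_index <- function(grid, x, y) {
  s <- attr(grid, "spacing_km")
  o <- attr(grid, "origin")
  nx <- max(floor((grid$x_center_km - o[1]) / s)) + 1L
  ny <- max(floor((grid$y_center_km - o[2]) / s)) + 1L
  ix <- floor((x - o[1]) / s)
  iy <- floor((y - o[2]) / s)
  idx <- ix + nx * iy + 1L
  idx[ix < 0 | iy < 0 | ix >= nx | iy >= ny] <- NA_integer_
  idx
}

#' Flag inhabited grid cells
#'
#' Marks as inhabited exactly those cells that contain at least one resident
#' location — the stand-in for masking out unpopulated cells with a
#' population-density layer before querying them.
#'
#' @param grid A `capture_grid`.
#' @param locations Data frame with `x_km`, `y_km` columns (typically agent
#'   positions), or NULL/empty for a fully uninhabited grid.
#' @return The grid with its `inhabited` column filled in.
#' @export
mask_uninhabited <- function(grid, locations = NULL) {
  stopifnot(inherits(grid, "capture_grid"))
  grid$inhabited <- FALSE
  if (!is.null(locations) && nrow(locations) > 0) {
    idx <- grid_cell_index(grid, locations$x_km, locations$y_km)
    grid$inhabited[unique(idx[!is.na(idx)])] <- TRUE
  }
  grid
}

#' Query the users nearest a virtual position
#'
#' Emulates a "nearby users" query from a virtual location: the K online
#' users closest to the query point by planar Euclidean distance, nearest
#' first, ties broken by user id. The result is truncated when more than K
#' users are online — the app only ever shows a bounded list, which is the
#' enumeration protocol's intrinsic undercount mechanism.
#'
#' @param center Numeric length-2 query point (km).
#' @param online_users Data frame with `user_id`, `x_km`, `y_km`; one row
#'   per online user.
#' @param K Positive list-length limit.
#' @return A list with `user_ids` (character, nearest first) and `truncated`
#'   (logical).
#' @export
nearby_query <- function(center, online_users, K = 60) {
  if (is.finite(K) && K < 1) stop("`K` must be at least 1", call. = FALSE)
  if (is.null(online_users) || nrow(online_users) == 0) {
    return(list(user_ids = character(0), truncated = FALSE))
  }
  d <- sqrt((online_users$x_km - center[1])^2 +
            (online_users$y_km - center[2])^2)
  ord <- order(d, online_users$user_id)
  keep <- ord[seq_len(min(K, length(ord)))]
  list(user_ids = online_users$user_id[keep],
       truncated = nrow(online_users) > K)
}

#' Enumerate one day's online users over the grid
#'
#' Runs a nearby-user query from the centre of every inhabited cell and
#' unions the results, deduplicating users seen from several positions —
#' the daily enumeration pass of the protocol. With `K` at least the number
#' of online users every query sees the whole roster, so the union equals
#' the true online set (complete coverage); finite `K` demonstrates
#' truncation undercount.
#'
#' @param grid A masked `capture_grid` (run [mask_uninhabited()] first).
#' @param day_roster Data frame of a single day's online users with
#'   `user_id`, `x_km`, `y_km`. Duplicate user ids collapse to their first
#'   position.
#' @param K List-length limit per query; `Inf` for complete coverage.
#' @return Sorted character vector of captured user ids.
#' @export
enumerate_day <- function(grid, day_roster, K = 60) {
  stopifnot(inherits(grid, "capture_grid"))
  if (anyNA(grid$inhabited)) {
    stop("grid has not been masked; call mask_uninhabited() first",
         call. = FALSE)
  }
  if (is.null(day_roster) || nrow(day_roster) == 0) return(character(0))
  users <- day_roster[!duplicated(day_roster$user_id),
                      c("user_id", "x_km", "y_km")]
  centers <- grid[grid$inhabited, c("x_center_km", "y_center_km")]
  if (nrow(centers) == 0) return(character(0))
  if (K >= nrow(users)) {
    # every query returns the full online list, so the union is the whole set
    return(sort(users$user_id))
  }
  seen <- lapply(seq_len(nrow(centers)), function(i) {
    nearby_query(c(centers$x_center_km[i], centers$y_center_km[i]),
                 users, K)$user_ids
  })
  sort(unique(unlist(seen)))
}
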