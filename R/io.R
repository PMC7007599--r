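#' Read and write package CSV formats
#'
#' Light wrappers over readr fixing the column contracts used throughout:
#' province profiles (`province,adult_men,internet_penetration,
#' msm_prevalence,x_km,y_km`), online rosters (`user_id,date,province,
#' cell_id`, ISO-8601 dates, optional `x_km`/`y_km`), capture samples
#' (`province,m,n,k`) and grids (`cell_id,x_center_km,y_center_km,
#' inhabited`).
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return validated tibbles; writers return `x` invisibly.
#' @name appcrc-io
NULL

#' @rdname appcrc-io
#' @export
read_province_profiles <- function(path) {
  validate_profiles(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname appcrc-io
#' @export
write_province_profiles <- function(x, path) {
  validate_profiles(x)
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname appcrc-io
#' @export
read_roster <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("user_id", "date", "province", "cell_id")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("roster lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$date <- as.Date(out$date)
  out
}

#' @rdname appcrc-io
#' @export
write_roster <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname appcrc-io
#' @export
read_capture_samples <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("province", "m", "n", "k"), names(out))
  if (length(missing)) {
    stop("capture samples lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_crc_sample(out$m, out$n, out$k)
  out
}

#' @rdname appcrc-io
#' @export
write_grid <- function(x, path) {
  stopifnot(inherits(x, "capture_grid"))
  readr::write_csv(as.data.frame(x), path)
  invisible(x)
}

#' Load a pipeline configuration from YAML
#'
#' The file mirrors [sim_config()]'s arguments plus pipeline options:
#' either `profiles` (path to a province CSV, resolved relative to the YAML
#' file) or `n_provinces`/`total_agents` for a synthetic set, and
#' optionally `stages` (subset of capture/estimate/stats/migrate), `K`, and
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return List with `config` (a `sim_config`), `stages`, `K`, `out_dir`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  provinces <- if (!is.null(y$profiles)) {
    p <- y$profiles
    if (!file.exists(p)) p <- file.path(dirname(path), y$profiles)
    read_province_profiles(p)
  } else {
    synthetic_provinces(y$n_provinces %||% 10,
                        y$total_agents %||% 50000, seed = seed)
  }
  args <- y[intersect(names(y),
                      c("n_days_holiday", "n_days_nonholiday",
                        "n_days_recapture", "migrant_fraction",
                        "grid_spacing_km", "p_online", "location_sd_km",
                        "holiday_start", "nonholiday_start",
                        "recapture_start"))]
  if (!is.null(args$p_online)) args$p_online <- unlist(args$p_online)
  config <- do.call(sim_config,
                    c(list(provinces = provinces, seed = seed), args))
  list(config = config,
       stages = unlist(y$stages) %||%
         c("capture", "estimate", "stats", "migrate"),
       K = y$K %||% Inf,
       out_dir = y$out_dir)
}
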