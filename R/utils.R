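#' Round half away from zero
#'
#' Commercial rounding used throughout the package wherever a real-valued
#' estimate is converted to a person count: 0.5 always rounds away from zero,
#' unlike [base::round()]'s banker's rounding. Stated once and reused
#' everywhere so that every table in the package is reproducible to the digit.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length containing whole numbers.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# shared input checks -------------------------------------------------------

check_counts <- function(..., allow_zero = TRUE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v)) ||
        any(v < if (allow_zero) 0 else 1)) {
      stop(sprintf("`%s` must contain non-negative whole numbers", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

check_fraction <- function(x, name, min_open = TRUE, max_closed = TRUE) {
  lo_ok <- if (min_open) all(x > 0) else all(x >= 0)
  hi_ok <- if (max_closed) all(x <= 1) else all(x < 1)
  if (!is.numeric(x) || anyNA(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must lie in %s0, 1%s", name,
                 if (min_open) "(" else "[", if (max_closed) "]" else ")"),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
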