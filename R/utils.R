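#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used for all
#' displayed percentages and the 0-100 display scale. Base `round()` rounds
#' half to even, which disagrees on exact .5 ties.
#'
#' @param x numeric vector (non-negative values are the intended use).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.455, 2)  # 0.46, where round() gives 0.45 or 0.46 by fp luck
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # pre-round at 9 decimals to undo binary representation error (0.455*100
  # is stored as 45.499999...), then apply the half-up rule
  floor(round(x * p, 9) + 0.5) / p
}

#' Format a percentage the way cohort tables print it
#'
#' `100 * k / n`, half-up rounded to two decimals.
#'
#' @param k count in the category.
#' @param n total count.
#' @return numeric percentage with two-decimal half-up rounding.
#' @export
#' @examples
#' percent_of(1135, 1814)  # 62.57
percent_of <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round_half_up(100 * k / n, 2)
}

# shared validators ---------------------------------------------------------

check_unit <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) stop(name, " must lie in [0, 1]", call. = FALSE)
  if (!allow_na && anyNA(x)) stop(name, " must not contain NA", call. = FALSE)
  invisible(x)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  if (is.logical(x) && all(is.na(x)))
    return(as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC"))
  if (is.character(x)) {
    out <- as.POSIXct(x, tz = "UTC", tryFormats = c(
      "%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
    if (anyNA(out) && !anyNA(x)) stop("unparseable timestamp(s): ",
                                      paste(utils::head(x[is.na(out)], 3), collapse = ", "),
                                      call. = FALSE)
    return(out)
  }
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  stop("cannot interpret timestamps of class ", paste(class(x), collapse = "/"), call. = FALSE)
}

format_utc <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

DAY_S <- 86400
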