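## Internal angle helpers.  All user-facing angles are degrees; the canonical
## wrapping interval is [-180, 180) throughout the package.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the canonical interval [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped so that every value lies in `[-180, 180)`.
#' @examples
#' wrap_angle(c(180, -180, 360, 211))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  ((x + 180) %% 360) - 180
}

## cosine/sine in degrees (exact at multiples of 90 via *pi functions)
cosd <- function(x) cospi(x / 180)
sind <- function(x) sinpi(x / 180)

## shared argument check: scalar finite numeric
check_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
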