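#' Round half away from zero upwards
#'
#' Rounds to the nearest integer with ties at .5 going up, the rule used for
#' all integer quantization in the package (range normalization, reported
#' percentages, cohort count allocation).
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, -0.5))
#' @export
round_half_up <- function(x) floor(x + 0.5)

# argument order keeps the attributes (dim) of x
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

pv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pupavision_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)

is_proportion <- function(x) length(x) == 1 && is.numeric(x) &&
  is.finite(x) && x >= 0 && x <= 1

#' Normalize an angle in degrees to (-90, 90]
#' @noRd
norm_angle <- function(a) {
  a <- a %% 180
  if (a > 90) a <- a - 180
  a
}
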