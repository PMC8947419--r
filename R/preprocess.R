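pixels_of <- function(img) {
  if (inherits(img, c("pupa_raw", "pupa_rgb8"))) img$pixels else img
}

validate_raw_pixels <- function(px, in_max) {
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3)
    pv_stop("pv_image_error", "expected a three-channel pixel array")
  mx <- max(px); mn <- min(px)
  if (mn < 0)
    pv_stop("pv_image_error", sprintf("negative pixel value %s", mn))
  if (mx > in_max)
    pv_stop("pv_image_error",
            sprintf("pixel maximum %s exceeds the declared range [0, %s]",
                    mx, in_max))
  invisible(px)
}

#' Normalize the acquisition pixel range to 8 bits
#'
#' Maps the raw range `[0, in_max]` (65520 for the stereomicroscope setup)
#' monotonically onto `[0, out_max]`, rounding half up, so that 0 maps to 0
#' and `in_max` to `out_max` exactly.
#'
#' @param img a `pupa_raw` object or an integer array `c(width, height, 3)`.
#' @param in_max declared maximum of the input range.
#' @param out_max maximum of the output range (255 for 8-bit).
#' @return a `pupa_rgb8` object (when given a `pupa_raw`) or a plain integer
#'   array, with pixels in `[0, out_max]`.
#' @examples
#' normalize_range(array(c(0L, 32760L, 65520L), c(1, 1, 3)))
#' @export
normalize_range <- function(img, in_max = 65520L, out_max = 255L) {
  if (in_max <= 0) pv_stop("pv_image_error", "in_max must be positive")
  px <- pixels_of(img)
  validate_raw_pixels(px, in_max)
  storage.mode(px) <- "integer"
  out <- cpp_normalize_range(px, as.integer(in_max), as.integer(out_max))
  if (inherits(img, "pupa_raw")) {
    structure(list(pixels = out, pupa_id = img$pupa_id,
                   day_index = img$day_index,
                   water_treated_day8 = img$water_treated_day8,
                   truth = img$truth, source = "pupa_raw"),
              class = "pupa_rgb8")
  } else out
}

#' Convert an 8-bit RGB image to HSV channels
#'
#' Standard RGB-to-HSV transform: `S = 255 * (max - min) / max` (0 where
#' `max = 0`) and `V = max`, both on the 0..255 integer scale. Hue is unused
#' downstream; by default it is mapped from 0-360 degrees onto the 0..255
#' byte scale for uniformity, while `hue_scale = "degrees"` returns it
#' unquantized (the representation under which HSV-to-RGB back-conversion
#' reproduces the input within one gray level; byte-quantized hue can cost up
#' to ~3). The saturation channel is what downstream segmentation thresholds.
#'
#' @param img a `pupa_rgb8` object or integer array `c(width, height, 3)`
#'   with values in 0..255.
#' @param hue_scale `"byte"` (0..255 integers) or `"degrees"` (numeric,
#'   0..360).
#' @return `list(h = , s = , v = )` of `width x height` matrices.
#' @export
to_hsv <- function(img, hue_scale = c("byte", "degrees")) {
  hue_scale <- match.arg(hue_scale)
  px <- pixels_of(img)
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3)
    pv_stop("pv_image_error", "expected a three-channel 8-bit image")
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  s <- round_half_up(255 * delta / pmax(mx, 1L))
  s[mx == 0] <- 0
  # hue in degrees, 0 where achromatic
  h <- matrix(0, d[1], d[2])
  nz <- delta > 0
  hr <- nz & mx == r
  h[hr] <- (60 * ((g[hr] - b[hr]) / delta[hr])) %% 360
  hg <- nz & mx == g & mx != r
  h[hg] <- 60 * ((b[hg] - r[hg]) / delta[hg]) + 120
  hb <- nz & mx == b & mx != r & mx != g
  h[hb] <- 60 * ((r[hb] - g[hb]) / delta[hb]) + 240
  if (hue_scale == "byte") h <- round_half_up(h / 360 * 255)
  list(h = h, s = s, v = mx)
}

#' Extract the saturation channel of an 8-bit RGB image
#'
#' Fast path for the segmentation stage; identical to the `s` component of
#' [to_hsv()].
#'
#' @inheritParams to_hsv
#' @return integer `width x height` matrix in 0..255.
#' @export
saturation_channel <- function(img) {
  px <- pixels_of(img)
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3)
    pv_stop("pv_image_error", "expected a three-channel 8-bit image")
  storage.mode(px) <- "integer"
  cpp_saturation(px, d[1], d[2])
}

#' Luminance of an 8-bit RGB image
#'
#' Rec. 601 gray conversion used as the working copy for texture features.
#'
#' @inheritParams to_hsv
#' @return numeric `width x height` matrix on the 0..255 scale.
#' @export
luminance <- function(img) {
  px <- pixels_of(img)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}
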