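#' Boundary pixel centers of a mask
#'
#' Foreground pixels with a 4-neighbour in the background or on the image
#' border, as 0-based `(x, y)` coordinates.
#'
#' @param m logical matrix.
#' @return two-column numeric matrix.
#' @export
boundary_points <- function(m) {
  W <- nrow(m); H <- ncol(m)
  shift <- function(dx, dy) {
    out <- matrix(FALSE, W, H)
    xs <- max(1, 1 + dx):min(W, W + dx)
    ys <- max(1, 1 + dy):min(H, H + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  interior <- shift(1, 0) & shift(-1, 0) & shift(0, 1) & shift(0, -1)
  pts <- which(m & !interior, arr.ind = TRUE)
  cbind(x = pts[, 1] - 1, y = pts[, 2] - 1)
}

new_ellipse <- function(center, semi_major, semi_minor, angle_deg) {
  structure(list(center = unname(center), semi_major = semi_major,
                 semi_minor = semi_minor, angle_deg = angle_deg),
            class = "enclosing_ellipse")
}

#' Minimum enclosing ellipse of a mask
#'
#' Minimum-area ellipse containing all foreground pixel centers, computed on
#' the boundary point set (which contains the convex-hull vertices) with the
#' Titterington algorithm ([cluster::ellipsoidhull()]). The returned ellipse
#' is rescaled so that every boundary point is inside or on it.
#'
#' @param m logical single-component mask.
#' @return an `enclosing_ellipse`: `center` (0-based `(x, y)`), `semi_major`,
#'   `semi_minor` (pixels), `angle_deg` of the major axis vs. the x axis in
#'   (-90, 90].
#' @export
fit_min_ellipse <- function(m) {
  pts <- boundary_points(m)
  if (nrow(pts) < 5)
    pv_stop("pv_degenerate_geometry",
            "too few boundary points to fit an ellipse")
  eh <- tryCatch(cluster::ellipsoidhull(pts, maxit = 5000),
                 error = function(e) NULL)
  if (is.null(eh) || !all(is.finite(eh$cov)) || det(eh$cov) <= 0)
    pv_stop("pv_degenerate_geometry",
            "degenerate point set: no proper enclosing ellipse")
  d2 <- max(eh$d2, max(mahalanobis(pts, eh$loc, eh$cov)))
  ev <- eigen(eh$cov, symmetric = TRUE)
  semi <- sqrt(pmax(ev$values, 0) * d2)
  if (semi[2] <= 0)
    pv_stop("pv_degenerate_geometry", "collinear boundary points")
  vec <- ev$vectors[, 1]
  if (vec[1] < 0) vec <- -vec
  new_ellipse(eh$loc, semi[1], semi[2],
              norm_angle(atan2(vec[2], vec[1]) * 180 / pi))
}

#' Rectangle circumscribing an enclosing ellipse
#'
#' The oriented rectangle sharing the ellipse's center and angle, with
#' `width = 2 * semi_major` and `height = 2 * semi_minor`; it contains the
#' ellipse and drives straightening.
#'
#' @param e an `enclosing_ellipse`.
#' @return an `enclosing_rect`: `center`, `width`, `height`, `angle_deg`.
#' @export
rect_from_ellipse <- function(e) {
  stopifnot(inherits(e, "enclosing_ellipse"))
  structure(list(center = e$center, width = 2 * e$semi_major,
                 height = 2 * e$semi_minor, angle_deg = e$angle_deg),
            class = "enclosing_rect")
}

#' Points on the boundary of an ellipse
#' @param e an `enclosing_ellipse`.
#' @param n number of points.
#' @return two-column matrix of `(x, y)` coordinates.
#' @export
ellipse_boundary <- function(e, n = 360) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- e$angle_deg * pi / 180
  u <- e$semi_major * cos(t); v <- e$semi_minor * sin(t)
  cbind(x = e$center[1] + cos(th) * u - sin(th) * v,
        y = e$center[2] + sin(th) * u + cos(th) * v)
}

# Rotate image content by phi degrees about `center` (0-based pixel coords),
# bilinear interpolation, zero padding, same canvas. EBImage::affine expects a
# forward map on coordinates with pixel centers at (0-based index + 0.5).
rotate_about <- function(img, center, phi_deg) {
  phi <- phi_deg * pi / 180
  caff <- center + 0.5
  cp <- cos(phi); sp <- sin(phi)
  m <- rbind(c(cp, sp),
             c(-sp, cp),
             c(caff[1] - cp * caff[1] + sp * caff[2],
               caff[2] - sp * caff[1] - cp * caff[2]))
  EBImage::imageData(EBImage::affine(EBImage::Image(img, dim = dim(img)),
                                     m, filter = "bilinear", bg.col = 0))
}

#' Straighten an image so an oriented rectangle becomes axis-aligned
#'
#' Rotates the image about the rectangle center by minus the rectangle angle
#' (bilinear interpolation, zero padding, unchanged canvas), so the body's
#' major axis becomes horizontal.
#'
#' @param img numeric matrix (`width x height`) or array
#'   (`width x height x channels`).
#' @param r an `enclosing_rect`.
#' @return `list(image = <rotated>, rect = <axis-aligned rect>)`.
#' @export
straighten <- function(img, r) {
  stopifnot(inherits(r, "enclosing_rect"))
  rot <- rotate_about(img, r$center, -r$angle_deg)
  r2 <- r; r2$angle_deg <- 0
  list(image = rot, rect = r2)
}

#' Crop to an axis-aligned rectangle and resize to the standard frame
#'
#' Crops with half-open integer bounds (floor of the minima, ceiling of the
#' maxima, clamped to the canvas) and resamples to exactly
#' `target_width x target_height` with separable bilinear interpolation. The
#' physical calibration is propagated per axis:
#' `um_per_px_std_x = um_per_px * crop_width / target_width` (same for y), so
#' physical lengths survive the deliberately anisotropic resize.
#'
#' @param img numeric matrix or 3-channel array (already straightened).
#' @param r axis-aligned `enclosing_rect` (angle 0).
#' @param um_per_px calibration of the input image, micrometres per pixel.
#' @param pupa_id,day_index identifiers carried through.
#' @param target_width,target_height output size in pixels.
#' @return a `pupa_std` object: `gray` (`target_width x target_height`
#'   matrix), optional `color` array, `um_per_px_std = c(x, y)`,
#'   `crop_bounds = c(x0, x1, y0, y1)`, identifiers.
#' @export
crop_and_resize <- function(img, r, um_per_px, pupa_id = NULL,
                            day_index = NULL,
                            target_width = 2800L, target_height = 1300L) {
  stopifnot(inherits(r, "enclosing_rect"))
  if (abs(r$angle_deg) > 1e-9)
    pv_stop("pv_geometry_error", "crop_and_resize expects an axis-aligned rect")
  if (r$width <= 0 || r$height <= 0)
    pv_stop("pv_degenerate_geometry", "degenerate rectangle with zero area")
  d <- dim(img)
  W <- d[1]; H <- d[2]
  x0 <- max(0L, as.integer(floor(r$center[1] - r$width / 2)))
  x1 <- min(W, as.integer(ceiling(r$center[1] + r$width / 2)))
  y0 <- max(0L, as.integer(floor(r$center[2] - r$height / 2)))
  y1 <- min(H, as.integer(ceiling(r$center[2] + r$height / 2)))
  if (x1 <= x0 || y1 <= y0)
    pv_stop("pv_degenerate_geometry", "crop rectangle lies outside the canvas")
  resize1 <- function(mat)
    cpp_resize_bilinear(mat[(x0 + 1):x1, (y0 + 1):y1, drop = FALSE],
                        as.integer(target_width), as.integer(target_height))
  if (length(d) == 3) {
    color <- array(0, c(target_width, target_height, d[3]))
    for (k in seq_len(d[3])) color[, , k] <- resize1(img[, , k])
    gray <- 0.299 * color[, , 1] + 0.587 * color[, , 2] + 0.114 * color[, , 3]
  } else {
    color <- NULL
    gray <- resize1(img)
  }
  structure(list(
    gray = gray, color = color,
    um_per_px_std = c(x = um_per_px * (x1 - x0) / target_width,
                      y = um_per_px * (y1 - y0) / target_height),
    crop_bounds = c(x0 = x0, x1 = x1, y0 = y0, y1 = y1),
    pupa_id = pupa_id, day_index = day_index
  ), class = "pupa_std")
}

#' Pose-normalize a segmented pupa image
#'
#' Composition of the geometry chain: fit the minimum enclosing ellipse of
#' the mask, take its circumscribed rectangle, straighten the image, crop and
#' resize to the standard frame.
#'
#' @param img numeric matrix (gray) or 3-channel array at raw scale.
#' @param mask logical body mask from [segment_pupa()].
#' @param um_per_px raw calibration, micrometres per pixel.
#' @inheritParams crop_and_resize
#' @return a `pupa_std` object (see [crop_and_resize()]); the fitted ellipse
#'   is attached as attribute `"ellipse"`.
#' @export
standardize_pupa <- function(img, mask, um_per_px, pupa_id = NULL,
                             day_index = NULL,
                             target_width = 2800L, target_height = 1300L) {
  e <- fit_min_ellipse(mask)
  r <- rect_from_ellipse(e)
  st <- straighten(img, r)
  std <- crop_and_resize(st$image, st$rect, um_per_px, pupa_id, day_index,
                         target_width, target_height)
  attr(std, "ellipse") <- e
  std
}
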