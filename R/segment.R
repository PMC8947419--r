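#' Otsu threshold of an 8-bit single-channel image
#'
#' Returns the threshold `t` in 0..255 maximizing the between-class variance
#' of the 256-bin histogram, with the two classes `{<= t}` and `{> t}`.
#' Ties are broken towards the smallest `t`.
#'
#' @param s integer matrix with values in 0..255 (e.g. a saturation channel).
#' @return integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(s) {
  if (min(s) == max(s))
    pv_stop("pv_degenerate_histogram",
            "Otsu threshold is undefined for a constant image")
  h <- as.numeric(tabulate(as.integer(s) + 1L, 256L))
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                 # mass of class {<= t}
  m0 <- cumsum(h * lev)           # unnormalized first moment of class {<= t}
  mt <- m0[256]
  w1 <- n - w0
  # between-class variance: w0*w1*(mu0-mu1)^2, algebraically reduced
  sb <- (mt * w0 / n - m0)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  as.integer(which.max(sb) - 1L)  # which.max takes the first (smallest) argmax
}

#' Binarize a channel at a threshold
#'
#' Foreground is the bright side: pixels strictly above `t`. For the
#' saturation channel this selects the highly saturated pupal body.
#'
#' @param s integer matrix.
#' @param t threshold gray level.
#' @return logical matrix of the same shape.
#' @export
binarize <- function(s, t) s > t

#' Fill interior holes of a binary mask
#'
#' Background components that do not touch the image border (4-connectivity
#' for the background, the dual of the 8-connected foreground) are turned
#' into foreground.
#'
#' @param m logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(
    EBImage::Image((!m) * 1, dim = dim(m))))
  border <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                             lab[, 1], lab[, ncol(lab)])), 0)
  m | (lab != 0 & !(lab %in% border))
}

#' Euclidean disk structuring element
#'
#' Offsets `(dx, dy)` with `dx^2 + dy^2 <= radius^2`, as a 0/1 matrix of side
#' `2 * radius + 1`.
#'
#' @param radius disk radius in pixels.
#' @return numeric matrix.
#' @export
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  outer(-r:r, -r:r, function(x, y) as.numeric(x^2 + y^2 <= r^2))
}

#' Morphological opening with a Euclidean disk
#'
#' Erosion followed by dilation with the disk of [disk_kernel()], computed
#' exactly via two Euclidean distance transforms: a pixel survives erosion iff
#' its distance to the nearest background pixel (image exterior counts as
#' background) exceeds the radius, and dilation is the dual. Removes
#' protrusions and speckle smaller than the disk.
#'
#' @param m logical matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return logical matrix.
#' @export
open_morphological <- function(m, radius = 5) {
  if (radius < 1) pv_stop("pv_config_error", "opening radius must be >= 1")
  if (!any(m)) return(m)
  W <- nrow(m); H <- ncol(m)
  # restrict to the foreground bounding box plus margin for speed
  rs <- range(which(rowSums(m) > 0)); cs <- range(which(colSums(m) > 0))
  pad <- as.integer(radius) + 1L
  x0 <- max(1L, rs[1] - pad); x1 <- min(W, rs[2] + pad)
  y0 <- max(1L, cs[1] - pad); y1 <- min(H, cs[2] + pad)
  sub <- m[x0:x1, y0:y1, drop = FALSE]
  # pad one background ring so the exterior counts as background for erosion
  mp <- matrix(0, nrow(sub) + 2L, ncol(sub) + 2L)
  mp[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  dist_fg <- EBImage::imageData(EBImage::distmap(EBImage::Image(mp, dim = dim(mp))))
  er <- (dist_fg > radius)[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L), drop = FALSE]
  if (any(er)) {
    dist_bg <- EBImage::imageData(EBImage::distmap(
      EBImage::Image((!er) * 1, dim = dim(er))))
    di <- dist_bg <= radius
  } else {
    di <- er
  }
  out <- matrix(FALSE, W, H)
  out[x0:x1, y0:y1] <- di
  out
}

#' Label 8-connected components of a binary mask
#'
#' EBImage's flood-fill labelling is 4-connected; components that touch only
#' diagonally are merged afterwards through a union-find pass over the label
#' adjacency graph, yielding 8-connectivity.
#'
#' @param m logical matrix.
#' @return integer matrix of labels (0 = background), relabelled 1..k.
#' @export
label_components <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1, dim = dim(m))))
  nlab <- max(lab)
  if (nlab <= 1) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  W <- nrow(lab); H <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-W, -H]), as.vector(lab[-1, -1])),   # (+1, +1)
    cbind(as.vector(lab[-W, -1]), as.vector(lab[-1, -H])))   # (+1, -1)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- matrix(0L, W, H)
  fg <- lab > 0
  out[fg] <- dense[lab[fg]]
  out
}

#' Keep the largest connected foreground component
#'
#' Retains only the largest 8-connected component, the pupal body; smaller
#' specks are discarded. The result carries `attr(, "component_count") = 1`.
#'
#' @param m logical matrix.
#' @param pupa_id,day_index optional identifiers included in error messages.
#' @return logical matrix with exactly one component.
#' @export
extract_pupa_region <- function(m, pupa_id = NULL, day_index = NULL) {
  if (!any(m)) {
    who <- if (!is.null(pupa_id))
      sprintf(" (pupa %s, day %s)", pupa_id, day_index) else ""
    pv_stop("pv_segmentation_failure",
            paste0("no foreground component to extract", who),
            pupa_id = pupa_id, day_index = day_index)
  }
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0])
  out <- lab == which.max(sizes)
  attr(out, "component_count") <- 1L
  out
}

#' Segment the pupal body from a saturation channel
#'
#' The full extraction chain: Otsu threshold, binarize to the bright
#' (saturated) side, fill interior holes, open with a Euclidean disk, keep
#' the largest component.
#'
#' @param s integer saturation matrix (0..255).
#' @param opening_radius disk radius for the opening, raw-image pixels.
#' @param pupa_id,day_index optional identifiers for error reporting.
#' @return logical mask of the pupal body.
#' @export
segment_pupa <- function(s, opening_radius = 5, pupa_id = NULL,
                         day_index = NULL) {
  t <- otsu_threshold(s)
  m <- binarize(s, t)
  m <- fill_holes(m)
  m <- open_morphological(m, opening_radius)
  extract_pupa_region(m, pupa_id, day_index)
}
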