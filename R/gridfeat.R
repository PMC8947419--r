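#' Grid specification for the standard frame
#'
#' The standard 2800 x 1300 image is tiled into `rows x cols` equal cells,
#' numbered row-major, 1-based, from the top-left. With the defaults the tail
#' of the pupa (left end of the straightened body, lower half) falls in cell
#' 17 (row 4, column 2); its mirror under a horizontal flip of the body is
#' cell 19 (row 4, column 4), exposed via [mirror_cell_index()] for the case
#' where head/tail orientation is ambiguous.
#'
#' @param rows,cols grid dimensions.
#' @param tail_cell_index index of the cell expected to carry the
#'   pectinate-setae signal.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(rows = 5L, cols = 5L, tail_cell_index = 17L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  tail_cell_index <- as.integer(tail_cell_index)
  if (rows < 1 || cols < 1)
    pv_stop("pv_config_error", "grid must have at least one row and column")
  if (tail_cell_index < 1 || tail_cell_index > rows * cols)
    pv_stop("pv_config_error", "tail_cell_index outside the grid")
  structure(list(rows = rows, cols = cols,
                 tail_cell_index = tail_cell_index), class = "grid_spec")
}

#' Mirrored cell index under a horizontal body flip
#' @param spec a [grid_spec()].
#' @param cell_index cell to mirror (default the tail cell).
#' @return integer cell index in the same row, mirrored column.
#' @export
mirror_cell_index <- function(spec, cell_index = spec$tail_cell_index) {
  r <- (cell_index - 1L) %/% spec$cols
  c <- (cell_index - 1L) %% spec$cols
  r * spec$cols + (spec$cols - 1L - c) + 1L
}

#' Half-open pixel bounds of a grid cell
#'
#' @param spec a [grid_spec()].
#' @param cell_index 1-based row-major cell index.
#' @param width,height image dimensions (must be divisible by the grid).
#' @return named integer vector `c(x0, x1, y0, y1)`, half-open, 0-based.
#' @export
cell_bounds <- function(spec, cell_index, width = 2800L, height = 1300L) {
  if (width %% spec$cols != 0 || height %% spec$rows != 0)
    pv_stop("pv_config_error",
            "image dimensions are not divisible by the grid")
  cw <- width %/% spec$cols; chh <- height %/% spec$rows
  r <- (cell_index - 1L) %/% spec$cols
  c <- (cell_index - 1L) %% spec$cols
  c(x0 = c * cw, x1 = (c + 1L) * cw, y0 = r * chh, y1 = (r + 1L) * chh)
}

#' Split the standard image into grid cells
#'
#' Returns the `rows x cols` non-overlapping cells that exactly tile the
#' image, in cell-index order.
#'
#' @param std a `pupa_std` object or a numeric `width x height` matrix.
#' @param spec a [grid_spec()].
#' @return list of `list(cell_index, bounds, pixels)`.
#' @export
make_grid <- function(std, spec = grid_spec()) {
  g <- if (inherits(std, "pupa_std")) std$gray else std
  W <- nrow(g); H <- ncol(g)
  lapply(seq_len(spec$rows * spec$cols), function(k) {
    b <- cell_bounds(spec, k, W, H)
    list(cell_index = k, bounds = b,
         pixels = g[(b["x0"] + 1):b["x1"], (b["y0"] + 1):b["y1"], drop = FALSE])
  })
}

#' Gray and texture features of one grid cell
#'
#' Computes the fixed feature set used for temporal screening: mean gray,
#' sample standard deviation, the fraction of pixels strictly below the
#' cell-adaptive dark threshold `max(0, mean - 2 * sd)`, and gray-level
#' co-occurrence contrast at horizontal offset 1 px after quantization of the
#' 8-bit scale to 32 levels (mean squared level difference over all
#' within-cell horizontal pairs).
#'
#' @param cell numeric matrix of gray values (0..255 scale), or an element of
#'   [make_grid()].
#' @return `data.frame(mean_gray, std_gray, dark_fraction, contrast)`.
#' @export
cell_features <- function(cell) {
  px <- if (is.list(cell)) cell$pixels else cell
  if (!length(px)) pv_stop("pv_image_error", "empty cell")
  mg <- mean(px)
  sg <- if (length(px) > 1) sd(px) else 0
  thr <- max(0, mg - 2 * sg)
  q <- clamp(floor(px / 8), 0, 31)
  ctr <- if (nrow(q) > 1) mean((q[-1, , drop = FALSE] -
                                  q[-nrow(q), , drop = FALSE])^2) else 0
  data.frame(mean_gray = mg, std_gray = sg,
             dark_fraction = mean(px < thr), contrast = ctr)
}

#' Per-cell features of a standardized image
#'
#' Computes [cell_features()] for every grid cell in one compiled pass.
#'
#' @param std a `pupa_std` object or numeric matrix.
#' @param spec a [grid_spec()].
#' @param pupa_id,day_index identifiers for the output rows (taken from `std`
#'   when available).
#' @return data frame with columns `pupa_id, day_index, cell_index,
#'   mean_gray, std_gray, dark_fraction, contrast`.
#' @export
grid_features <- function(std, spec = grid_spec(), pupa_id = NULL,
                          day_index = NULL) {
  g <- if (inherits(std, "pupa_std")) std$gray else std
  if (inherits(std, "pupa_std")) {
    pupa_id <- pupa_id %||% std$pupa_id
    day_index <- day_index %||% std$day_index
  }
  if (nrow(g) %% spec$cols != 0 || ncol(g) %% spec$rows != 0)
    pv_stop("pv_config_error",
            "image dimensions are not divisible by the grid")
  stats <- cpp_grid_stats(g, spec$cols, spec$rows, 2.0)
  data.frame(
    pupa_id = pupa_id %||% NA_integer_,
    day_index = day_index %||% NA_integer_,
    cell_index = seq_len(spec$rows * spec$cols),
    mean_gray = stats[, 1], std_gray = stats[, 2],
    dark_fraction = stats[, 3], contrast = stats[, 4]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen grid cells for day-over-day texture change
#'
#' For every feature, computes the cohort mean of the absolute change of each
#' cell between day `d` and day 1, z-scores that change matrix per feature
#' across all cells and days, and scores each cell by the maximum z over days
#' and features. Cells are ranked by descending score, so the cell containing
#' the emerging setae ranks first in a cohort with any males.
#'
#' @param features data frame from [grid_features()] rows covering >= 2 days.
#' @param spec a [grid_spec()].
#' @return data frame `cell_index, score`, ordered by descending score (ties
#'   by cell index); the per-day cohort change matrices are attached as
#'   attribute `"change"`.
#' @export
temporal_screen <- function(features, spec = grid_spec()) {
  days <- sort(unique(features$day_index))
  if (length(days) < 2)
    pv_stop("pv_config_error",
            "temporal screening needs features from at least two days")
  feat_names <- c("mean_gray", "std_gray", "dark_fraction", "contrast")
  base <- features[features$day_index == days[1], ]
  n_cells <- spec$rows * spec$cols
  later <- setdiff(days, days[1])
  change <- lapply(feat_names, function(fn) {
    m <- matrix(0, n_cells, length(later),
                dimnames = list(NULL, paste0("day", later)))
    for (j in seq_along(later)) {
      cur <- features[features$day_index == later[j], ]
      key <- paste(cur$pupa_id, cur$cell_index)
      bkey <- paste(base$pupa_id, base$cell_index)
      delta <- abs(cur[[fn]] - base[[fn]][match(key, bkey)])
      m[, j] <- vapply(seq_len(n_cells), function(k)
        mean(delta[cur$cell_index == k], na.rm = TRUE), numeric(1))
    }
    m
  })
  names(change) <- feat_names
  zmax <- matrix(-Inf, n_cells, length(later))
  for (fn in feat_names) {
    m <- change[[fn]]
    mu <- mean(m); s <- sd(as.vector(m))
    z <- if (is.na(s) || s == 0) m * 0 else (m - mu) / s
    zmax <- pmax(zmax, z)
  }
  score <- apply(zmax, 1, max)
  out <- data.frame(cell_index = seq_len(n_cells), score = score)
  out <- out[order(-out$score, out$cell_index), ]
  rownames(out) <- NULL
  attr(out, "change") <- change
  out
}
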