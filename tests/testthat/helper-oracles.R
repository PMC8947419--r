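# Independent brute-force oracles used across the test files. These
# deliberately avoid the implementation's code paths: direct definitional
# computations, exhaustive scans, and breadth-first search.

# Exhaustive Otsu: evaluate the between-class variance of every threshold
# directly from per-class weights and means.
oracle_otsu <- function(s) {
  v <- as.vector(s)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var + 1e-12) {
      best_var <- bc
      best_t <- t
    }
  }
  best_t
}

# Hole filling by breadth-first flood fill of the background from the border
# (4-connectivity): anything not reached is a hole.
oracle_fill_holes <- function(m) {
  W <- nrow(m); H <- ncol(m)
  reached <- matrix(FALSE, W, H)
  queue <- which(!m & (row(m) %in% c(1, W) | col(m) %in% c(1, H)))
  reached[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    x <- (i - 1) %% W + 1; y <- (i - 1) %/% W + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nx <- x + d[1]; ny <- y + d[2]
      if (nx >= 1 && nx <= W && ny >= 1 && ny <= H) {
        j <- nx + (ny - 1) * W
        if (!m[j] && !reached[j]) {
          reached[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  m | !reached
}

# Sliding-window min/max morphology with an explicit Euclidean disk.
oracle_open <- function(m, r) {
  offs <- which(outer(-r:r, -r:r, function(x, y) x^2 + y^2 <= r^2),
                arr.ind = TRUE) - (r + 1)
  W <- nrow(m); H <- ncol(m)
  apply_se <- function(img, combine, outside) {
    out <- matrix(outside, W, H)
    out[] <- if (identical(combine, `&`)) TRUE else FALSE
    for (i in seq_len(nrow(offs))) {
      sh <- matrix(outside, W, H)
      xs <- max(1, 1 - offs[i, 1]):min(W, W - offs[i, 1])
      ys <- max(1, 1 - offs[i, 2]):min(H, H - offs[i, 2])
      sh[xs, ys] <- img[xs + offs[i, 1], ys + offs[i, 2]]
      out <- combine(out, sh)
    }
    out
  }
  er <- apply_se(m, `&`, FALSE)
  apply_se(er, `|`, FALSE)
}

# Gray-level co-occurrence contrast by explicit pair counting.
oracle_contrast <- function(px) {
  q <- pmin(floor(px / 8), 31)
  n <- 0; acc <- 0
  for (y in seq_len(ncol(q))) {
    for (x in seq_len(nrow(q) - 1)) {
      acc <- acc + (q[x + 1, y] - q[x, y])^2
      n <- n + 1
    }
  }
  acc / n
}

# Reduced-size generator configuration used by most tests; the default-scale
# configuration (the study conditions) is reserved for the acceptance suite.
small_gen_cfg <- function(n_pupae = 2, seed = 11, ...) {
  generator_config(
    n_pupae = n_pupae, seed = seed,
    image_width_px = 560L, image_height_px = 360L,
    body_semi_major_px = 200, body_semi_minor_px = 80,
    um_per_px = 12, ...
  )
}

# Render one standardized-frame cell (gray matrix) containing vertical dark
# capsules of known physical length, working in physical micrometre
# coordinates so the anisotropic calibration is honored exactly.
# stripes: data.frame(x0_px, y0_px, len_mm, w_mm, gray).
render_test_cell <- function(width = 560, height = 260, bg = 130,
                             stripes = NULL, noise_sd = 0, seed = 1,
                             um = c(x = 2, y = 1.5)) {
  set.seed(seed)
  px <- matrix(bg, width, height)
  if (!is.null(stripes)) {
    PX <- matrix(0:(width - 1), width, height) * um[["x"]]
    PY <- matrix(0:(height - 1), width, height, byrow = TRUE) * um[["y"]]
    aa <- um[["y"]]  # ~1 px of anti-aliasing, in micrometres
    for (i in seq_len(nrow(stripes))) {
      s <- stripes[i, ]
      Lum <- s$len_mm * 1000
      Wum <- s$w_mm * 1000
      half <- max(0, (Lum - Wum) / 2)
      dx <- PX - s$x0_px * um[["x"]]
      dy <- PY - s$y0_px * um[["y"]]
      tc <- pmin(half, pmax(-half, dy))
      d <- sqrt(dx^2 + (dy - tc)^2)
      covs <- pmin(1, pmax(0, (Wum / 2 + aa - d) / aa))
      px <- px + (s$gray - px) * covs
    }
  }
  if (noise_sd > 0) px <- px + rnorm(length(px), 0, noise_sd)
  px
}
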