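# Rasterize a solid ellipse mask (pixel centers inside).
raster_ellipse <- function(W, H, cx, cy, a, b, angle_deg = 0) {
  th <- angle_deg * pi / 180
  dx <- matrix(0:(W - 1), W, H) - cx
  dy <- matrix(0:(H - 1), W, H, byrow = TRUE) - cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

test_that("minimum enclosing ellipse recovers rendered ellipse parameters", {
  m <- raster_ellipse(450, 220, 224.5, 109.5, 200, 80)
  e <- fit_min_ellipse(m)
  expect_lt(abs(e$semi_major - 200), 2)
  expect_lt(abs(e$semi_minor - 80), 2)
  expect_lt(abs(e$angle_deg), 2)
  expect_lt(max(abs(e$center - c(224.5, 109.5))), 2)

  rot <- raster_ellipse(450, 300, 224.5, 149.5, 150, 60, angle_deg = 25)
  e2 <- fit_min_ellipse(rot)
  expect_lt(abs(e2$angle_deg - 25), 2)

  # containment: every foreground pixel center inside within 0.5 px
  pts <- which(m, arr.ind = TRUE) - 1
  th <- e$angle_deg * pi / 180
  du <- cos(th) * (pts[, 1] - e$center[1]) + sin(th) * (pts[, 2] - e$center[2])
  dv <- -sin(th) * (pts[, 1] - e$center[1]) + cos(th) * (pts[, 2] - e$center[2])
  expect_true(all((du / (e$semi_major + 0.5))^2 +
                    (dv / (e$semi_minor + 0.5))^2 <= 1 + 1e-9))
})

test_that("circle fits give equal semi-axes and degenerate input errors", {
  m <- raster_ellipse(120, 120, 59.5, 59.5, 40, 40)
  e <- fit_min_ellipse(m)
  expect_lt(abs(e$semi_major - e$semi_minor), 1)
  collinear <- matrix(FALSE, 20, 20)
  collinear[5:8, 10] <- TRUE
  expect_error(fit_min_ellipse(collinear), class = "pv_degenerate_geometry")
  expect_error(fit_min_ellipse(matrix(FALSE, 10, 10)),
               class = "pv_degenerate_geometry")
})

test_that("rectangle from ellipse has forced dimensions and contains it", {
  e <- structure(list(center = c(100, 50), semi_major = 200, semi_minor = 80,
                      angle_deg = 30), class = "enclosing_ellipse")
  r <- rect_from_ellipse(e)
  expect_equal(r$width, 400)
  expect_equal(r$height, 160)
  expect_equal(r$angle_deg, 30)
  circ <- rect_from_ellipse(structure(
    list(center = c(0, 0), semi_major = 50, semi_minor = 50, angle_deg = 0),
    class = "enclosing_ellipse"))
  expect_equal(circ$width, circ$height)

  set.seed(5)
  for (i in 1:10) {
    e2 <- structure(list(center = runif(2, 50, 150),
                         semi_major = runif(1, 50, 100),
                         semi_minor = runif(1, 10, 50),
                         angle_deg = runif(1, -89, 90)),
                    class = "enclosing_ellipse")
    r2 <- rect_from_ellipse(e2)
    pts <- ellipse_boundary(e2, 360)
    th <- r2$angle_deg * pi / 180
    du <- cos(th) * (pts[, 1] - r2$center[1]) +
      sin(th) * (pts[, 2] - r2$center[2])
    dv <- -sin(th) * (pts[, 1] - r2$center[1]) +
      cos(th) * (pts[, 2] - r2$center[2])
    expect_true(all(abs(du) <= r2$width / 2 + 1e-6))
    expect_true(all(abs(dv) <= r2$height / 2 + 1e-6))
  }
})

test_that("straightening brings the major axis horizontal within 1 degree", {
  for (ang in c(-40, -15, 10, 30, 44)) {
    m <- raster_ellipse(560, 360, 279.5, 179.5, 200, 80, angle_deg = ang)
    e <- fit_min_ellipse(m)
    r <- rect_from_ellipse(e)
    st <- straighten(m * 1, r)
    e2 <- fit_min_ellipse(st$image > 0.5)
    expect_lt(abs(e2$angle_deg), 1)
  }
})

test_that("straightening at angle zero is the identity and rotation round-trips", {
  set.seed(6)
  img <- matrix(runif(80 * 60, 0, 255), 80, 60)
  r0 <- structure(list(center = c(39.5, 29.5), width = 60, height = 40,
                       angle_deg = 0), class = "enclosing_rect")
  st <- straighten(img, r0)
  expect_equal(st$image, img, tolerance = 1e-6, ignore_attr = TRUE)

  smooth <- outer(seq(0, 255, length.out = 120),
                  seq(0, 255, length.out = 100), function(a, b) (a + b) / 2)
  rA <- structure(list(center = c(59.5, 49.5), width = 10, height = 10,
                       angle_deg = -30), class = "enclosing_rect")
  rot1 <- straighten(smooth, rA)$image          # rotate by +30
  rB <- structure(list(center = c(59.5, 49.5), width = 10, height = 10,
                       angle_deg = 30), class = "enclosing_rect")
  back <- straighten(rot1, rB)$image            # rotate by -30
  interior <- cbind(rep(30:90, each = 41), rep(30:70, times = 61))
  expect_lt(max(abs(back[interior] - smooth[interior])), 2)
})

test_that("crop and resize yields exact dimensions and propagated calibration", {
  set.seed(9)
  img <- matrix(runif(300 * 200, 0, 255), 300, 200)
  # crop exactly matching the target: resize is the identity
  r <- structure(list(center = c(140, 80), width = 280, height = 130,
                      angle_deg = 0), class = "enclosing_rect")
  std <- crop_and_resize(img, r, um_per_px = 10,
                         target_width = 280L, target_height = 130L)
  expect_identical(dim(std$gray), c(280L, 130L))
  expect_equal(std$gray, img[1:280, 16:145],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(std$um_per_px_std), c(10, 10))

  # 2x upscale halves the per-pixel calibration on both axes
  r2 <- structure(list(center = c(140, 79.5), width = 140, height = 65,
                       angle_deg = 0), class = "enclosing_rect")
  std2 <- crop_and_resize(img, r2, um_per_px = 10,
                          target_width = 280L, target_height = 130L)
  expect_identical(dim(std2$gray), c(280L, 130L))
  expect_equal(unname(std2$um_per_px_std), c(5, 5))

  expect_error(crop_and_resize(img, structure(
    list(center = c(10, 10), width = 0, height = 0, angle_deg = 0),
    class = "enclosing_rect"), 10), class = "pv_degenerate_geometry")
})

test_that("the full pose chain standardizes synthetic images exactly", {
  cfg <- small_gen_cfg(seed = 13)
  truth <- cohort_truth(cfg)
  series <- generate_pupa_series(cfg, truth[1, ])
  for (raw in series[c(2, 7, 11)]) {
    rgb8 <- normalize_range(raw)
    mask <- segment_pupa(saturation_channel(rgb8), 5)
    std <- standardize_pupa(luminance(rgb8), mask, cfg$um_per_px)
    expect_identical(dim(std$gray), c(2800L, 1300L))
    ell <- attr(std, "ellipse")
    # the fitted rotation matches the generator's rotation
    expect_lt(abs(ell$angle_deg - raw$truth$angle_deg), 1)
  }
})
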