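#' Configuration for the synthetic pupal-image generator
#'
#' Defines the acquisition conditions emulated by the generator: a cohort of
#' single-pupa day series (one three-channel 16-bit-range image per day for
#' `n_days` days), with ground-truth sex and eclosion outcome per pupa.
#' Male pupae develop long dark pectinate setae on the tail backplane on the
#' last `setae_onset_days_before_eclosion` days before eclosion; short, lighter
#' setae appear on both sexes on those days. Pupae that never emerge
#' ("unfledged") die early and never develop setae.
#'
#' @param n_pupae number of pupae in the cohort.
#' @param male_fraction proportion of males; the male count is
#'   `round_half_up(n_pupae * male_fraction)`.
#' @param unfledged_fraction proportion of pupae that never emerge, allocated
#'   by the same rounding rule, independently of sex.
#' @param n_days days of imaging (day 1 .. n_days).
#' @param eclosion_day day of adult emergence for pupae that emerge; imaging
#'   stops the day before.
#' @param setae_onset_days_before_eclosion setae become visible this many days
#'   before eclosion.
#' @param long_setae_length_range_mm physical length range (mm) of the long,
#'   male-only pectinate setae.
#' @param short_setae_length_range_mm length range (mm) of the short, lighter
#'   setae carried by both sexes.
#' @param setae_count_range integer range of long setae per male tail.
#' @param short_setae_count_range integer range of short setae per pupa.
#' @param long_setae_width_mm,short_setae_width_mm rendered stripe widths (mm).
#' @param um_per_px physical calibration of the raw images, micrometres per
#'   pixel (isotropic at acquisition).
#' @param image_width_px,image_height_px raw canvas size in pixels.
#' @param body_semi_major_px,body_semi_minor_px nominal body ellipse semi-axes
#'   in raw pixels; each pupa jitters both by up to `body_jitter` relative.
#' @param body_jitter relative per-pupa jitter of the body semi-axes.
#' @param noise_sd additive Gaussian read noise, in units of the raw
#'   16-bit-range gray scale (0..65520).
#' @param rotation_range_deg interval from which each day's body rotation is
#'   drawn, degrees. Must stay inside (-90, 90) so that pose normalization is
#'   unambiguous (see the package vignette).
#' @param water_treated_day8 metadata flag carried on day-8+ images, marking
#'   the physical water-immersion treatment; it does not alter rendering.
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration, so identical configurations give bit-identical cohorts.
#' @return an object of class `generator_config`.
#' @seealso [generate_cohort()], [generate_pupa_series()]
#' @export
generator_config <- function(n_pupae = 500L,
                             male_fraction = 0.5,
                             unfledged_fraction = 0.096,
                             n_days = 11L,
                             eclosion_day = 12L,
                             setae_onset_days_before_eclosion = 2L,
                             long_setae_length_range_mm = c(0.05, 0.18),
                             short_setae_length_range_mm = c(0.02, 0.05),
                             setae_count_range = c(16L, 20L),
                             short_setae_count_range = c(6L, 12L),
                             long_setae_width_mm = 0.02,
                             short_setae_width_mm = 0.03,
                             um_per_px = 8,
                             image_width_px = 900L,
                             image_height_px = 560L,
                             body_semi_major_px = 320,
                             body_semi_minor_px = 125,
                             body_jitter = 0.05,
                             noise_sd = 800,
                             rotation_range_deg = c(-45, 45),
                             water_treated_day8 = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_pupae = as.integer(n_pupae), male_fraction = male_fraction,
    unfledged_fraction = unfledged_fraction, n_days = as.integer(n_days),
    eclosion_day = as.integer(eclosion_day),
    setae_onset_days_before_eclosion = as.integer(setae_onset_days_before_eclosion),
    long_setae_length_range_mm = long_setae_length_range_mm,
    short_setae_length_range_mm = short_setae_length_range_mm,
    setae_count_range = as.integer(setae_count_range),
    short_setae_count_range = as.integer(short_setae_count_range),
    long_setae_width_mm = long_setae_width_mm,
    short_setae_width_mm = short_setae_width_mm,
    um_per_px = um_per_px,
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    body_semi_major_px = body_semi_major_px,
    body_semi_minor_px = body_semi_minor_px,
    body_jitter = body_jitter, noise_sd = noise_sd,
    rotation_range_deg = rotation_range_deg,
    water_treated_day8 = isTRUE(water_treated_day8),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (!is_count(cfg$n_pupae))
    pv_stop("pv_config_error", "n_pupae must be a non-negative integer")
  if (!is_proportion(cfg$male_fraction))
    pv_stop("pv_config_error", "male_fraction must be in [0, 1]")
  if (!is_proportion(cfg$unfledged_fraction))
    pv_stop("pv_config_error", "unfledged_fraction must be in [0, 1]")
  if (!is_count(cfg$n_days) || cfg$n_days < 1)
    pv_stop("pv_config_error", "n_days must be a positive integer")
  for (nm in c("long_setae_length_range_mm", "short_setae_length_range_mm",
               "rotation_range_deg")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || !is.numeric(r) || r[1] > r[2])
      pv_stop("pv_config_error", sprintf("%s must be an interval c(lo, hi)", nm))
  }
  if (any(cfg$long_setae_length_range_mm <= 0) ||
      any(cfg$short_setae_length_range_mm <= 0))
    pv_stop("pv_config_error", "setae length ranges must be positive")
  if (cfg$rotation_range_deg[1] <= -90 || cfg$rotation_range_deg[2] >= 90)
    pv_stop("pv_config_error",
            "rotation_range_deg must lie strictly inside (-90, 90)")
  if (cfg$um_per_px <= 0)
    pv_stop("pv_config_error", "um_per_px must be positive")
  if (cfg$eclosion_day <= cfg$n_days)
    pv_stop("pv_config_error", "eclosion_day must come after the imaged days")
  invisible(cfg)
}

# Seed for the (pupa, day) render stream; day 0 is the per-pupa trait stream.
# Kept below 2^31 and collision-free for pupa ids < 10^4 and days < 100.
series_seed <- function(seed, pupa, day) {
  (abs(seed) %% 2000L) * 1000000L + (pupa %% 10000L) * 100L + day
}

#' Ground-truth manifest for a synthetic cohort
#'
#' Allocates sex and eclosion outcome across the cohort deterministically from
#' the configuration seed. Counts use round-half-up on the configured
#' fractions; unfledged status is assigned independently of sex. Males that
#' emerge carry setae on the last `setae_onset_days_before_eclosion` days
#' before `eclosion_day` that fall within the imaged days; unfledged pupae die
#' early and never develop setae.
#'
#' @param cfg a [generator_config()].
#' @return a data frame with one row per pupa: `pupa_id`, `true_sex`
#'   (`"male"`/`"female"`), `outcome` (`"male"`/`"female"`/`"unfledged"`),
#'   `eclosion_day` (NA for unfledged), `um_per_px`, and a list column
#'   `setae_visible_days`.
#' @export
cohort_truth <- function(cfg) {
  validate_generator_config(cfg)
  n <- cfg$n_pupae
  if (n == 0L) {
    return(data.frame(pupa_id = integer(), true_sex = character(),
                      outcome = character(), eclosion_day = integer(),
                      um_per_px = numeric()))
  }
  n_male <- as.integer(round_half_up(n * cfg$male_fraction))
  n_unf <- as.integer(round_half_up(n * cfg$unfledged_fraction))
  set.seed(series_seed(cfg$seed, 0L, 0L))
  males <- sample.int(n, n_male)
  unfledged <- sample.int(n, n_unf)
  sex <- rep("female", n)
  sex[males] <- "male"
  outcome <- sex
  outcome[unfledged] <- "unfledged"
  onset <- cfg$eclosion_day - cfg$setae_onset_days_before_eclosion
  vis_days <- lapply(seq_len(n), function(i) {
    if (outcome[i] == "unfledged") integer() else
      intersect(onset:(cfg$eclosion_day - 1L), seq_len(cfg$n_days))
  })
  out <- data.frame(
    pupa_id = seq_len(n),
    true_sex = sex,
    outcome = outcome,
    eclosion_day = ifelse(outcome == "unfledged", NA_integer_,
                          cfg$eclosion_day),
    um_per_px = cfg$um_per_px,
    stringsAsFactors = FALSE
  )
  out$setae_visible_days <- vis_days
  out
}

check_record <- function(cfg, record) {
  need <- c("pupa_id", "true_sex", "outcome")
  if (!all(need %in% names(record)))
    pv_stop("pv_record_error", "record must carry pupa_id, true_sex, outcome")
  if (!record$true_sex %in% c("male", "female"))
    pv_stop("pv_record_error", "true_sex must be 'male' or 'female'")
  if (!record$outcome %in% c("male", "female", "unfledged"))
    pv_stop("pv_record_error", "outcome must be male, female or unfledged")
  if (record$outcome == "unfledged") {
    if (!is.null(record$eclosion_day) && !is.na(record$eclosion_day))
      pv_stop("pv_record_error", "unfledged records must not carry an eclosion_day")
  } else if (record$outcome != record$true_sex) {
    pv_stop("pv_record_error", "outcome of an emerged pupa must equal true_sex")
  }
  invisible(record)
}

# Per-pupa stable traits: body axes, setae geometry (drawn once; the same comb
# is rendered on every visible day).
pupa_traits <- function(cfg, pupa_id, sex) {
  set.seed(series_seed(cfg$seed, pupa_id, 0L))
  a <- cfg$body_semi_major_px * (1 + runif(1, -cfg$body_jitter, cfg$body_jitter))
  b <- cfg$body_semi_minor_px * (1 + runif(1, -cfg$body_jitter, cfg$body_jitter))
  tilt <- runif(1, -20, 20)  # common comb tilt from perpendicular, degrees
  stripes <- NULL
  if (sex == "male") {
    n_long <- sample(seq(cfg$setae_count_range[1], cfg$setae_count_range[2]), 1)
    u0 <- seq(-0.55, -0.25, length.out = n_long) +
      runif(n_long, -0.004, 0.004)
    stripes <- data.frame(
      u0 = u0, v0 = 0.45,
      len_mm = runif(n_long, cfg$long_setae_length_range_mm[1],
                     cfg$long_setae_length_range_mm[2]),
      w_mm = cfg$long_setae_width_mm,
      phi_deg = tilt + runif(n_long, -3, 3),
      r = 45, g = 28, b = 18, kind = "long"
    )
  }
  n_short <- sample(seq(cfg$short_setae_count_range[1],
                        cfg$short_setae_count_range[2]), 1)
  short <- data.frame(
    u0 = seq(-0.55, -0.25, length.out = n_short) + runif(n_short, -0.006, 0.006),
    v0 = 0.28,
    len_mm = runif(n_short, cfg$short_setae_length_range_mm[1],
                   cfg$short_setae_length_range_mm[2]),
    w_mm = cfg$short_setae_width_mm,
    phi_deg = tilt + runif(n_short, -3, 3),
    r = 140, g = 105, b = 75, kind = "short"
  )
  stripes <- rbind(stripes, short)
  list(a = a, b = b, stripes = stripes)
}

# Render anti-aliased stripe capsules into the scene, restricted to their
# bounding windows. Stripe length is the tip-to-tip extent (caps included).
render_stripes <- function(scene, stripes, cx, cy, a, b, theta, um_per_px) {
  W <- dim(scene)[1]; H <- dim(scene)[2]
  ct <- cos(theta); st <- sin(theta)
  for (i in seq_len(nrow(stripes))) {
    s <- stripes[i, ]
    Lpx <- s$len_mm * 1000 / um_per_px
    Wpx <- s$w_mm * 1000 / um_per_px
    half <- max(0, (Lpx - Wpx) / 2)  # segment half-length; caps add Wpx/2
    phi <- s$phi_deg * pi / 180
    dirc <- c(sin(phi), cos(phi))    # unit vector, near-perpendicular to body
    c_can <- c(s$u0 * a, s$v0 * b)
    ends <- rbind(c_can + dirc * half, c_can - dirc * half)
    pex <- cx + ct * ends[, 1] - st * ends[, 2]
    pey <- cy + st * ends[, 1] + ct * ends[, 2]
    pad <- Wpx / 2 + 2
    xs <- max(0, floor(min(pex) - pad)):min(W - 1, ceiling(max(pex) + pad))
    ys <- max(0, floor(min(pey) - pad)):min(H - 1, ceiling(max(pey) + pad))
    if (!length(xs) || !length(ys)) next
    ix <- xs + 1L; iy <- ys + 1L
    dx <- outer(xs, rep(1, length(ys))) - cx
    dy <- outer(rep(1, length(xs)), ys) - cy
    du <- (ct * dx + st * dy) - c_can[1]
    dv <- (-st * dx + ct * dy) - c_can[2]
    tproj <- clamp(du * dirc[1] + dv * dirc[2], -half, half)
    dseg <- sqrt((du - tproj * dirc[1])^2 + (dv - tproj * dirc[2])^2)
    covs <- clamp(Wpx / 2 + 0.5 - dseg, 0, 1)
    col <- c(s$r, s$g, s$b)
    for (k in 1:3)
      scene[ix, iy, k] <- scene[ix, iy, k] + (col[k] - scene[ix, iy, k]) * covs
  }
  scene
}

#' Generate the day series of raw images for one pupa
#'
#' Renders `cfg$n_days` three-channel 16-bit-range images of a single pupa: a
#' bright, saturated ellipse at a fresh random rotation each day on a
#' low-saturation background, with additive Gaussian noise. On the record's
#' `setae_visible_days`, the tail region (left end of the body in canonical
#' pose) carries the pupa's pectinate-setae comb: long dark stripes for males,
#' plus short light stripes for either sex.
#'
#' @param cfg a [generator_config()].
#' @param record one row of [cohort_truth()] (or an equivalent list).
#' @return a list of `pupa_raw` objects (one per day), each with the integer
#'   pixel array (`c(width, height, 3)`, range 0..65520), identifiers, the
#'   `water_treated_day8` flag, and a `truth` list holding the rendered body
#'   ellipse, stripe table and calibration for oracle-based testing.
#' @export
generate_pupa_series <- function(cfg, record) {
  validate_generator_config(cfg)
  check_record(cfg, record)
  pid <- as.integer(record$pupa_id)
  traits <- pupa_traits(cfg, pid, record$true_sex)
  vis <- record$setae_visible_days
  if (is.list(vis)) vis <- vis[[1]]
  W <- cfg$image_width_px; H <- cfg$image_height_px
  cx0 <- (W - 1) / 2; cy0 <- (H - 1) / 2
  lapply(seq_len(cfg$n_days), function(day) {
    set.seed(series_seed(cfg$seed, pid, day))
    angle <- runif(1, cfg$rotation_range_deg[1], cfg$rotation_range_deg[2])
    theta <- angle * pi / 180
    scene <- cpp_render_body(W, H, cx0, cy0, traits$a, traits$b, theta,
                             c(190, 120, 45), c(120, 118, 116), 1.5)
    stripes_today <- if (day %in% vis) traits$stripes else
      traits$stripes[0, , drop = FALSE]
    if (nrow(stripes_today))
      scene <- render_stripes(scene, stripes_today, cx0, cy0,
                              traits$a, traits$b, theta, cfg$um_per_px)
    px <- cpp_finalize_raw(scene, 65520 / 255, cfg$noise_sd, 65520L)
    structure(list(
      pixels = px,
      pupa_id = pid,
      day_index = day,
      water_treated_day8 = cfg$water_treated_day8 && day >= 8L,
      truth = list(center = c(cx0, cy0), semi_major = traits$a,
                   semi_minor = traits$b, angle_deg = angle,
                   stripes = stripes_today, um_per_px = cfg$um_per_px,
                   true_sex = record$true_sex, outcome = record$outcome)
    ), class = "pupa_raw")
  })
}

#' Rasterize the ground-truth body ellipse of a generated image
#'
#' Used as an oracle in segmentation tests: the exact set of pixel centers
#' inside the rendered body ellipse.
#'
#' @param raw a `pupa_raw` produced by [generate_pupa_series()].
#' @return a logical `width x height` matrix.
#' @export
truth_body_mask <- function(raw) {
  tr <- raw$truth
  if (is.null(tr)) pv_stop("pv_record_error", "image carries no ground truth")
  W <- dim(raw$pixels)[1]; H <- dim(raw$pixels)[2]
  theta <- tr$angle_deg * pi / 180
  dx <- matrix(0:(W - 1), W, H) - tr$center[1]
  dy <- matrix(0:(H - 1), W, H, byrow = TRUE) - tr$center[2]
  ua <- cos(theta) * dx + sin(theta) * dy
  vb <- -sin(theta) * dx + cos(theta) * dy
  (ua / tr$semi_major)^2 + (vb / tr$semi_minor)^2 <= 1
}

#' Generate a full synthetic cohort in memory
#'
#' Materializes every day series plus the ground-truth manifest. Intended for
#' small cohorts (tests, examples); for large cohorts prefer streaming one
#' pupa at a time via [cohort_truth()] + [generate_pupa_series()], or
#' [write_cohort()] to put the cohort on disk.
#'
#' @param cfg a [generator_config()].
#' @return `list(series = <list of day-series lists>, manifest = <data frame>)`.
#' @export
generate_cohort <- function(cfg) {
  truth <- cohort_truth(cfg)
  series <- lapply(seq_len(nrow(truth)), function(i)
    generate_pupa_series(cfg, truth[i, ]))
  list(series = series, manifest = truth)
}

#' Write a synthetic cohort to disk
#'
#' Writes each image as a 3-channel 16-bit TIFF named
#' `<pupa_id>_day<d>.tif` and the manifest as `manifest.csv` with columns
#' `pupa_id,true_sex,outcome,eclosion_day,um_per_px`.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory, created if missing.
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cfg, dir) {
  truth <- cohort_truth(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(truth))) {
    series <- generate_pupa_series(cfg, truth[i, ])
    for (raw in series) {
      path <- file.path(dir, sprintf("%d_day%d.tif", raw$pupa_id,
                                     raw$day_index))
      write_pupa_tiff(raw, path)
    }
  }
  man <- truth[, c("pupa_id", "true_sex", "outcome", "eclosion_day",
                   "um_per_px")]
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(truth)
}
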