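#' Parameters of the pectinate-setae classifier
#'
#' The sex call rests on the long pectinate setae, which occur in males only:
#' a stripe counts as "long" when its calibrated length strictly exceeds
#' `long_threshold_mm` (the 0.05 mm boundary value, shared by the longest
#' short setae, is deliberately assigned to "short"). A pupa-day is called
#' male when at least `min_long_count` long stripes are present; presence,
#' not the anatomical comb count, carries the signal, so the default is 1.
#'
#' @param long_threshold_mm strict lower bound (mm) for a long seta.
#' @param min_long_count long stripes required for a male call.
#' @param elongation_min minimum major/minor extent ratio of a dark component
#'   to count as a stripe (rejects round blobs).
#' @param orientation_band_deg allowed deviation of the stripe axis from
#'   vertical in the standardized cell (setae grow roughly perpendicular to
#'   the body axis).
#' @param dark_k multiplier of the cell-adaptive dark threshold
#'   `mean - dark_k * sd`.
#' @param min_area_px minimum component area in standardized pixels; rejects
#'   isolated noise specks.
#' @param min_darkness minimum mean darkness (cell mean gray minus component
#'   mean gray) of a stripe. Pectinate setae are strongly pigmented -- on the
#'   order of a hundred gray levels darker than the surrounding cuticle --
#'   whereas chance dips of correlated sensor noise sit only a few gray
#'   levels below the dark threshold, so this separates the two by an order
#'   of magnitude.
#' @return a `classifier_params` object.
#' @export
classifier_params <- function(long_threshold_mm = 0.05,
                              min_long_count = 1L,
                              elongation_min = 3,
                              orientation_band_deg = 30,
                              dark_k = 2,
                              min_area_px = 10L,
                              min_darkness = 25) {
  if (long_threshold_mm <= 0 || long_threshold_mm > 0.18)
    pv_stop("pv_config_error", "long_threshold_mm must lie in (0, 0.18]")
  if (min_long_count < 1)
    pv_stop("pv_config_error", "min_long_count must be >= 1")
  structure(list(long_threshold_mm = long_threshold_mm,
                 min_long_count = as.integer(min_long_count),
                 elongation_min = elongation_min,
                 orientation_band_deg = orientation_band_deg,
                 dark_k = dark_k, min_area_px = as.integer(min_area_px),
                 min_darkness = min_darkness),
            class = "classifier_params")
}

empty_stripes <- function() {
  data.frame(cell_index = integer(), centroid_x = numeric(),
             centroid_y = numeric(), length_px = numeric(),
             length_mm = numeric(), width_px = numeric(),
             elongation = numeric(), orientation_deg = numeric(),
             mean_darkness = numeric(), area_px = integer())
}

#' Detect elongated dark stripes (candidate setae) in a grid cell
#'
#' Dark objects are pixels strictly below the cell-adaptive threshold
#' `max(0, mean - dark_k * sd)`. 8-connected components are measured along
#' their principal axis (extent of the pixel projections plus one pixel) and
#' kept when large enough, elongated enough, and oriented within
#' `orientation_band_deg` of vertical. Physical length projects the per-axis
#' standard-frame calibration onto the stripe axis, which undoes the
#' anisotropy of the fixed-size resize.
#'
#' @param cell numeric gray matrix of the cell (standard frame), or an
#'   element of [make_grid()].
#' @param calibration `c(x, y)` micrometres per standardized pixel
#'   (`um_per_px_std` of the `pupa_std`).
#' @param params a [classifier_params()].
#' @param cell_index cell identifier carried into the output.
#' @return data frame of stripes: centroid, pixel and mm lengths,
#'   elongation, orientation (degrees vs. horizontal, in (-90, 90]),
#'   mean darkness (cell mean minus stripe mean gray), area.
#' @export
detect_stripes <- function(cell, calibration, params = classifier_params(),
                           cell_index = NA_integer_) {
  px <- if (is.list(cell)) cell$pixels else cell
  if (is.list(cell) && is.na(cell_index)) cell_index <- cell$cell_index
  if (any(calibration <= 0))
    pv_stop("pv_config_error", "calibration must be positive")
  mg <- mean(px); sg <- sd(px)
  thr <- max(0, mg - params$dark_k * sg)
  dm <- px < thr
  if (!any(dm)) return(empty_stripes())
  lab <- label_components(dm)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_area_px)
  if (!length(keep)) return(empty_stripes())
  out <- lapply(keep, function(L) {
    pts <- which(lab == L, arr.ind = TRUE) - 1  # 0-based (x, y)
    ctr <- colMeans(pts)
    pc <- sweep(pts, 2, ctr)
    ev <- eigen(cov(pc), symmetric = TRUE)
    v1 <- ev$vectors[, 1]
    if (v1[1] < 0) v1 <- -v1
    pr <- pc %*% ev$vectors
    len_px <- diff(range(pr[, 1])) + 1
    wid_px <- diff(range(pr[, 2])) + 1
    ori <- norm_angle(atan2(v1[2], v1[1]) * 180 / pi)
    len_mm <- len_px *
      sqrt((v1[1] * calibration[1])^2 + (v1[2] * calibration[2])^2) / 1000
    data.frame(cell_index = cell_index, centroid_x = ctr[1],
               centroid_y = ctr[2], length_px = len_px, length_mm = len_mm,
               width_px = wid_px, elongation = len_px / wid_px,
               orientation_deg = ori,
               mean_darkness = mg - mean(px[lab == L]),
               area_px = sizes[L])
  })
  out <- do.call(rbind, out)
  ok <- out$elongation >= params$elongation_min &
    abs(abs(out$orientation_deg) - 90) <= params$orientation_band_deg &
    out$mean_darkness >= params$min_darkness
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call sex evidence for one pupa-day from detected stripes
#'
#' `male_setae_detected` iff at least `min_long_count` stripes are strictly
#' longer than `long_threshold_mm`; otherwise `no_setae_detected`.
#'
#' @param stripes data frame from [detect_stripes()].
#' @param params a [classifier_params()].
#' @param pupa_id,day_index identifiers carried into the call.
#' @return a one-row data frame: `pupa_id, day_index, n_stripes,
#'   long_stripe_count, max_length_mm, call`.
#' @export
call_sex <- function(stripes, params = classifier_params(),
                     pupa_id = NA_integer_, day_index = NA_integer_) {
  long_n <- sum(stripes$length_mm > params$long_threshold_mm)
  data.frame(
    pupa_id = pupa_id, day_index = day_index,
    n_stripes = nrow(stripes),
    long_stripe_count = long_n,
    max_length_mm = if (nrow(stripes)) max(stripes$length_mm) else NA_real_,
    call = if (long_n >= params$min_long_count) "male_setae_detected"
           else "no_setae_detected"
  )
}

#' Pupa-level call from the daily series of calls
#'
#' A pupa is setae-positive iff any day is positive (the setae appear only on
#' the last days before eclosion, and once seen the evidence stands). The
#' first positive day is recorded.
#'
#' @param daily_calls data frame of [call_sex()] rows for one pupa.
#' @return one-row data frame: `pupa_id, call, first_positive_day, n_days`.
#' @export
call_pupa <- function(daily_calls) {
  if (!nrow(daily_calls))
    pv_stop("pv_config_error", "call_pupa needs at least one daily call")
  pos <- daily_calls$day_index[daily_calls$call == "male_setae_detected"]
  data.frame(
    pupa_id = daily_calls$pupa_id[1],
    call = if (length(pos)) "male_setae_detected" else "no_setae_detected",
    first_positive_day = if (length(pos)) min(pos) else NA_integer_,
    n_days = nrow(daily_calls)
  )
}
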