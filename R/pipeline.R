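#' Pipeline configuration
#'
#' Collects the constants of every stage. Defaults are the values used
#' throughout: raw range 65520 to 8-bit, opening radius 5 px, standard frame
#' 2800 x 1300, 5 x 5 grid with tail cell 17, and the default
#' [classifier_params()].
#'
#' @param in_max,out_max raw and normalized pixel range maxima.
#' @param opening_radius disk radius of the morphological opening (raw px).
#' @param target_width,target_height standard frame size.
#' @param grid a [grid_spec()].
#' @param classifier a [classifier_params()].
#' @param um_per_px fallback raw calibration when the manifest carries none.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(in_max = 65520L, out_max = 255L,
                            opening_radius = 5,
                            target_width = 2800L, target_height = 1300L,
                            grid = grid_spec(),
                            classifier = classifier_params(),
                            um_per_px = 8) {
  if (in_max <= 0 || out_max <= 0)
    pv_stop("pv_config_error", "pixel range maxima must be positive")
  structure(list(in_max = as.integer(in_max), out_max = as.integer(out_max),
                 opening_radius = opening_radius,
                 target_width = as.integer(target_width),
                 target_height = as.integer(target_height),
                 grid = grid, classifier = classifier,
                 um_per_px = um_per_px), class = "pipeline_config")
}

#' Process one raw pupa image through preprocessing, segmentation, pose
#' normalization, grid features and stripe detection
#'
#' @param raw a `pupa_raw` object.
#' @param cfg a [pipeline_config()].
#' @param um_per_px raw calibration; defaults to the image's own ground truth
#'   (synthetic images) or the config fallback.
#' @return list with `features` (25-row data frame), `daily_call` (one row),
#'   `stripes`, and the `std` frame's calibration.
#' @export
process_raw_image <- function(raw, cfg = pipeline_config(),
                              um_per_px = NULL) {
  um <- um_per_px %||% raw$truth$um_per_px %||% cfg$um_per_px
  rgb8 <- normalize_range(raw, cfg$in_max, cfg$out_max)
  s <- saturation_channel(rgb8)
  mask <- segment_pupa(s, cfg$opening_radius, raw$pupa_id, raw$day_index)
  gray <- luminance(rgb8)
  std <- standardize_pupa(gray, mask, um, raw$pupa_id, raw$day_index,
                          cfg$target_width, cfg$target_height)
  feats <- grid_features(std, cfg$grid)
  tb <- cell_bounds(cfg$grid, cfg$grid$tail_cell_index,
                    cfg$target_width, cfg$target_height)
  tail_cell <- std$gray[(tb["x0"] + 1):tb["x1"], (tb["y0"] + 1):tb["y1"]]
  stripes <- detect_stripes(tail_cell, std$um_per_px_std, cfg$classifier,
                            cfg$grid$tail_cell_index)
  daily <- call_sex(stripes, cfg$classifier, raw$pupa_id, raw$day_index)
  list(features = feats, daily_call = daily, stripes = stripes,
       um_per_px_std = std$um_per_px_std)
}

#' Process a full day series of one pupa
#'
#' @param series list of `pupa_raw` (one per day).
#' @param cfg a [pipeline_config()].
#' @param um_per_px raw calibration override.
#' @return list with stacked `features`, `daily_calls`, the per-pupa `call`
#'   row, and a `failures` data frame of images that could not be processed
#'   (empty when all days succeed).
#' @export
process_series <- function(series, cfg = pipeline_config(),
                           um_per_px = NULL) {
  feats <- list(); daily <- list(); fails <- list()
  for (raw in series) {
    res <- tryCatch(process_raw_image(raw, cfg, um_per_px),
                    pupavision_error = function(e) e)
    if (inherits(res, "pupavision_error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        pupa_id = raw$pupa_id, day_index = raw$day_index,
        reason = conditionMessage(res))
    } else {
      feats[[length(feats) + 1L]] <- res$features
      daily[[length(daily) + 1L]] <- res$daily_call
    }
  }
  daily_df <- if (length(daily)) do.call(rbind, daily) else
    data.frame(pupa_id = integer(), day_index = integer(),
               n_stripes = integer(), long_stripe_count = integer(),
               max_length_mm = numeric(), call = character())
  list(
    features = if (length(feats)) do.call(rbind, feats) else NULL,
    daily_calls = daily_df,
    call = if (nrow(daily_df)) call_pupa(daily_df) else NULL,
    failures = if (length(fails)) do.call(rbind, fails) else
      data.frame(pupa_id = integer(), day_index = integer(),
                 reason = character())
  )
}

collect_results <- function(per_pupa, manifest, cfg) {
  features <- do.call(rbind, lapply(per_pupa, `[[`, "features"))
  daily_calls <- do.call(rbind, lapply(per_pupa, `[[`, "daily_calls"))
  pupa_calls <- do.call(rbind, lapply(per_pupa, `[[`, "call"))
  failures <- do.call(rbind, lapply(per_pupa, `[[`, "failures"))
  screen <- temporal_screen(features, cfg$grid)
  tab <- build_table(pupa_calls, manifest)
  structure(list(features = features, daily_calls = daily_calls,
                 pupa_calls = pupa_calls, screen = screen, table = tab,
                 failures = failures, manifest = manifest),
            class = "pupavision_result")
}

#' @export
print.pupavision_result <- function(x, ...) {
  cat(sprintf("pupavision run: %d pupae, %d images, %d failures\n",
              nrow(x$pupa_calls), nrow(x$daily_calls), nrow(x$failures)))
  cat(sprintf("top-ranked grid cell by temporal change: %d\n",
              x$screen$cell_index[1]))
  print(x$table)
  invisible(x)
}

#' Run the pipeline on a synthetic cohort, streaming pupa by pupa
#'
#' Generates each pupa's day series from the configuration, processes it, and
#' keeps only features and calls, so cohorts of hundreds of pupae run in
#' constant memory. The evaluation compares calls against the generator's
#' ground-truth outcomes.
#'
#' @param gen_cfg a [generator_config()].
#' @param cfg a [pipeline_config()].
#' @return a `pupavision_result`: `features`, `daily_calls`, `pupa_calls`,
#'   `screen` (temporal ranking), `table` (a `pupa_eval`), `failures`,
#'   `manifest`.
#' @export
run_synthetic_cohort <- function(gen_cfg, cfg = pipeline_config()) {
  truth <- cohort_truth(gen_cfg)
  if (!nrow(truth))
    pv_stop("pv_config_error", "empty cohort: nothing to run")
  per_pupa <- lapply(seq_len(nrow(truth)), function(i) {
    series <- generate_pupa_series(gen_cfg, truth[i, ])
    process_series(series, cfg)
  })
  man <- truth[, c("pupa_id", "true_sex", "outcome", "eclosion_day",
                   "um_per_px")]
  collect_results(per_pupa, man, cfg)
}

#' Run the pipeline on a directory of TIFF day series
#'
#' Expects images named `<pupa_id>_day<d>.tif` and a manifest CSV with
#' columns `pupa_id,true_sex,outcome,eclosion_day,um_per_px` (sex/outcome
#' columns may be the eventual eclosion record). Images are validated
#' against the declared pixel range on load; per-image failures are recorded
#' and the pupa is excluded from classification for that day rather than
#' aborting the run.
#'
#' @param input_dir directory of TIFF images.
#' @param manifest_path path to the manifest CSV (default
#'   `input_dir/manifest.csv`).
#' @param output_dir when non-NULL, CSV/JSON reports are written there via
#'   [write_results()].
#' @param cfg a [pipeline_config()].
#' @return a `pupavision_result`, invisibly when writing reports.
#' @export
run_pipeline <- function(input_dir,
                         manifest_path = file.path(input_dir, "manifest.csv"),
                         output_dir = NULL, cfg = pipeline_config()) {
  if (!file.exists(manifest_path))
    pv_stop("pv_io_error", sprintf("manifest not found: %s", manifest_path))
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  files <- list.files(input_dir, pattern = "_day[0-9]+\\.tif$")
  if (!length(files))
    pv_stop("pv_io_error", sprintf("no pupa images in %s", input_dir))
  per_pupa <- lapply(manifest$pupa_id, function(pid) {
    um <- manifest$um_per_px[manifest$pupa_id == pid][1]
    fs <- files[startsWith(files, paste0(pid, "_day"))]
    days <- as.integer(sub(".*_day([0-9]+)\\.tif$", "\\1", fs))
    fs <- fs[order(days)]
    series <- list(); fails <- list()
    for (f in fs) {
      d <- as.integer(sub(".*_day([0-9]+)\\.tif$", "\\1", f))
      raw <- tryCatch(
        read_pupa_tiff(file.path(input_dir, f), pid, d, cfg$in_max),
        pupavision_error = function(e) e)
      if (inherits(raw, "pupavision_error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          pupa_id = pid, day_index = d, reason = conditionMessage(raw))
      } else series[[length(series) + 1L]] <- raw
    }
    res <- process_series(series, cfg, um_per_px = um)
    res$failures <- rbind(do.call(rbind, fails), res$failures)
    res
  })
  out <- collect_results(per_pupa, manifest, cfg)
  if (!is.null(output_dir)) {
    write_results(out, output_dir)
    return(invisible(out))
  }
  out
}

#' Read one raw pupa image from a 16-bit TIFF
#'
#' @param path TIFF path.
#' @param pupa_id,day_index identifiers to attach.
#' @param in_max declared pixel-range maximum; values above it are rejected.
#' @return a `pupa_raw` object.
#' @export
read_pupa_tiff <- function(path, pupa_id = NA_integer_,
                           day_index = NA_integer_, in_max = 65520L) {
  arr <- tryCatch(tiff::readTIFF(path), error = function(e)
    pv_stop("pv_io_error", sprintf("cannot read %s: %s", path,
                                   conditionMessage(e))))
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    pv_stop("pv_image_error", sprintf("%s: expected a 3-channel image", path))
  px <- aperm(arr[, , 1:3, drop = FALSE], c(2, 1, 3))  # to (x, y, channel)
  px <- array(as.integer(round_half_up(px * 65535)), dim(px))
  if (max(px) > in_max)
    pv_stop("pv_image_error",
            sprintf("%s: pixel maximum %d exceeds [0, %d]",
                    path, max(px), in_max))
  structure(list(pixels = px, pupa_id = pupa_id, day_index = day_index,
                 water_treated_day8 = !is.na(day_index) && day_index >= 8,
                 truth = NULL), class = "pupa_raw")
}

#' Write one raw pupa image as a 16-bit TIFF
#'
#' Pixels are stored as `value / 65535`, so the integer values round-trip
#' exactly through [read_pupa_tiff()].
#'
#' @param raw a `pupa_raw`.
#' @param path output path.
#' @export
write_pupa_tiff <- function(raw, path) {
  px <- aperm(raw$pixels, c(2, 1, 3)) / 65535
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

write_df <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write the CSV/JSON reports of a pipeline run
#'
#' Writes `features.csv`, `daily_calls.csv`, `pupa_calls.csv`, `screen.csv`,
#' `failures.csv`, `evaluation.csv` and `evaluation.json` into `dir`.
#' Identical results write byte-identical files.
#'
#' @param res a `pupavision_result`.
#' @param dir output directory, created if missing.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "pupavision_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
    df
  }
  write_df(fmt(res$features), file.path(dir, "features.csv"))
  write_df(fmt(res$daily_calls), file.path(dir, "daily_calls.csv"))
  write_df(res$pupa_calls, file.path(dir, "pupa_calls.csv"))
  write_df(fmt(res$screen), file.path(dir, "screen.csv"))
  write_df(res$failures, file.path(dir, "failures.csv"))
  write_df(summarize_evaluation(res$table), file.path(dir, "evaluation.csv"))
  jsonlite::write_json(evaluation_as_list(res$table),
                       file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
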