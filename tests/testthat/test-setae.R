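um_std <- c(x = 2, y = 1.5)  # a typical standardized-frame calibration

test_that("a blank cell yields no stripes", {
  cell <- render_test_cell(noise_sd = 2, seed = 2)
  expect_equal(nrow(detect_stripes(cell, um_std)), 0)
})

test_that("a rendered 0.12 mm stripe is recovered within 10 percent", {
  stripes <- data.frame(x0_px = 280, y0_px = 130, len_mm = 0.12,
                        w_mm = 0.02, gray = 30)
  cell <- render_test_cell(stripes = stripes, noise_sd = 2, seed = 3)
  got <- detect_stripes(cell, um_std)
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$length_mm - 0.12) / 0.12, 0.10)
  expect_gt(abs(got$orientation_deg), 60)  # near vertical
})

test_that("round blobs and shallow smudges are rejected", {
  blob <- data.frame(x0_px = 280, y0_px = 130, len_mm = 0.04,
                     w_mm = 0.04, gray = 30)
  cell <- render_test_cell(stripes = blob, noise_sd = 1, seed = 4)
  expect_equal(nrow(detect_stripes(cell, um_std)), 0)

  faint <- data.frame(x0_px = 280, y0_px = 130, len_mm = 0.12,
                      w_mm = 0.02, gray = 122)  # barely below the cuticle
  cell2 <- render_test_cell(stripes = faint, noise_sd = 6, seed = 5)
  got <- detect_stripes(cell2, um_std)
  if (nrow(got)) expect_true(all(got$mean_darkness >= 25))
})

test_that("multiple stripes are measured individually", {
  stripes <- data.frame(x0_px = c(150, 250, 350, 450),
                        y0_px = 130,
                        len_mm = c(0.06, 0.10, 0.14, 0.17),
                        w_mm = 0.02, gray = 30)
  cell <- render_test_cell(stripes = stripes, noise_sd = 2, seed = 6)
  got <- detect_stripes(cell, um_std)
  expect_equal(nrow(got), 4)
  got <- got[order(got$centroid_x), ]
  expect_equal(got$length_mm, stripes$len_mm, tolerance = 0.08)
})

test_that("sex calls follow the strict long-stripe rule", {
  p <- classifier_params()
  mk <- function(lens) data.frame(length_mm = lens)
  expect_equal(call_sex(mk(c(0.02, 0.18)), p)$call, "male_setae_detected")
  expect_equal(call_sex(mk(c(0.02, 0.05)), p)$call, "no_setae_detected")
  expect_equal(call_sex(mk(numeric()), p)$call, "no_setae_detected")
  # the 0.05 mm boundary itself is short: strictly greater is required
  expect_equal(call_sex(mk(0.050000), p)$long_stripe_count, 0)
  expect_equal(call_sex(mk(0.0501), p)$long_stripe_count, 1)
})

test_that("raising the long threshold never converts negative to positive", {
  set.seed(31)
  for (i in 1:20) {
    lens <- runif(sample(0:6, 1), 0.01, 0.2)
    thresholds <- sort(runif(2, 0.02, 0.18))
    lo <- call_sex(data.frame(length_mm = lens),
                   classifier_params(long_threshold_mm = thresholds[1]))
    hi <- call_sex(data.frame(length_mm = lens),
                   classifier_params(long_threshold_mm = thresholds[2]))
    if (lo$call == "no_setae_detected")
      expect_equal(hi$call, "no_setae_detected")
  }
})

test_that("pupa-level call latches on any positive day", {
  daily <- data.frame(pupa_id = 1, day_index = 1:11,
                      call = c(rep("no_setae_detected", 9),
                               rep("male_setae_detected", 2)))
  out <- call_pupa(daily)
  expect_equal(out$call, "male_setae_detected")
  expect_equal(out$first_positive_day, 10)

  neg <- data.frame(pupa_id = 2, day_index = 1:5,
                    call = rep("no_setae_detected", 5))
  expect_equal(call_pupa(neg)$call, "no_setae_detected")

  latch <- data.frame(pupa_id = 3, day_index = 1:3,
                      call = c("male_setae_detected", "no_setae_detected",
                               "no_setae_detected"))
  expect_equal(call_pupa(latch)$call, "male_setae_detected")
  expect_equal(call_pupa(latch)$first_positive_day, 1)
})

test_that("detected long setae on a synthetic male match the generated comb", {
  cfg <- small_gen_cfg(seed = 37)
  truth <- cohort_truth(cfg)
  male <- truth[truth$outcome == "male", ][1, ]
  series <- generate_pupa_series(cfg, male)
  res <- process_raw_image(series[[10]], pipeline_config())
  truth_long <- series[[10]]$truth$stripes
  truth_long <- truth_long[truth_long$kind == "long", ]
  # every generated long seta comfortably above the threshold should be seen
  expect_gte(res$daily_call$long_stripe_count,
             sum(truth_long$len_mm > 0.08))
  expect_lte(res$daily_call$long_stripe_count, nrow(truth_long))
  # the longest measured stripe matches the longest generated one
  expect_lt(abs(res$daily_call$max_length_mm - max(truth_long$len_mm)) /
              max(truth_long$len_mm), 0.10)
})

test_that("identical inputs give identical calls", {
  cfg <- small_gen_cfg(seed = 41)
  truth <- cohort_truth(cfg)
  male <- truth[truth$true_sex == "male", ][1, ]
  raw <- generate_pupa_series(cfg, male)[[10]]
  r1 <- process_raw_image(raw, pipeline_config())
  r2 <- process_raw_image(raw, pipeline_config())
  expect_identical(r1$daily_call, r2$daily_call)
  expect_identical(r1$stripes, r2$stripes)
})
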