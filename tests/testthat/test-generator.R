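test_that("cohort counts follow the round-half-up allocation", {
  cfg <- small_gen_cfg(n_pupae = 10, male_fraction = 0.5,
                       unfledged_fraction = 0, seed = 3)
  truth <- cohort_truth(cfg)
  expect_equal(sum(truth$true_sex == "male"), 5)

  # independent re-application of the rounding rule at several sizes
  for (par in list(c(500, 0.5, 0.096), c(37, 0.31, 0.11),
                   c(21, 0.25, 0.5))) {
    cfg2 <- small_gen_cfg(n_pupae = par[1], male_fraction = par[2],
                          unfledged_fraction = par[3], seed = 7)
    truth2 <- cohort_truth(cfg2)
    expect_equal(sum(truth2$true_sex == "male"), floor(par[1] * par[2] + 0.5))
    expect_equal(sum(truth2$outcome == "unfledged"),
                 floor(par[1] * par[3] + 0.5))
    expect_true(all(truth2$outcome[truth2$outcome != "unfledged"] ==
                      truth2$true_sex[truth2$outcome != "unfledged"]))
    expect_true(all(is.na(truth2$eclosion_day[truth2$outcome == "unfledged"])))
  }
})

test_that("an empty cohort is empty, not an error", {
  cfg <- small_gen_cfg(n_pupae = 0)
  out <- generate_cohort(cfg)
  expect_length(out$series, 0)
  expect_equal(nrow(out$manifest), 0)
})

test_that("invalid configurations and records are rejected", {
  expect_error(generator_config(male_fraction = 1.2),
               class = "pv_config_error")
  expect_error(generator_config(rotation_range_deg = c(-120, 45)),
               class = "pv_config_error")
  cfg <- small_gen_cfg()
  expect_error(
    generate_pupa_series(cfg, list(pupa_id = 1, true_sex = "male",
                                   outcome = "female")),
    class = "pv_record_error")
  expect_error(
    generate_pupa_series(cfg, list(pupa_id = 1, true_sex = "x",
                                   outcome = "male")),
    class = "pv_record_error")
})

test_that("the same configuration reproduces the cohort bit for bit", {
  cfg <- small_gen_cfg(n_pupae = 2, seed = 19)
  t1 <- cohort_truth(cfg)
  t2 <- cohort_truth(cfg)
  expect_identical(t1[, setdiff(names(t1), "setae_visible_days")],
                   t2[, setdiff(names(t2), "setae_visible_days")])
  s1 <- generate_pupa_series(cfg, t1[1, ])
  s2 <- generate_pupa_series(cfg, t1[1, ])
  for (d in seq_along(s1))
    expect_identical(s1[[d]]$pixels, s2[[d]]$pixels)
})

test_that("generated images satisfy the raw-image contract", {
  cfg <- small_gen_cfg(seed = 29)
  truth <- cohort_truth(cfg)
  series <- generate_pupa_series(cfg, truth[1, ])
  expect_length(series, cfg$n_days)
  for (raw in series[c(1, 8, 11)]) {
    expect_identical(dim(raw$pixels), c(cfg$image_width_px,
                                        cfg$image_height_px, 3L))
    expect_gte(min(raw$pixels), 0)
    expect_lte(max(raw$pixels), 65520)
  }
  expect_false(series[[7]]$water_treated_day8)
  expect_true(series[[8]]$water_treated_day8)
})

test_that("setae appear only on the last two days before eclosion, males only", {
  cfg <- small_gen_cfg(n_pupae = 6, seed = 31, unfledged_fraction = 0.34)
  truth <- cohort_truth(cfg)
  male <- truth[truth$outcome == "male", ][1, ]
  female <- truth[truth$outcome == "female", ][1, ]
  unfledged <- truth[truth$outcome == "unfledged", ][1, ]

  ms <- generate_pupa_series(cfg, male)
  days_with_long <- which(vapply(ms, function(r)
    any(r$truth$stripes$kind == "long"), logical(1)))
  expect_equal(days_with_long, c(10L, 11L))
  n_long <- sum(ms[[10]]$truth$stripes$kind == "long")
  expect_gte(n_long, 16)
  expect_lte(n_long, 20)
  lens <- ms[[10]]$truth$stripes
  expect_true(all(lens$len_mm[lens$kind == "long"] >= 0.05 &
                    lens$len_mm[lens$kind == "long"] <= 0.18))
  expect_true(all(lens$len_mm[lens$kind == "short"] >= 0.02 &
                    lens$len_mm[lens$kind == "short"] <= 0.05))

  fs <- generate_pupa_series(cfg, female)
  for (r in fs) {
    expect_false(any(r$truth$stripes$kind == "long"))
    if (nrow(r$truth$stripes))
      expect_true(all(r$truth$stripes$len_mm <= 0.05))
  }
  us <- generate_pupa_series(cfg, unfledged)
  for (r in us) expect_equal(nrow(r$truth$stripes), 0)
})

test_that("TIFF output round-trips pixel-exactly and the manifest is valid", {
  cfg <- small_gen_cfg(n_pupae = 1, n_days = 2, eclosion_day = 12,
                       seed = 43)
  dir <- withr::local_tempdir()
  write_cohort(cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(names(man), c("pupa_id", "true_sex", "outcome",
                                 "eclosion_day", "um_per_px"))
  truth <- cohort_truth(cfg)
  orig <- generate_pupa_series(cfg, truth[1, ])[[2]]
  back <- read_pupa_tiff(file.path(dir, "1_day2.tif"), 1L, 2L)
  expect_identical(back$pixels, orig$pixels)
})
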