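test_that("heatmap tables are min-max normalised with flag-driven masks", {
  co <- small_cohort(seed = 5)
  cls <- suppressWarnings(classify_cohort(co))
  hm <- suppressWarnings(heatmap_table(cls))
  feat_cols <- c(
    "accuracy_subtract", "rt_subtract", "headset_mean", "gaze_mean",
    "headset_slope", "gaze_slope", "accuracy_slope", "rt_slope",
    "atypicality", "orientation", "challenge", "severity"
  )
  for (tab in hm) {
    vals <- as.matrix(tab[, feat_cols])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(any(vals == 1)) # someone holds each column maximum
  }
  # mask density over the 8 feature cells equals mean atypicality / 8
  pat <- hm$patients
  mask <- as.matrix(pat[, paste0("mask_", c(
    "accuracy_subtract", "rt_subtract", "headset_mean", "gaze_mean",
    "headset_slope", "gaze_slope", "accuracy_slope", "rt_slope"
  ))])
  mean_atyp <- mean(cls$atypicality[cls$group == "patient"])
  expect_equal(mean(mask), mean_atyp / 8)
})

test_that("an all-typical cohort produces an empty mask and constant warning", {
  features <- tibble::tibble(
    player_id = sprintf("Z%02d", 1:8),
    group = rep(c("control", "patient"), each = 4),
    accuracy_subtract = 0, rt_subtract = 0,
    headset_mean_8 = 0, headset_mean_16 = 0, headset_mean_24 = 0,
    gaze_mean_8 = 0, gaze_mean_16 = 0, gaze_mean_24 = 0,
    headset_slope = 0, gaze_slope = 0, accuracy_slope = 0, rt_slope = 0,
    acc_left = 95, acc_right = 95
  )
  cls <- classify_cohort(features)
  w <- capture_warnings(hm <- heatmap_table(cls))
  expect_true(any(grepl("constant column", w)))
  mask <- as.matrix(dplyr::select(hm$patients, dplyr::starts_with("mask_")))
  expect_false(any(mask))
  expect_true(all(as.matrix(hm$patients[, "accuracy_subtract"]) == 0.5))
})

test_that("raycast histograms conserve frames in 1-degree bins", {
  frames <- tibble::tibble(
    player_id = "P01", source = "gaze", set_size = 24L,
    lateral_angle = c(10.2, 10.7, -3.5, 0.0), vertical_angle = c(1.1, 1.9, -2.2, 0.4)
  )
  h <- raycast_histogram(frames, "gaze")
  expect_equal(sum(h$count), 4)
  expect_equal(attr(h, "total_frames"), 4L)
  expect_equal(h$count[h$lat_bin == 10 & h$vert_bin == 1], 2)

  same_spot <- dplyr::mutate(frames, lateral_angle = 5.5, vertical_angle = 0.5)
  h1 <- raycast_histogram(same_spot, "gaze")
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 4)

  empty <- raycast_histogram(frames, "controller")
  expect_equal(sum(empty$count), 0)
  expect_equal(attr(raycast_histogram(NULL, "gaze"), "total_frames"), 0L)

  co <- simulate_cohort(
    n_controls = 1, n_patients = 1, patient_mix = c(typical = 1),
    seed = 3, n_frames_per_level = 50
  )
  h2 <- raycast_histogram(co$frames, "headset", set_size = 24)
  expect_equal(sum(h2$count), attr(h2, "total_frames"))
  expect_equal(
    attr(h2, "total_frames"),
    sum(co$frames$source == "headset" & co$frames$set_size == 24)
  )
})

test_that("position maps aggregate accuracy and drop RT where nothing survives", {
  tr <- dplyr::bind_rows(
    trial_row(lat = 25, vert = 0, correct = 1L, rt = 1.0),
    trial_row(lat = 25, vert = 0, correct = 1L, rt = 1.2),
    trial_row(lat = 25, vert = 0, correct = 1L, rt = 1.1),
    trial_row(lat = 25, vert = 0, correct = 0L, rt = 2.0),
    trial_row(lat = -25, vert = 0, correct = 0L, rt = 2.5),
    trial_row(lat = -25, vert = 0, correct = 0L, rt = 2.6)
  )
  pm <- position_maps(tr)
  right <- pm[pm$target_lateral_angle == 25, ]
  expect_equal(right$accuracy_pct, 75)
  expect_equal(right$rt_s, 1.1)
  left <- pm[pm$target_lateral_angle == -25, ]
  expect_equal(left$accuracy_pct, 0)
  expect_true(is.na(left$rt_s))
  expect_equal(left$n_rt, 0L)
})

test_that("category summaries mirror the classification and hide singleton SDs", {
  co <- small_cohort(seed = 9)
  cls <- suppressWarnings(classify_cohort(co))
  cs <- category_summary(cls, co$covariates)
  expect_equal(sum(cs$n), sum(cls$group == "patient"))
  singles <- cs[cs$n == 1, ]
  if (nrow(singles) > 0) expect_true(all(is.na(singles$atypicality_sd)))
  neg_rows <- cs[startsWith(cs$rowclass, "Neglect"), ]
  expect_equal(sum(neg_rows$n), sum(cls$label == "neglect" & cls$group == "patient"))
  expect_equal(sum(neg_rows$pct_of_neglect), 100)
  expect_true("non_neglect" %in% cs$rowclass)
})

test_that("report files are written and re-running is reproducible", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(
    n_controls = 5, n_patients = 8,
    patient_mix = c(typical = 5, loc = 1, ro = 1, minor = 1),
    seed = 14, n_frames_per_level = 20
  )
  cls <- suppressWarnings(classify_cohort(co))
  paths <- suppressWarnings(write_report(cls, co, dir))
  expect_true(all(file.exists(file.path(
    dir,
    c(
      "heatmap_patients.csv", "heatmap_controls.csv", "categories.csv",
      "position_map.csv", "histogram_gaze.csv"
    )
  ))))
  first <- readr::read_csv(file.path(dir, "categories.csv"), show_col_types = FALSE)
  suppressWarnings(write_report(suppressWarnings(classify_cohort(co)), co, dir))
  second <- readr::read_csv(file.path(dir, "categories.csv"), show_col_types = FALSE)
  expect_equal(first, second)
})
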