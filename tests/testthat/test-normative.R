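test_that("tukey_fence matches an independent quantile computation", {
  # [1,2,3,4] under linear interpolation: Q1 = 1.75, Q3 = 3.25
  f <- tukey_fence(c(1, 2, 3, 4))
  expect_equal(f$q1, 1.75)
  expect_equal(f$q3, 3.25)
  expect_equal(f$iqr, 1.5)
  expect_equal(f$lower, 1.75 - 2.25)
  expect_equal(f$upper, 3.25 + 2.25)

  const <- tukey_fence(c(5, 5, 5, 5))
  expect_equal(const$iqr, 0)
  expect_equal(const$lower, 5)
  expect_equal(const$upper, 5)

  expect_error(tukey_fence(c(1, 2, 3)), "fewer than 4")
  expect_error(tukey_fence(c(1, 2, 3, NA)), "fewer than 4")
})

test_that("cutoffs cover every metric with per-set-size fences for means", {
  co <- small_cohort(seed = 2)
  cuts <- compute_cutoffs(extract_features(co))
  counts <- dplyr::count(tibble::as_tibble(cuts), metric, cohort)
  wide <- tidyr::pivot_wider(counts, names_from = cohort, values_from = n)
  expect_setequal(
    wide$metric,
    c(
      "accuracy_subtract", "rt_subtract", "headset_slope", "gaze_slope",
      "accuracy_slope", "rt_slope", "headset_mean", "gaze_mean"
    )
  )
  expect_true(all(wide$controls == ifelse(grepl("_mean$", wide$metric), 3, 1)))
  expect_true(all(wide$patients == wide$controls))
  expect_true(all(cuts$lower <= cuts$q1 & cuts$q3 <= cuts$upper))
})

test_that("cutoffs on a hand-built feature table equal per-vector fences", {
  set.seed(9)
  features <- tibble::tibble(
    player_id = sprintf("X%02d", 1:10),
    group = rep(c("control", "patient"), each = 5),
    accuracy_subtract = stats::rnorm(10), rt_subtract = stats::rnorm(10),
    headset_mean_8 = stats::rnorm(10), headset_mean_16 = stats::rnorm(10),
    headset_mean_24 = stats::rnorm(10),
    gaze_mean_8 = stats::rnorm(10), gaze_mean_16 = stats::rnorm(10),
    gaze_mean_24 = stats::rnorm(10),
    headset_slope = stats::rnorm(10), gaze_slope = stats::rnorm(10),
    accuracy_slope = stats::rnorm(10), rt_slope = stats::rnorm(10),
    acc_left = 90, acc_right = 90
  )
  cuts <- compute_cutoffs(features)
  pick <- function(metric, cohort, set_size = NA) {
    r <- cuts[cuts$metric == metric & cuts$cohort == cohort &
      (is.na(set_size) == is.na(cuts$set_size)) &
      (is.na(set_size) | cuts$set_size %in% set_size), ]
    r
  }
  oracle <- tukey_fence(features$rt_subtract[features$group == "control"])
  got <- pick("rt_subtract", "controls")
  expect_equal(got$lower, oracle$lower)
  expect_equal(got$upper, oracle$upper)
  oracle <- tukey_fence(features$gaze_mean_16[features$group == "patient"])
  got <- pick("gaze_mean", "patients", 16)
  expect_equal(got$lower, oracle$lower)
  expect_equal(got$upper, oracle$upper)
})

test_that("insufficient cohorts are refused", {
  f <- extract_features(small_cohort(seed = 3))
  expect_error(compute_cutoffs(f[f$group == "patient", ]), "insufficient cohort")
  expect_error(compute_cutoffs(f[1:12, ], min_cohort = 5), "insufficient cohort")
})

test_that("atypicality requires exceeding both cohorts' fences, strictly", {
  ctrl <- tukey_fence(c(1, 2, 3, 4)) # fences -0.5 / 5.5
  pat <- tukey_fence(c(0, 3, 6, 9)) # q1 2.25 q3 6.75 iqr 4.5 -> -4.5 / 13.5
  expect_false(is_atypical(3, ctrl, pat)) # inside both
  expect_false(is_atypical(7, ctrl, pat)) # outside control, inside patient
  expect_true(is_atypical(14, ctrl, pat)) # outside both
  expect_false(is_atypical(5.5, ctrl, ctrl)) # boundary value is typical
  expect_warning(res <- is_atypical(NA, ctrl, pat), "missing")
  expect_false(res)
})

test_that("flags follow sign and one-sided challenge rules", {
  set.seed(10)
  base <- tibble::tibble(
    player_id = sprintf("N%02d", 1:12),
    group = rep(c("control", "patient"), 6),
    accuracy_subtract = stats::rnorm(12, 0, 0.5),
    rt_subtract = stats::rnorm(12, 0, 0.01),
    headset_mean_8 = stats::rnorm(12, 0, 0.5),
    headset_mean_16 = stats::rnorm(12, 0, 0.5),
    headset_mean_24 = stats::rnorm(12, 0, 0.5),
    gaze_mean_8 = stats::rnorm(12, 0, 0.5),
    gaze_mean_16 = stats::rnorm(12, 0, 0.5),
    gaze_mean_24 = stats::rnorm(12, 0, 0.5),
    headset_slope = stats::rnorm(12, 0, 0.05),
    gaze_slope = stats::rnorm(12, 0, 0.05),
    accuracy_slope = stats::rnorm(12, -0.1, 0.05),
    rt_slope = stats::rnorm(12, 0.03, 0.005),
    acc_left = 90, acc_right = 90
  )
  cuts <- compute_cutoffs(base)

  probe <- base[1, ]
  probe$player_id <- "probe"
  probe$group <- "patient"

  # atypically positive RT contrast -> +1
  probe$rt_subtract <- 1
  fl <- flag_features(probe, cuts)
  expect_equal(fl$rt_subtract, 1L)

  # atypically *positive* accuracy slope is the wrong direction: flag 0
  probe$accuracy_slope <- 5
  fl <- flag_features(probe, cuts)
  expect_equal(fl$accuracy_slope, 0L)
  probe$accuracy_slope <- -5
  fl <- flag_features(probe, cuts)
  expect_equal(fl$accuracy_slope, 1L)

  # rt slope one-sided: atypically *fast* scaling is not challenge
  probe$rt_slope <- -1
  fl <- flag_features(probe, cuts)
  expect_equal(fl$rt_slope, 0L)

  # mean metric: atypical at >= 1 set size, direction of largest exceedance
  probe$gaze_mean_16 <- -25
  fl <- flag_features(probe, cuts)
  expect_equal(fl$gaze_mean, -1L)

  # values inside fences leave all flags zero
  fl0 <- flag_features(base[2, ], cuts)
  expect_true(all(as.matrix(fl0[, -1]) == 0))
})

test_that("cutoffs survive a JSON round trip and freeze classification", {
  dir <- withr::local_tempdir()
  co <- small_cohort(seed = 4)
  f <- extract_features(co)
  cuts <- compute_cutoffs(f)
  path <- file.path(dir, "cutoffs.json")
  write_cutoffs(cuts, path)
  back <- read_cutoffs(path)
  expect_equal(
    as.data.frame(back)[order(back$metric, back$set_size, back$cohort), ],
    as.data.frame(cuts)[order(cuts$metric, cuts$set_size, cuts$cohort), ],
    tolerance = 1e-12, ignore_attr = TRUE
  )
  a <- suppressWarnings(classify_cohort(co))
  b <- suppressWarnings(classify_cohort(co, cutoffs = back))
  expect_equal(a$label, b$label)
  expect_equal(a$category_code, b$category_code)
})
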