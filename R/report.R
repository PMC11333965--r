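heatmap_feature_cols <- function() {
  c(feature_metric_names(), "atypicality", "orientation", "challenge", "severity")
}

#' Numeric classifier heatmap table
#'
#' One row per player, columns for the eight raw features and the four summary
#' scores, each min-max normalised to \[0, 1\] within the table (constant
#' columns normalise to 0.5 with a warning), plus `mask_*` columns marking the
#' cells whose feature flag is non-zero. The per-set-size mean lateral angles
#' are represented by the set-size mean of largest magnitude. Patients and
#' controls are returned as separate tables, as they are displayed.
#'
#' @param classification A `neglect_classification` from [classify_cohort()].
#' @return A list with tibbles `patients` and `controls`.
#' @export
heatmap_table <- function(classification) {
  features <- attr(classification, "features")
  cls <- tibble::as_tibble(as.data.frame(classification))

  raw <- tibble::tibble(
    player_id = features$player_id,
    accuracy_subtract = features$accuracy_subtract,
    rt_subtract = features$rt_subtract,
    headset_mean = dominant_mean(features, "headset_mean"),
    gaze_mean = dominant_mean(features, "gaze_mean"),
    headset_slope = features$headset_slope,
    gaze_slope = features$gaze_slope,
    accuracy_slope = features$accuracy_slope,
    rt_slope = features$rt_slope
  ) %>%
    dplyr::left_join(
      dplyr::select(
        cls, "player_id", "group", "label", "atypicality_band",
        "atypicality", "orientation", "challenge", "severity"
      ),
      by = "player_id"
    )

  one_table <- function(tab) {
    if (nrow(tab) == 0) {
      return(tab)
    }
    out <- dplyr::select(
      tab, "player_id", "label", band = "atypicality_band",
      dplyr::all_of(heatmap_feature_cols())
    ) %>%
      dplyr::arrange(.data$player_id)
    for (col in heatmap_feature_cols()) {
      v <- out[[col]]
      rng <- range(v, na.rm = TRUE)
      if (!all(is.finite(rng)) || rng[1] == rng[2]) {
        warning("heatmap_table(): constant column '", col, "' normalised to 0.5.",
          call. = FALSE
        )
        out[[col]] <- rep(0.5, nrow(out))
      } else {
        out[[col]] <- (v - rng[1]) / (rng[2] - rng[1])
      }
    }
    flags <- dplyr::select(
      cls, "player_id", dplyr::all_of(feature_metric_names())
    ) %>%
      dplyr::rename_with(~ paste0("mask_", .x), -"player_id")
    dplyr::left_join(out, flags, by = "player_id") %>%
      dplyr::mutate(dplyr::across(
        dplyr::starts_with("mask_"), ~ .x != 0
      ))
  }

  list(
    patients = one_table(dplyr::filter(raw, .data$group == "patient")),
    controls = one_table(dplyr::filter(raw, .data$group == "control"))
  )
}

# representative per-set-size mean: the value of largest magnitude
dominant_mean <- function(features, src) {
  cols <- paste0(src, "_", analysis_set_sizes())
  vals <- as.matrix(features[, cols])
  apply(vals, 1, function(v) {
    if (all(is.na(v))) {
      return(NA_real_)
    }
    v[which.max(abs(v))]
  })
}

#' Two-dimensional raycast attention histogram
#'
#' Counts raycast frames in 1-degree (by default) bins of lateral and vertical
#' angle, for one raycast source, restricted to set-size-24 levels by default
#' (the most attention-demanding search). Bin edges sit at integer multiples
#' of the bin width.
#'
#' @param frames Frame table (columns `source`, `set_size`, `lateral_angle`,
#'   `vertical_angle`), e.g. `cohort$frames`.
#' @param source `"headset"`, `"gaze"` or `"controller"`.
#' @param set_size Set size to keep (`NULL` keeps all).
#' @param bin_width Bin width in degrees.
#' @return A tibble of occupied bins (`lat_bin`, `vert_bin` are lower edges,
#'   `count`) with attribute `total_frames`; counts sum to the frames used.
#' @export
raycast_histogram <- function(frames, source, set_size = 24, bin_width = 1) {
  if (is.null(frames) || nrow(frames) == 0) {
    out <- tibble::tibble(
      lat_bin = numeric(), vert_bin = numeric(), count = integer()
    )
    attr(out, "total_frames") <- 0L
    attr(out, "bin_width") <- bin_width
    return(out)
  }
  f <- dplyr::filter(frames, .data$source == !!source)
  if (!is.null(set_size)) f <- dplyr::filter(f, .data$set_size == !!set_size)
  out <- f %>%
    dplyr::mutate(
      lat_bin = floor(.data$lateral_angle / bin_width) * bin_width,
      vert_bin = floor(.data$vertical_angle / bin_width) * bin_width
    ) %>%
    dplyr::count(.data$lat_bin, .data$vert_bin, name = "count")
  attr(out, "total_frames") <- nrow(f)
  attr(out, "bin_width") <- bin_width
  out
}

#' Gameplay performance by target position
#'
#' Mean accuracy (percent) and mean correct-trial RT per target position, with
#' RT outliers removed per player (pooled fences) before aggregation.
#' Positions with no surviving correct trial carry `rt_s = NA` rather than 0.
#'
#' @param trials Trial table (analysis trials are selected automatically).
#' @return Tibble: `target_lateral_angle`, `target_vertical_angle`,
#'   `n_trials`, `accuracy_pct`, `n_rt`, `rt_s`.
#' @export
position_maps <- function(trials) {
  t <- trials %>%
    dplyr::filter(.data$set_size %in% analysis_set_sizes()) %>%
    dplyr::mutate(correct = as.logical(.data$correct))
  if (nrow(t) == 0) {
    stop("position_maps(): no analysis trials.", call. = FALSE)
  }
  acc <- t %>%
    dplyr::group_by(.data$target_lateral_angle, .data$target_vertical_angle) %>%
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy_pct = mean(.data$correct) * 100,
      .groups = "drop"
    )
  rt <- t %>%
    dplyr::filter(.data$correct) %>%
    dplyr::group_by(.data$player_id) %>%
    dplyr::filter(rt_keep_mask(.data$rt_s)) %>%
    dplyr::group_by(.data$target_lateral_angle, .data$target_vertical_angle) %>%
    dplyr::summarise(
      n_rt = dplyr::n(),
      rt_s = mean(.data$rt_s),
      .groups = "drop"
    )
  out <- dplyr::left_join(
    acc, rt,
    by = c("target_lateral_angle", "target_vertical_angle")
  )
  out$n_rt[is.na(out$n_rt)] <- 0L
  out
}

#' Per-category summary table
#'
#' One row per occupied neglect category plus non-neglect and
#' minor-atypicality rows: n, percent (of neglect cases for category rows),
#' optional reference-test detection percent, and mean and SD of atypicality,
#' orientation, challenge and severity (SD absent for singleton rows).
#'
#' @param classification A `neglect_classification`.
#' @param reference Optional per-player reference-test results: a data frame
#'   with `player_id` and `pen_paper_neglect` (0/1), e.g. the cohort
#'   covariates.
#' @return A tibble with one row per category/summary class.
#' @export
category_summary <- function(classification, reference = NULL) {
  cls <- tibble::as_tibble(as.data.frame(classification)) %>%
    dplyr::filter(.data$group == "patient")
  if (!is.null(reference)) {
    cls <- dplyr::left_join(
      cls,
      dplyr::select(
        tibble::as_tibble(reference), "player_id", "pen_paper_neglect"
      ),
      by = "player_id"
    )
  } else {
    cls$pen_paper_neglect <- NA_real_
  }
  cls$rowclass <- ifelse(
    cls$label == "neglect", paste("Neglect", cls$category_code), cls$label
  )
  n_neglect <- sum(cls$label == "neglect")
  sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
  out <- cls %>%
    dplyr::group_by(.data$rowclass) %>%
    dplyr::summarise(
      n = dplyr::n(),
      pct_of_neglect = if (startsWith(.data$rowclass[1], "Neglect")) {
        100 * dplyr::n() / n_neglect
      } else {
        NA_real_
      },
      detected_pen_paper_pct = if (all(is.na(.data$pen_paper_neglect))) {
        NA_real_
      } else {
        100 * mean(.data$pen_paper_neglect, na.rm = TRUE)
      },
      atypicality_mean = mean(.data$atypicality),
      atypicality_sd = sd_or_na(.data$atypicality),
      orientation_mean = mean(.data$orientation),
      orientation_sd = sd_or_na(.data$orientation),
      challenge_mean = mean(.data$challenge),
      challenge_sd = sd_or_na(.data$challenge),
      severity_mean = mean(.data$severity),
      severity_sd = sd_or_na(.data$severity),
      .groups = "drop"
    ) %>%
    dplyr::arrange(
      !startsWith(.data$rowclass, "Neglect"),
      dplyr::desc(.data$n)
    )
  out
}

#' Write the numeric report tables for a classified cohort
#'
#' Writes `heatmap_patients.csv`, `heatmap_controls.csv`, `categories.csv`,
#' `position_map.csv` and, when frames are available,
#' `histogram_<source>.csv`.
#'
#' @param classification A `neglect_classification`.
#' @param cohort The [neglect_cohort()] it was computed from.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(classification, cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  hm <- heatmap_table(classification)
  p <- file.path(dir, "heatmap_patients.csv")
  readr::write_csv(hm$patients, p)
  paths <- c(paths, p)
  p <- file.path(dir, "heatmap_controls.csv")
  readr::write_csv(hm$controls, p)
  paths <- c(paths, p)
  p <- file.path(dir, "categories.csv")
  readr::write_csv(category_summary(classification, cohort$covariates), p)
  paths <- c(paths, p)
  p <- file.path(dir, "position_map.csv")
  readr::write_csv(position_maps(cohort$trials), p)
  paths <- c(paths, p)
  if (!is.null(cohort$frames)) {
    for (src in unique(cohort$frames$source)) {
      p <- file.path(dir, paste0("histogram_", src, ".csv"))
      readr::write_csv(raycast_histogram(cohort$frames, src), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
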