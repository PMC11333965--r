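#' Remove interquartile-fence reaction-time outliers
#'
#' Drops values strictly below `Q1 - 1.5 * IQR` or strictly above
#' `Q3 + 1.5 * IQR` of the input itself, with quartiles by linear
#' interpolation (the default type-7 convention). Values equal to a fence are
#' kept. Inputs with fewer than 4 values are returned unchanged with a
#' warning, because quartiles of so few points are not meaningful.
#'
#' @param rts Numeric vector of correct-trial reaction times in seconds.
#' @return The retained reaction times, in input order.
#' @export
#' @examples
#' filter_rt_outliers(c(1, 1, 1, 1, 10)) # drops the 10
filter_rt_outliers <- function(rts) {
  if (length(rts) == 0) {
    stop("filter_rt_outliers(): empty input.", call. = FALSE)
  }
  if (any(!is.finite(rts) | rts <= 0)) {
    stop("filter_rt_outliers(): reaction times must be finite and positive.", call. = FALSE)
  }
  if (length(rts) < 4) {
    warning("filter_rt_outliers(): fewer than 4 values; returned unchanged.", call. = FALSE)
    return(rts)
  }
  rts[rt_keep_mask(rts)]
}

# logical keep-mask version used for grouped trial filtering; same convention.
# The tiny relative epsilon keeps values that sit exactly on a fence when the
# fence itself is not exactly representable in floating point.
rt_keep_mask <- function(rts) {
  if (length(rts) < 4) {
    return(rep(TRUE, length(rts)))
  }
  q <- stats::quantile(rts, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  eps <- 1e-9 * (abs(q[1]) + abs(q[2]) + iqr)
  rts >= q[1] - 1.5 * iqr - eps & rts <= q[2] + 1.5 * iqr + eps
}

check_single_player <- function(trials, what) {
  ids <- unique(trials$player_id)
  if (length(ids) != 1) {
    stop(what, "(): expected trials from a single player, got ",
      length(ids), " players.",
      call. = FALSE
    )
  }
}

#' Hemispace accuracy contrast (right minus left)
#'
#' Percentage-point difference in target-detection accuracy between right- and
#' left-hemispace targets, pooled over the analysed set sizes (8, 16, 24).
#' Positive values mean better detection on the right, i.e. a rightward
#' orientation. Midline targets are excluded.
#'
#' @param trials One player's trial table (as in [neglect_cohort()]`$trials`).
#' @return Percentage points (`NA` if either hemispace has no analysis trial).
#' @export
hemispace_contrast_accuracy <- function(trials) {
  check_single_player(trials, "hemispace_contrast_accuracy")
  t <- dplyr::filter(
    trials, .data$set_size %in% analysis_set_sizes(),
    .data$target_hemispace %in% c("left", "right")
  )
  acc <- function(side) {
    x <- t$correct[t$target_hemispace == side]
    if (length(x) == 0) NA_real_ else mean(x) * 100
  }
  acc("right") - acc("left")
}

#' Hemispace reaction-time contrast (left minus right)
#'
#' Difference in mean correct-trial RT between left- and right-hemispace
#' targets, pooled over the analysed set sizes, after removing the player's
#' pooled RT outliers with [filter_rt_outliers()]. Positive values mean slower
#' detection on the left, i.e. a rightward orientation.
#'
#' @inheritParams hemispace_contrast_accuracy
#' @return Seconds (`NA` if a hemispace has no surviving correct trial).
#' @export
hemispace_contrast_rt <- function(trials) {
  check_single_player(trials, "hemispace_contrast_rt")
  t <- dplyr::filter(
    trials, .data$set_size %in% analysis_set_sizes(),
    .data$correct, .data$target_hemispace %in% c("left", "right")
  )
  if (nrow(t) == 0) {
    return(NA_real_)
  }
  t <- t[rt_keep_mask(t$rt_s), ]
  m <- function(side) {
    x <- t$rt_s[t$target_hemispace == side]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  m("left") - m("right")
}

#' Ordinary least-squares set-size slope
#'
#' Slope of a per-set-size summary value against set size. For the three
#' equally spaced analysed set sizes (8, 16, 24) this reduces to
#' `(value_24 - value_8) / 16`.
#'
#' @param set_sizes Numeric vector of set sizes.
#' @param values Summary values at those set sizes.
#' @return Per-item slope, or `NA` with fewer than 2 finite points.
#' @export
#' @examples
#' set_size_slope(c(8, 16, 24), c(50, 40, 30)) # -1.25 %/item
set_size_slope <- function(set_sizes, values) {
  ok <- is.finite(set_sizes) & is.finite(values)
  if (sum(ok) < 2) {
    return(NA_real_)
  }
  s <- set_sizes[ok]
  v <- values[ok]
  sum((s - mean(s)) * (v - mean(v))) / sum((s - mean(s))^2)
}

feature_metric_names <- function() {
  c(
    "accuracy_subtract", "rt_subtract", "headset_mean", "gaze_mean",
    "headset_slope", "gaze_slope", "accuracy_slope", "rt_slope"
  )
}
orientation_metric_names <- function() feature_metric_names()[1:6]
challenge_metric_names <- function() feature_metric_names()[7:8]

#' Extract the eight raw classifier features for every player
#'
#' Computes, per player: the hemispace accuracy contrast (percentage points,
#' right minus left) and RT contrast (seconds, left minus right, correct
#' trials only, pooled-outlier-filtered); per-set-size headset and gaze mean
#' lateral angles; and four set-size slopes (headset and gaze orientation in
#' degrees/item, accuracy in %/item, RT in s/item). Per-set-size RT means for
#' the RT slope are taken over correct trials after outlier filtering within
#' each game level; the two repetitions of a set size are pooled. Tutorial
#' trials (set size 2) and midline targets (for hemispace contrasts) are
#' excluded.
#'
#' @param cohort A [neglect_cohort()], or a trials tibble (then orientation
#'   features are `NA`).
#' @return A tibble with one row per player: `player_id`, `group`, the eight
#'   feature columns (`headset_mean`/`gaze_mean` expanded to `_8`, `_16`,
#'   `_24`), and pooled per-hemispace accuracies `acc_left`, `acc_right`
#'   (used for severity).
#' @export
extract_features <- function(cohort) {
  if (inherits(cohort, "neglect_cohort")) {
    trials <- cohort$trials
    orientation <- cohort$orientation
  } else {
    trials <- tibble::as_tibble(cohort)
    orientation <- NULL
  }
  players <- dplyr::distinct(trials, .data$player_id, .data$group)
  t <- dplyr::filter(trials, .data$set_size %in% analysis_set_sizes())
  if (nrow(t) == 0) {
    stop("extract_features(): no analysis trials (set sizes 8/16/24).", call. = FALSE)
  }

  sided <- dplyr::filter(t, .data$target_hemispace %in% c("left", "right"))

  acc_side <- sided %>%
    dplyr::group_by(.data$player_id, .data$target_hemispace) %>%
    dplyr::summarise(acc = mean(.data$correct) * 100, .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "target_hemispace", values_from = "acc",
      names_prefix = "acc_"
    )
  for (col in c("acc_left", "acc_right")) {
    if (!col %in% names(acc_side)) acc_side[[col]] <- NA_real_
  }
  acc_side$accuracy_subtract <- acc_side$acc_right - acc_side$acc_left

  rt_sub <- sided %>%
    dplyr::filter(.data$correct) %>%
    dplyr::group_by(.data$player_id) %>%
    dplyr::filter(rt_keep_mask(.data$rt_s)) %>%
    dplyr::group_by(.data$player_id, .data$target_hemispace) %>%
    dplyr::summarise(rt = mean(.data$rt_s), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "target_hemispace", values_from = "rt",
      names_prefix = "rt_"
    )
  for (col in c("rt_left", "rt_right")) {
    if (!col %in% names(rt_sub)) rt_sub[[col]] <- NA_real_
  }
  rt_sub$rt_subtract <- rt_sub$rt_left - rt_sub$rt_right
  rt_sub <- dplyr::select(rt_sub, "player_id", "rt_subtract")

  acc_by_size <- t %>%
    dplyr::group_by(.data$player_id, .data$set_size) %>%
    dplyr::summarise(acc = mean(.data$correct) * 100, .groups = "drop")
  acc_slope <- acc_by_size %>%
    dplyr::group_by(.data$player_id) %>%
    dplyr::summarise(
      accuracy_slope = set_size_slope(.data$set_size, .data$acc),
      .groups = "drop"
    )

  rt_by_size <- t %>%
    dplyr::filter(.data$correct) %>%
    dplyr::group_by(.data$player_id, .data$level_index) %>%
    dplyr::filter(rt_keep_mask(.data$rt_s)) %>%
    dplyr::group_by(.data$player_id, .data$set_size) %>%
    dplyr::summarise(rt = mean(.data$rt_s), .groups = "drop")
  rt_slope <- rt_by_size %>%
    dplyr::group_by(.data$player_id) %>%
    dplyr::summarise(
      rt_slope = set_size_slope(.data$set_size, .data$rt),
      .groups = "drop"
    )

  out <- players %>%
    dplyr::left_join(acc_side, by = "player_id") %>%
    dplyr::left_join(rt_sub, by = "player_id") %>%
    dplyr::left_join(acc_slope, by = "player_id") %>%
    dplyr::left_join(rt_slope, by = "player_id")

  if (!is.null(orientation) && nrow(orientation) > 0) {
    or <- orientation %>%
      dplyr::filter(.data$source %in% c("headset", "gaze")) %>%
      tidyr::pivot_wider(
        id_cols = "player_id",
        names_from = c("source", "set_size"),
        values_from = "mean_lateral_angle_deg",
        names_glue = "{source}_mean_{set_size}"
      )
    out <- dplyr::left_join(out, or, by = "player_id")
    for (src in c("headset", "gaze")) {
      cols <- paste0(src, "_mean_", analysis_set_sizes())
      for (col in cols) if (!col %in% names(out)) out[[col]] <- NA_real_
      vals <- as.matrix(out[, cols])
      out[[paste0(src, "_slope")]] <- apply(
        vals, 1, function(v) set_size_slope(analysis_set_sizes(), v)
      )
    }
  } else {
    for (src in c("headset", "gaze")) {
      for (col in c(paste0(src, "_mean_", analysis_set_sizes()), paste0(src, "_slope"))) {
        out[[col]] <- NA_real_
      }
    }
    warning("extract_features(): no orientation summaries; raycast features are NA.",
      call. = FALSE
    )
  }

  dplyr::select(
    out,
    "player_id", "group",
    "accuracy_subtract", "rt_subtract",
    dplyr::starts_with("headset_mean_"), dplyr::starts_with("gaze_mean_"),
    "headset_slope", "gaze_slope", "accuracy_slope", "rt_slope",
    "acc_left", "acc_right"
  )
}
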