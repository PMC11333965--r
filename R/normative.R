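#' Tukey fences of a metric
#'
#' First and third quartiles (linear interpolation, type 7), interquartile
#' range, and the 1.5 IQR outlier fences `lower = Q1 - 1.5 * IQR`,
#' `upper = Q3 + 1.5 * IQR`.
#'
#' @param values Numeric vector; at least 4 finite values are required (fences
#'   from fewer are refused).
#' @param metric Optional metric name used in error messages and output.
#' @return A one-row tibble: `metric`, `n`, `q1`, `q3`, `iqr`, `lower`,
#'   `upper`.
#' @export
tukey_fence <- function(values, metric = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    stop(
      "tukey_fence(): fewer than 4 finite values",
      if (!is.na(metric)) paste0(" for metric '", metric, "'"), ".",
      call. = FALSE
    )
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  tibble::tibble(
    metric = metric, n = length(values),
    q1 = q[1], q3 = q[2], iqr = iqr,
    lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr
  )
}

cutoff_metric_table <- function(features) {
  long <- list()
  for (m in c(
    "accuracy_subtract", "rt_subtract", "headset_slope", "gaze_slope",
    "accuracy_slope", "rt_slope"
  )) {
    long[[m]] <- tibble::tibble(
      player_id = features$player_id, group = features$group,
      metric = m, set_size = NA_integer_, value = features[[m]]
    )
  }
  for (src in c("headset_mean", "gaze_mean")) {
    for (s in analysis_set_sizes()) {
      col <- paste0(src, "_", s)
      long[[col]] <- tibble::tibble(
        player_id = features$player_id, group = features$group,
        metric = src, set_size = s, value = features[[col]]
      )
    }
  }
  dplyr::bind_rows(long)
}

#' Normative cut-offs from a labelled feature table
#'
#' Computes Tukey fences for every classifier metric twice: once from the
#' control cohort and once from the patient cohort. The per-set-size mean
#' lateral angle metrics (`headset_mean`, `gaze_mean`) get separate fences per
#' set size. A value is later called atypical only when it falls strictly
#' outside *both* cohorts' fences, so the control fences define normality
#' while the patient fences demand that the behaviour is unusual even among
#' patients.
#'
#' @param features Feature table from [extract_features()] (must contain both
#'   groups).
#' @param min_cohort Minimum players per cohort per metric (default 4).
#' @return A `neglect_cutoffs` tibble: `metric`, `set_size`, `cohort`, `n`,
#'   `q1`, `q3`, `iqr`, `lower`, `upper`.
#' @export
compute_cutoffs <- function(features, min_cohort = 4) {
  long <- cutoff_metric_table(features)
  fences <- long %>%
    dplyr::mutate(cohort = ifelse(.data$group == "control", "controls", "patients")) %>%
    dplyr::group_by(.data$metric, .data$set_size, .data$cohort) %>%
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE, type = 7),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE, type = 7),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      lower = .data$q1 - 1.5 * .data$iqr,
      upper = .data$q3 + 1.5 * .data$iqr
    )
  short <- dplyr::filter(fences, .data$n < min_cohort)
  if (nrow(short) > 0 || length(unique(fences$cohort)) < 2) {
    bad <- unique(paste0(
      short$metric,
      ifelse(is.na(short$set_size), "", paste0("@", short$set_size)),
      " (", short$cohort, ", n=", short$n, ")"
    ))
    stop(
      "compute_cutoffs(): insufficient cohort (need >= ", min_cohort,
      " per group) for: ",
      if (length(bad)) paste(bad, collapse = "; ") else "a whole cohort is absent",
      call. = FALSE
    )
  }
  structure(fences, class = c("neglect_cutoffs", class(fences)))
}

#' Is a value atypical under the two-cohort conjunction rule?
#'
#' `TRUE` only when the value lies strictly outside the control fences *and*
#' strictly outside the patient fences; boundary values are typical. Missing
#' values are typical with a warning (treating missingness as pathology would
#' fabricate atypicality).
#'
#' @param value Numeric value(s).
#' @param control_fence,patient_fence One-row fence tables with `lower` and
#'   `upper` columns (e.g. from [tukey_fence()]).
#' @return Logical vector.
#' @export
is_atypical <- function(value, control_fence, patient_fence) {
  if (any(is.na(value))) {
    warning("is_atypical(): missing value treated as typical.", call. = FALSE)
  }
  out_c <- value < control_fence$lower | value > control_fence$upper
  out_p <- value < patient_fence$lower | value > patient_fence$upper
  ifelse(is.na(value), FALSE, out_c & out_p)
}

#' Threshold raw features into directional and challenge flags
#'
#' Applies the conjunction atypicality rule to every metric of every player.
#' Orientation contrasts and slopes map to `sign(value)` when atypical, else
#' 0. The per-set-size mean metrics are flagged when atypical at one or more
#' set sizes; the flag direction is the sign of the atypical mean with the
#' largest fence exceedance (exceedance measured against the nearer of the two
#' cohorts' fences, i.e. the binding constraint); exact directional ties give
#' 0 with a warning. Challenge flags are one-sided: `accuracy_slope` is 1 only
#' when atypically *below* the lower fences (accuracy falling with set size),
#' `rt_slope` only when atypically *above* the upper fences (RT rising).
#'
#' @param features Feature table from [extract_features()].
#' @param cutoffs `neglect_cutoffs` from [compute_cutoffs()].
#' @return Tibble: `player_id` plus the eight integer flag columns
#'   (orientation flags in -1/0/+1, challenge flags in 0/1).
#' @export
flag_features <- function(features, cutoffs) {
  fence_of <- function(metric, cohort, set_size = NA_integer_) {
    f <- cutoffs[cutoffs$metric == metric & cutoffs$cohort == cohort &
      (is.na(set_size) & is.na(cutoffs$set_size) |
        !is.na(set_size) & !is.na(cutoffs$set_size) & cutoffs$set_size == set_size), ]
    if (nrow(f) != 1) {
      stop("flag_features(): no fence for metric '", metric, "'.", call. = FALSE)
    }
    f
  }
  missing_any <- FALSE

  flag_signed <- function(metric) {
    v <- features[[metric]]
    missing_any <<- missing_any || any(is.na(v))
    atyp <- suppressWarnings(
      is_atypical(v, fence_of(metric, "controls"), fence_of(metric, "patients"))
    )
    as.integer(ifelse(atyp, sign(v), 0L))
  }

  flag_mean <- function(src) {
    sizes <- analysis_set_sizes()
    vals <- sapply(sizes, function(s) features[[paste0(src, "_", s)]])
    vals <- matrix(vals, nrow = nrow(features))
    missing_any <<- missing_any || any(is.na(vals))
    exceed <- matrix(0, nrow(features), length(sizes))
    for (j in seq_along(sizes)) {
      fc <- fence_of(src, "controls", sizes[j])
      fp <- fence_of(src, "patients", sizes[j])
      v <- vals[, j]
      exc_c <- pmax(fc$lower - v, v - fc$upper, 0)
      exc_p <- pmax(fp$lower - v, v - fp$upper, 0)
      exc <- pmin(exc_c, exc_p) # must clear both fences
      exceed[, j] <- ifelse(is.na(exc), 0, exc)
    }
    out <- integer(nrow(features))
    tied <- FALSE
    for (i in seq_len(nrow(features))) {
      exc <- exceed[i, ]
      if (all(exc <= 0)) next
      best <- which(exc == max(exc))
      dirs <- unique(sign(vals[i, best]))
      if (length(dirs) > 1) {
        tied <- TRUE
        next
      }
      out[i] <- as.integer(dirs[1])
    }
    if (tied) {
      warning("flag_features(): directional tie in ", src, "; flagged 0.", call. = FALSE)
    }
    out
  }

  flag_challenge <- function(metric, side) {
    v <- features[[metric]]
    missing_any <<- missing_any || any(is.na(v))
    fc <- fence_of(metric, "controls")
    fp <- fence_of(metric, "patients")
    hit <- if (side == "lower") {
      v < fc$lower & v < fp$lower
    } else {
      v > fc$upper & v > fp$upper
    }
    as.integer(ifelse(is.na(v), FALSE, hit))
  }

  out <- tibble::tibble(
    player_id = features$player_id,
    accuracy_subtract = flag_signed("accuracy_subtract"),
    rt_subtract = flag_signed("rt_subtract"),
    headset_mean = flag_mean("headset_mean"),
    gaze_mean = flag_mean("gaze_mean"),
    headset_slope = flag_signed("headset_slope"),
    gaze_slope = flag_signed("gaze_slope"),
    accuracy_slope = flag_challenge("accuracy_slope", "lower"),
    rt_slope = flag_challenge("rt_slope", "upper")
  )
  if (missing_any) {
    warning("flag_features(): missing feature values were flagged 0 (typical).",
      call. = FALSE
    )
  }
  out
}

#' Export normative cut-offs to JSON
#'
#' Freezing the fences lets a normative model derived from one cohort score
#' new players without re-deriving quartiles.
#'
#' @param cutoffs `neglect_cutoffs` from [compute_cutoffs()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_cutoffs <- function(cutoffs, path) {
  jsonlite::write_json(
    list(
      schema = "neglect_cutoffs",
      version = 1L,
      fences = as.data.frame(cutoffs)
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Import normative cut-offs from JSON
#'
#' @param path JSON written by [write_cutoffs()].
#' @return A `neglect_cutoffs` tibble.
#' @export
read_cutoffs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "neglect_cutoffs")) {
    stop("read_cutoffs(): not a neglect_cutoffs JSON file.", call. = FALSE)
  }
  fences <- tibble::as_tibble(obj$fences)
  fences$set_size <- as.integer(fences$set_size)
  structure(fences, class = c("neglect_cutoffs", class(fences)))
}
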