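#' Summarise feature flags into atypicality, orientation, challenge, severity
#'
#' Atypicality counts the non-zero flags (0-8). Orientation is the algebraic
#' sum of the six directional flags (-6..+6), so opposite effects cancel.
#' Challenge is the sum of the two challenge flags (0-2). Severity is the
#' proportion of detection errors in the worse hemispace,
#' `1 - min(acc_left, acc_right) / 100`; it is descriptive and never used for
#' classification. The atypicality band is `none` (0), `minor` (<= 2),
#' `moderate` (<= 4) or `comprehensive` (> 4).
#'
#' @param flags Flag table from [flag_features()].
#' @param acc_left,acc_right Pooled per-hemispace accuracies in percent
#'   (columns of [extract_features()] output).
#' @return Tibble: `player_id`, `atypicality`, `orientation`, `challenge`,
#'   `severity`, `atypicality_band`.
#' @export
summarize_flags <- function(flags, acc_left = NA_real_, acc_right = NA_real_) {
  ori <- as.matrix(flags[, orientation_metric_names()])
  cha <- as.matrix(flags[, challenge_metric_names()])
  atyp <- rowSums(ori != 0) + rowSums(cha != 0)
  tibble::tibble(
    player_id = flags$player_id,
    atypicality = as.integer(atyp),
    orientation = as.integer(rowSums(ori)),
    challenge = as.integer(rowSums(cha)),
    severity = 1 - pmin(acc_left, acc_right) / 100,
    atypicality_band = dplyr::case_when(
      atyp == 0 ~ "none",
      atyp <= 2 ~ "minor",
      atyp <= 4 ~ "moderate",
      TRUE ~ "comprehensive"
    )
  )
}

#' Apply the rule-based neglect definition
#'
#' A player is labelled `neglect` when `|orientation| > 1`, or when both
#' `|orientation| > 0` and `challenge > 0`; `minor_atypicality` when some flag
#' is atypical but the neglect rule is not met; `non_neglect` when atypicality
#' is 0. The absolute orientation is used so that right-neglect cases
#' (negative orientation sums) satisfy the same rule as left-neglect cases.
#' The neglected side is opposite the orientation: rightward orientation
#' (`orientation > 0`) means left neglect.
#'
#' @param summary Tibble from [summarize_flags()] (columns `atypicality`,
#'   `orientation`, `challenge`).
#' @return The input with `label` (`neglect`/`minor_atypicality`/
#'   `non_neglect`) and `neglected_side` (`left`/`right`/`none`) added.
#' @export
classify <- function(summary) {
  dplyr::mutate(
    tibble::as_tibble(summary),
    label = dplyr::case_when(
      abs(.data$orientation) > 1 ~ "neglect",
      abs(.data$orientation) > 0 & .data$challenge > 0 ~ "neglect",
      .data$atypicality > 0 ~ "minor_atypicality",
      TRUE ~ "non_neglect"
    ),
    neglected_side = dplyr::case_when(
      .data$label != "neglect" ~ "none",
      .data$orientation > 0 ~ "left",
      .data$orientation < 0 ~ "right",
      TRUE ~ "none"
    )
  )
}

#' Assign multidimensional neglect category codes
#'
#' Codes cross three factors for neglect-labelled players: neglected side
#' (`L`/`R`), high orientation (`O` appended when `|orientation|` is at or
#' above the median absolute orientation over all neglect players, both sides
#' pooled) and high challenge (`C` appended when challenge is at or above the
#' median challenge over neglect players). The at-or-above-median convention
#' is what allows a cut-off to sit on a commonly attained value.
#'
#' @param summaries Classified summaries (from [classify()]) containing at
#'   least one `label == "neglect"` row.
#' @param orientation_cutoff,challenge_cutoff Optional explicit cut-offs; when
#'   `NULL` (default) the within-sample medians over neglect players are used.
#' @return The input with a `category_code` column (`NA` for non-neglect
#'   players).
#' @export
assign_categories <- function(summaries, orientation_cutoff = NULL,
                              challenge_cutoff = NULL) {
  neg <- summaries$label == "neglect"
  if (!any(neg)) {
    stop("assign_categories(): no neglect-labelled players.", call. = FALSE)
  }
  if (is.null(orientation_cutoff)) {
    orientation_cutoff <- stats::median(abs(summaries$orientation[neg]))
  }
  if (is.null(challenge_cutoff)) {
    challenge_cutoff <- stats::median(summaries$challenge[neg])
  }
  code <- ifelse(
    neg,
    paste0(
      ifelse(summaries$orientation > 0, "L", "R"),
      ifelse(abs(summaries$orientation) >= orientation_cutoff, "O", ""),
      ifelse(summaries$challenge >= challenge_cutoff, "C", "")
    ),
    NA_character_
  )
  out <- dplyr::mutate(summaries, category_code = code)
  attr(out, "category_cutoffs") <- c(
    orientation = orientation_cutoff, challenge = challenge_cutoff
  )
  out
}

#' Classify a whole cohort
#'
#' Runs the full pipeline: feature extraction, normative cut-offs (derived
#' from this cohort unless frozen cut-offs are supplied), conjunction
#' flagging, summary scores, the neglect rule, and multidimensional category
#' codes. Controls are scored and labelled like patients, but category codes
#' and the category median split are restricted to neglect-labelled patients.
#'
#' @param cohort A [neglect_cohort()] or a feature table from
#'   [extract_features()].
#' @param cutoffs Optional frozen `neglect_cutoffs`; default derives fences
#'   from this cohort.
#' @return A `neglect_classification` tibble: one row per player with group,
#'   the eight flags, the four summary scores, band, label, side and category
#'   code. The cut-offs and raw features travel as attributes `cutoffs` and
#'   `features`.
#' @export
classify_cohort <- function(cohort, cutoffs = NULL) {
  features <- if (inherits(cohort, "neglect_cohort")) {
    extract_features(cohort)
  } else {
    tibble::as_tibble(cohort)
  }
  if (is.null(cutoffs)) cutoffs <- compute_cutoffs(features)
  flags <- flag_features(features, cutoffs)
  summaries <- summarize_flags(flags, features$acc_left, features$acc_right)
  summaries <- classify(summaries)
  summaries$group <- features$group

  patients_neglect <- summaries$label == "neglect" & summaries$group == "patient"
  if (any(patients_neglect)) {
    pat <- summaries[summaries$group == "patient", ]
    pat <- assign_categories(pat)
    cuts <- attr(pat, "category_cutoffs")
    summaries <- dplyr::left_join(
      summaries,
      dplyr::select(pat, "player_id", "category_code"),
      by = "player_id"
    )
  } else {
    summaries$category_code <- NA_character_
    cuts <- c(orientation = NA_real_, challenge = NA_real_)
  }

  out <- flags %>%
    dplyr::left_join(summaries, by = "player_id") %>%
    dplyr::relocate("group", .after = "player_id")
  structure(
    out,
    cutoffs = cutoffs,
    features = features,
    category_cutoffs = cuts,
    class = c("neglect_classification", class(out))
  )
}

#' @export
print.neglect_classification <- function(x, ...) {
  cat("<neglect_classification> ", nrow(x), " players\n", sep = "")
  tab <- table(x$group, x$label)
  print(tab)
  cuts <- attr(x, "category_cutoffs")
  if (!all(is.na(cuts))) {
    cat(sprintf(
      "category cut-offs: |orientation| >= %.1f, challenge >= %.1f\n",
      cuts["orientation"], cuts["challenge"]
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-player classification results as a plain tibble
#'
#' @param x A `neglect_classification`.
#' @param ... Unused.
#' @method tidy neglect_classification
#' @export
tidy.neglect_classification <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row cohort summary of a classification
#'
#' Reports cohort sizes, patient label counts and prevalences (percent), and
#' mean atypicality by group.
#'
#' @param x A `neglect_classification`.
#' @param ... Unused.
#' @method glance neglect_classification
#' @export
glance.neglect_classification <- function(x, ...) {
  pat <- x[x$group == "patient", ]
  n_pat <- nrow(pat)
  tibble::tibble(
    n_players = nrow(x),
    n_controls = sum(x$group == "control"),
    n_patients = n_pat,
    n_neglect = sum(pat$label == "neglect"),
    n_minor = sum(pat$label == "minor_atypicality"),
    n_non_neglect = sum(pat$label == "non_neglect"),
    neglect_prevalence_pct = 100 * sum(pat$label == "neglect") / n_pat,
    minor_prevalence_pct = 100 * sum(pat$label == "minor_atypicality") / n_pat,
    non_neglect_prevalence_pct = 100 * sum(pat$label == "non_neglect") / n_pat,
    mean_atypicality_patients = mean(pat$atypicality),
    mean_atypicality_controls = mean(x$atypicality[x$group == "control"])
  )
}

#' Write a classification table to CSV
#'
#' @param classification A `neglect_classification`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(classification, path) {
  readr::write_csv(tidy(classification), path)
  invisible(path)
}
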