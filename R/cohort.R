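#' Convert an on-sphere raycast point to signed viewing angles
#'
#' Raycasts are points where the headset, gaze or controller forward vector
#' intersects a sphere of radius `r` centred on the calibrated head position.
#' The player faces `+z`, `+x` is to the player's right and `+y` is up, so the
#' lateral angle is negative for points left of the calibrated midline and
#' positive to the right.
#'
#' @param x,y,z Cartesian coordinates in metres of a point on the sphere.
#' @param r Sphere radius in metres (the game uses a fixed 2 m sphere).
#' @param tol Relative tolerance for the on-sphere check, as a fraction of `r`.
#'
#' @return A tibble with columns `lateral_angle` (degrees, in \[-180, 180\])
#'   and `vertical_angle` (degrees, in \[-90, 90\]).
#' @seealso [spherical_to_cartesian()] for the inverse mapping.
#' @export
#' @examples
#' cartesian_to_spherical(0, 0, 2)            # straight ahead -> (0, 0)
#' cartesian_to_spherical(-2, 0, 0)$lateral_angle  # 90 deg to the left -> -90
cartesian_to_spherical <- function(x, y, z, r = 2, tol = 1e-6) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("cartesian_to_spherical(): non-finite coordinates.", call. = FALSE)
  }
  if (!is.finite(r) || r <= 0) {
    stop("cartesian_to_spherical(): sphere radius must be positive.", call. = FALSE)
  }
  len <- sqrt(x^2 + y^2 + z^2)
  off <- abs(len - r) > tol * r
  if (any(off)) {
    stop(
      sprintf(
        "cartesian_to_spherical(): %d point(s) are off the sphere of radius %g (max deviation %.3g m).",
        sum(off), r, max(abs(len - r))
      ),
      call. = FALSE
    )
  }
  tibble::tibble(
    lateral_angle = atan2(x, z) * 180 / pi,
    vertical_angle = asin(pmin(1, pmax(-1, y / len))) * 180 / pi
  )
}

#' Convert signed viewing angles back to a Cartesian on-sphere point
#'
#' @param lateral_angle,vertical_angle Signed angles in degrees
#'   (negative lateral = left of midline).
#' @param r Sphere radius in metres.
#' @return A tibble with columns `x`, `y`, `z` in metres.
#' @export
spherical_to_cartesian <- function(lateral_angle, vertical_angle, r = 2) {
  lat <- lateral_angle * pi / 180
  vert <- vertical_angle * pi / 180
  tibble::tibble(
    x = r * cos(vert) * sin(lat),
    y = r * sin(vert),
    z = r * cos(vert) * cos(lat)
  )
}

#' Hemispace of a signed lateral angle
#'
#' @param lateral_angle Signed lateral angle(s) in degrees.
#' @return Character vector: `"left"` (< 0), `"right"` (> 0) or `"midline"`
#'   (exactly 0).
#' @export
hemispace_of <- function(lateral_angle) {
  if (any(!is.finite(lateral_angle))) {
    stop("hemispace_of(): lateral_angle must be finite.", call. = FALSE)
  }
  dplyr::case_when(
    lateral_angle < 0 ~ "left",
    lateral_angle > 0 ~ "right",
    TRUE ~ "midline"
  )
}

# analysed set sizes; 2 is the tutorial level and excluded from analysis
analysis_set_sizes <- function() c(8L, 16L, 24L)
all_set_sizes <- function() c(2L, 8L, 16L, 24L)

trials_schema <- c(
  "player_id", "group", "level_index", "half", "set_size",
  "target_lateral_angle", "target_vertical_angle", "correct", "rt_s"
)
orientation_schema <- c(
  "player_id", "source", "set_size", "mean_lateral_angle_deg", "n_frames"
)

#' Assemble and validate a gameplay cohort
#'
#' Bundles trial-level gameplay logs, per-level raycast orientation summaries
#' and optional clinical covariates into a validated cohort object. Tutorial
#' trials (set size 2) are retained but marked `analysis = FALSE` and excluded
#' from all downstream feature computations.
#'
#' @param trials Data frame of search trials with columns `player_id`, `group`
#'   (`"control"`/`"patient"`), `level_index` (1-8), `half` (1/2), `set_size`
#'   (2/8/16/24), `target_lateral_angle` and `target_vertical_angle` (degrees,
#'   signed), `correct` (0/1 or logical) and `rt_s` (seconds, > 0).
#' @param orientation Data frame of per-set-size mean lateral angles with
#'   columns `player_id`, `source` (`"headset"`/`"gaze"`/`"controller"`),
#'   `set_size`, `mean_lateral_angle_deg`, `n_frames`.
#' @param covariates Optional data frame of per-player clinical fields
#'   (`player_id`, `pen_paper_neglect` 0/1, plus any of age, sex, diagnosis,
#'   injury and FIM columns).
#' @param frames Optional data frame of per-frame raycast samples (columns
#'   `player_id`, `source`, `set_size`, and either `lateral_angle`/
#'   `vertical_angle` in degrees or `x`/`y`/`z` in metres on the 2 m sphere).
#'
#' @return An object of class `neglect_cohort`: a list of tibbles `trials`
#'   (with derived `target_hemispace` and `analysis` columns), `orientation`,
#'   `covariates` and `frames`.
#' @export
neglect_cohort <- function(trials, orientation, covariates = NULL, frames = NULL) {
  trials <- tibble::as_tibble(trials)
  orientation <- tibble::as_tibble(orientation)

  missing_tr <- setdiff(trials_schema, names(trials))
  missing_or <- setdiff(orientation_schema, names(orientation))
  if (length(missing_tr) || length(missing_or)) {
    stop(
      "neglect_cohort(): missing columns: ",
      paste(c(missing_tr, missing_or), collapse = ", "),
      call. = FALSE
    )
  }

  bad <- which(!trials$set_size %in% all_set_sizes())
  if (length(bad)) {
    stop(
      "neglect_cohort(): invalid set_size in trials rows ",
      paste(utils::head(bad, 10), collapse = ", "),
      " (allowed: 2, 8, 16, 24).",
      call. = FALSE
    )
  }
  bad <- which(!is.finite(trials$rt_s) | trials$rt_s <= 0)
  if (length(bad)) {
    stop(
      "neglect_cohort(): non-positive rt_s in trials rows ",
      paste(utils::head(bad, 10), collapse = ", "), ".",
      call. = FALSE
    )
  }
  if (!all(trials$group %in% c("control", "patient"))) {
    stop("neglect_cohort(): group must be 'control' or 'patient'.", call. = FALSE)
  }
  if (!all(trials$correct %in% c(0, 1, TRUE, FALSE))) {
    stop("neglect_cohort(): correct must be 0/1.", call. = FALSE)
  }
  grp <- dplyr::distinct(trials, .data$player_id, .data$group)
  if (anyDuplicated(grp$player_id)) {
    stop("neglect_cohort(): a player_id appears in more than one group.", call. = FALSE)
  }

  if (!all(orientation$source %in% c("headset", "gaze", "controller"))) {
    stop("neglect_cohort(): orientation source must be headset, gaze or controller.", call. = FALSE)
  }
  if (!all(orientation$set_size %in% analysis_set_sizes())) {
    stop("neglect_cohort(): orientation set_size must be 8, 16 or 24.", call. = FALSE)
  }
  if (any(orientation$n_frames < 1)) {
    stop("neglect_cohort(): orientation n_frames must be >= 1.", call. = FALSE)
  }
  key <- paste(orientation$player_id, orientation$source, orientation$set_size)
  if (anyDuplicated(key)) {
    stop(
      "neglect_cohort(): duplicate (player, source, set_size) orientation rows: ",
      paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
      call. = FALSE
    )
  }
  unknown <- setdiff(orientation$player_id, trials$player_id)
  if (length(unknown)) {
    stop(
      "neglect_cohort(): orientation rows for unknown players: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }

  trials <- trials %>%
    dplyr::mutate(
      correct = as.logical(.data$correct),
      set_size = as.integer(.data$set_size),
      target_hemispace = hemispace_of(.data$target_lateral_angle),
      analysis = .data$set_size %in% analysis_set_sizes()
    )

  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!"player_id" %in% names(covariates)) {
      stop("neglect_cohort(): covariates need a player_id column.", call. = FALSE)
    }
    if (anyDuplicated(covariates$player_id)) {
      stop("neglect_cohort(): duplicate player_id in covariates.", call. = FALSE)
    }
  }
  if (!is.null(frames)) {
    frames <- tibble::as_tibble(frames)
    if (!all(c("lateral_angle", "vertical_angle") %in% names(frames))) {
      if (all(c("x", "y", "z") %in% names(frames))) {
        ang <- cartesian_to_spherical(frames$x, frames$y, frames$z)
        frames$lateral_angle <- ang$lateral_angle
        frames$vertical_angle <- ang$vertical_angle
      } else {
        stop("neglect_cohort(): frames need lateral/vertical angles or x/y/z.", call. = FALSE)
      }
    }
  }

  structure(
    list(
      trials = trials,
      orientation = orientation,
      covariates = covariates,
      frames = frames
    ),
    class = "neglect_cohort"
  )
}

#' @export
print.neglect_cohort <- function(x, ...) {
  grp <- dplyr::distinct(x$trials, .data$player_id, .data$group)
  cat(
    "<neglect_cohort> ", nrow(grp), " players (",
    sum(grp$group == "control"), " controls, ",
    sum(grp$group == "patient"), " patients); ",
    nrow(x$trials), " trials (", sum(x$trials$analysis), " analysis), ",
    nrow(x$orientation), " orientation summaries",
    if (!is.null(x$frames)) paste0(", ", nrow(x$frames), " raycast frames") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a cohort from CSV tables
#'
#' @param trials,orientation,covariates,frames Paths to CSV files following
#'   the column schemas documented in [neglect_cohort()] (covariates and
#'   frames optional).
#' @return A validated [neglect_cohort()] object.
#' @export
read_cohort <- function(trials, orientation, covariates = NULL, frames = NULL) {
  read1 <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  neglect_cohort(
    trials = read1(trials),
    orientation = read1(orientation),
    covariates = if (!is.null(covariates)) read1(covariates),
    frames = if (!is.null(frames)) read1(frames)
  )
}

#' Write a cohort to CSV tables
#'
#' Writes `trials.csv`, `orientation.csv` and, when present, `covariates.csv`
#' and `frames.csv` into `dir`.
#'
#' @param cohort A [neglect_cohort()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "neglect_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  tr <- dplyr::select(cohort$trials, dplyr::all_of(trials_schema))
  tr$correct <- as.integer(tr$correct)
  p <- file.path(dir, "trials.csv")
  readr::write_csv(tr, p)
  paths <- c(paths, p)
  p <- file.path(dir, "orientation.csv")
  readr::write_csv(cohort$orientation, p)
  paths <- c(paths, p)
  if (!is.null(cohort$covariates)) {
    p <- file.path(dir, "covariates.csv")
    readr::write_csv(cohort$covariates, p)
    paths <- c(paths, p)
  }
  if (!is.null(cohort$frames)) {
    p <- file.path(dir, "frames.csv")
    readr::write_csv(cohort$frames, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Mirror a cohort left-to-right
#'
#' Negates every lateral angle (targets, orientation summaries, raycast
#' frames), swapping the left and right hemispaces. Useful for symmetry
#' checks: orientation features and flags of the mirrored cohort are the
#' negation of the originals, and neglect sides swap.
#'
#' @param cohort A [neglect_cohort()] object.
#' @return The mirrored `neglect_cohort`.
#' @export
mirror_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "neglect_cohort"))
  cohort$trials <- cohort$trials %>%
    dplyr::mutate(
      target_lateral_angle = -.data$target_lateral_angle,
      target_hemispace = hemispace_of(.data$target_lateral_angle)
    )
  cohort$orientation$mean_lateral_angle_deg <- -cohort$orientation$mean_lateral_angle_deg
  if (!is.null(cohort$frames)) {
    cohort$frames$lateral_angle <- -cohort$frames$lateral_angle
    if ("x" %in% names(cohort$frames)) cohort$frames$x <- -cohort$frames$x
  }
  cohort
}
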