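#' Define a gameplay simulation profile
#'
#' A profile parameterises one simulated player: baseline accuracy and
#' reaction time, hemispace-specific deficits, set-size slopes, lateral
#' orientation bias of the headset/gaze raycasts, and noise levels. The
#' defaults describe an unimpaired adult performing serial visual search
#' (accuracy near ceiling, ~30 ms/item RT slope, no lateral bias).
#'
#' @param accuracy_base Baseline probability of selecting the target.
#' @param accuracy_deficit_left,accuracy_deficit_right Probability decrement
#'   applied to targets in the named hemispace.
#' @param accuracy_slope_per_item Probability change per array element; a
#'   single value, or a named vector `c(left = , right = )` for
#'   hemispace-specific slopes.
#' @param rt_base Baseline reaction time in seconds (> 0).
#' @param rt_slope_per_item RT increase per array element (s/item).
#' @param rt_penalty_left,rt_penalty_right Seconds added to RTs for targets in
#'   the named (neglected) hemispace.
#' @param lateral_bias_mean Mean lateral orientation of headset and gaze
#'   raycasts, degrees (positive = rightward).
#' @param lateral_bias_slope Additional lateral bias per array element
#'   (degrees/item).
#' @param gaze_bias_extra Extra lateral bias applied to gaze only (degrees);
#'   lets gaze-specific anomalies be simulated.
#' @param angle_noise_sd SD of the per-set-size mean lateral angle (degrees).
#' @param rt_noise_log_sd SD of multiplicative log-normal RT noise
#'   (log-seconds).
#' @param lapse_rate Probability that a trial is failed regardless of the
#'   target's hemispace (attentional lapse).
#' @param trials_per_level Trials per game level (split evenly between left
#'   and right target hemispaces).
#' @param n_frames_per_level Raycast frames to simulate per (source,
#'   set size); 0 disables frame-level output.
#' @param pen_paper_rate Probability that the simulated pen-and-paper
#'   reference battery flags this player as having neglect.
#' @param minor_random If `TRUE`, the player receives one mild anomaly on a
#'   single randomly chosen dimension (gaze bias, unilateral accuracy deficit,
#'   RT hemispace penalty, or accuracy set-size slope) instead of the fixed
#'   effects above; used by the `minor` preset so that mild cases spread
#'   across features as they do clinically.
#'
#' @return A list of class `sim_profile`.
#' @export
sim_profile <- function(accuracy_base = 0.95,
                        accuracy_deficit_left = 0,
                        accuracy_deficit_right = 0,
                        accuracy_slope_per_item = -0.001,
                        rt_base = 1.0,
                        rt_slope_per_item = 0.03,
                        rt_penalty_left = 0,
                        rt_penalty_right = 0,
                        lateral_bias_mean = 0,
                        lateral_bias_slope = 0,
                        gaze_bias_extra = 0,
                        angle_noise_sd = 2,
                        rt_noise_log_sd = 0.25,
                        lapse_rate = 0.01,
                        trials_per_level = 40,
                        n_frames_per_level = 0,
                        pen_paper_rate = 0.02,
                        minor_random = FALSE) {
  if (!is.finite(rt_base) || rt_base <= 0) {
    stop("sim_profile(): rt_base must be > 0.", call. = FALSE)
  }
  if (!is.finite(trials_per_level) || trials_per_level < 1) {
    stop("sim_profile(): trials_per_level must be >= 1.", call. = FALSE)
  }
  slope <- accuracy_slope_per_item
  if (length(slope) == 1) slope <- c(left = unname(slope), right = unname(slope))
  if (!all(c("left", "right") %in% names(slope))) {
    stop("sim_profile(): accuracy_slope_per_item must be scalar or named c(left=, right=).",
      call. = FALSE
    )
  }
  clip01 <- function(p) pmin(1, pmax(0, p))
  structure(
    list(
      accuracy_base = clip01(accuracy_base),
      accuracy_deficit_left = clip01(accuracy_deficit_left),
      accuracy_deficit_right = clip01(accuracy_deficit_right),
      accuracy_slope_per_item = slope,
      rt_base = rt_base,
      rt_slope_per_item = rt_slope_per_item,
      rt_penalty_left = rt_penalty_left,
      rt_penalty_right = rt_penalty_right,
      lateral_bias_mean = lateral_bias_mean,
      lateral_bias_slope = lateral_bias_slope,
      gaze_bias_extra = gaze_bias_extra,
      angle_noise_sd = angle_noise_sd,
      rt_noise_log_sd = rt_noise_log_sd,
      lapse_rate = clip01(lapse_rate),
      trials_per_level = as.integer(trials_per_level),
      n_frames_per_level = as.integer(n_frames_per_level),
      pen_paper_rate = clip01(pen_paper_rate),
      minor_random = isTRUE(minor_random)
    ),
    class = "sim_profile"
  )
}

#' Library of simulation presets
#'
#' Named presets covering an unimpaired control, a typical (non-neglect)
#' brain-injury patient, a mild single-feature anomaly (`minor`), and the six
#' observed multidimensional neglect categories: left/right neglect with or
#' without strong orientation (`O`) and challenge (`C`) components. Effect
#' sizes are fixed: raycast biases of ~30 degrees and hemispace accuracy
#' deficits of ~30 percentage points for strong-orientation presets, RT
#' hemispace penalties of 0.5-0.7 s, and steepened set-size slopes for
#' challenge presets.
#'
#' @return A named list of [sim_profile()] objects
#'   (`control`, `typical`, `minor`, `loc`, `lo`, `lc`, `l`, `ro`, `rc`).
#' @export
profile_library <- function() {
  patient_base <- list(
    accuracy_base = 0.93, rt_base = 1.3, rt_slope_per_item = 0.035,
    angle_noise_sd = 2, lapse_rate = 0.015, pen_paper_rate = 0.02
  )
  pb <- function(...) do.call(sim_profile, utils::modifyList(patient_base, list(...)))
  list(
    control = sim_profile(),
    typical = pb(),
    minor   = pb(minor_random = TRUE, pen_paper_rate = 0.05),
    loc = pb(
      lateral_bias_mean = 30, lateral_bias_slope = 0.4,
      accuracy_deficit_left = 0.35, rt_penalty_left = 0.7,
      accuracy_slope_per_item = c(left = -0.018, right = -0.008),
      rt_slope_per_item = 0.09, pen_paper_rate = 1.0
    ),
    lo = pb(
      lateral_bias_mean = 30, lateral_bias_slope = 0.4,
      accuracy_deficit_left = 0.30, rt_penalty_left = 0.6,
      pen_paper_rate = 1.0
    ),
    lc = pb(
      accuracy_deficit_left = 0.15, rt_penalty_left = 0.5,
      accuracy_slope_per_item = c(left = -0.016, right = -0.008),
      rt_slope_per_item = 0.09, pen_paper_rate = 0.0
    ),
    l = pb(
      accuracy_deficit_left = 0.25, rt_penalty_left = 0.5,
      pen_paper_rate = 0.0
    ),
    ro = pb(
      lateral_bias_mean = -30, lateral_bias_slope = -0.4,
      accuracy_deficit_right = 0.30, rt_penalty_right = 0.6,
      pen_paper_rate = 0.0
    ),
    rc = pb(
      accuracy_deficit_right = 0.15, rt_penalty_right = 0.5,
      accuracy_slope_per_item = c(left = -0.008, right = -0.016),
      rt_slope_per_item = 0.09, pen_paper_rate = 0.33
    )
  )
}

# Level schedule: 8 levels, set sizes 2/8/16/24 twice, reverse-ordered in the
# second half; set size 2 is the tutorial.
level_schedule <- function() {
  tibble::tibble(
    level_index = 1:8,
    half = rep(1:2, each = 4L),
    set_size = c(2L, 8L, 16L, 24L, 24L, 16L, 8L, 2L)
  )
}

# deterministic master-seed -> per-player seed (documented multiplicative hash,
# kept below 2^31 so it is a valid R integer seed)
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 16807) %% 2147483647) + 1L
}

# resolve the 'minor' preset into one mild concrete anomaly (seed-determined)
resolve_minor <- function(profile) {
  if (!profile$minor_random) {
    return(profile)
  }
  variant <- sample(c("gaze", "accuracy", "rt", "acc_slope"), 1)
  side <- sample(c(-1, 1), 1)
  profile$minor_random <- FALSE
  switch(variant,
    gaze = {
      profile$gaze_bias_extra <- 11 * side
    },
    accuracy = {
      if (side < 0) {
        profile$accuracy_deficit_right <- 0.12
      } else {
        profile$accuracy_deficit_left <- 0.12
      }
    },
    rt = {
      if (side < 0) profile$rt_penalty_right <- 0.3 else profile$rt_penalty_left <- 0.3
    },
    acc_slope = {
      profile$accuracy_slope_per_item <- c(left = -0.012, right = -0.012)
    }
  )
  profile
}

simulate_covariates <- function(player_id, group, preset, pen_paper_rate) {
  is_pat <- group == "patient"
  left_neglect <- preset %in% c("loc", "lo", "lc", "l")
  right_neglect <- preset %in% c("ro", "rc")
  hemi_prob <-
    if (left_neglect) {
      c(left = 0.1, right = 0.8, bilateral = 0.1)
    } else if (right_neglect) {
      c(left = 0.75, right = 0.15, bilateral = 0.1)
    } else {
      c(left = 0.40, right = 0.38, bilateral = 0.22)
    }
  neglectish <- left_neglect || right_neglect
  tibble::tibble(
    player_id = player_id,
    pen_paper_neglect = as.integer(stats::runif(1) < pen_paper_rate),
    age = round(pmin(95, pmax(
      18,
      stats::rnorm(1, if (is_pat) 65.5 else 40.5, if (is_pat) 17.3 else 12.5)
    ))),
    sex = sample(c("male", "female"), 1, prob = if (is_pat) c(.71, .29) else c(.37, .63)),
    days_since_injury = if (is_pat) round(stats::rlnorm(1, log(30), 0.8)) else NA_real_,
    days_in_rehab = if (is_pat) round(stats::rlnorm(1, log(12), 0.8)) else NA_real_,
    fim_motor = if (is_pat) {
      round(pmin(7, pmax(1, stats::rnorm(1, if (neglectish) 2.4 else 3.8, 1.3))), 1)
    } else {
      NA_real_
    },
    fim_cognition = if (is_pat) {
      round(pmin(7, pmax(1, stats::rnorm(1, if (neglectish) 4.4 else 5.3, 1.2))), 1)
    } else {
      NA_real_
    },
    diagnosis = if (is_pat) {
      sample(c("stroke", "abi", "tbi"), 1, prob = c(.745, .157, .098))
    } else {
      NA_character_
    },
    hemisphere = if (is_pat) {
      sample(names(hemi_prob), 1, prob = hemi_prob)
    } else {
      NA_character_
    },
    preset = preset
  )
}

#' Simulate one player's gameplay session
#'
#' Generates the full eight-level game (two repetitions of set sizes 2, 8, 16
#' and 24; the second half reverse-ordered; set size 2 marked as tutorial),
#' with targets balanced between the left and right hemispaces within each
#' level. Per trial, correctness is Bernoulli with probability
#' `clip(accuracy_base + slope * set_size - hemispace deficit) * (1 - lapse)`,
#' and RT is log-normal around
#' `rt_base + rt_slope_per_item * set_size + hemispace penalty`. Headset and
#' gaze per-set-size mean lateral angles are normal around
#' `lateral_bias_mean + lateral_bias_slope * set_size` with SD
#' `angle_noise_sd`.
#'
#' @param profile A [sim_profile()].
#' @param group `"control"` or `"patient"`.
#' @param seed Integer seed; identical (profile, seed) pairs give identical
#'   sessions.
#' @param player_id Player identifier.
#' @param preset Optional preset name recorded in the covariates.
#' @return A one-player [neglect_cohort()].
#' @export
simulate_player <- function(profile, group = c("patient", "control"), seed = 1,
                            player_id = "P01", preset = NA_character_) {
  stopifnot(inherits(profile, "sim_profile"))
  group <- match.arg(group)
  if (profile$trials_per_level < 1) {
    stop("simulate_player(): trials_per_level must be >= 1.", call. = FALSE)
  }
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  profile <- resolve_minor(profile)

  sched <- level_schedule()
  n_lvl <- profile$trials_per_level
  n_left <- n_lvl %/% 2
  trials <- sched[rep(seq_len(nrow(sched)), each = n_lvl), ]
  trials$side <- rep(
    c(rep("left", n_left), rep("right", n_lvl - n_left)),
    times = nrow(sched)
  )
  n <- nrow(trials)
  # target grid mirrors the spherical stimulus layout: four eccentricities,
  # three elevations
  ecc <- sample(c(12.5, 25, 37.5, 50), n, replace = TRUE)
  trials$target_lateral_angle <- ifelse(trials$side == "left", -ecc, ecc)
  trials$target_vertical_angle <- sample(c(-15, 0, 15), n, replace = TRUE)

  slope <- profile$accuracy_slope_per_item
  deficit <- ifelse(trials$side == "left",
    profile$accuracy_deficit_left, profile$accuracy_deficit_right
  )
  p <- profile$accuracy_base +
    unname(slope[trials$side]) * trials$set_size - deficit
  p <- pmin(1, pmax(0, p)) * (1 - profile$lapse_rate)
  correct <- stats::runif(n) < p

  rt_mu <- profile$rt_base + profile$rt_slope_per_item * trials$set_size +
    ifelse(trials$side == "left", profile$rt_penalty_left, profile$rt_penalty_right)
  rt_mu <- pmax(rt_mu, 0.05)
  rt <- rt_mu * exp(stats::rnorm(n, 0, profile$rt_noise_log_sd))

  trials_tbl <- tibble::tibble(
    player_id = player_id,
    group = group,
    level_index = trials$level_index,
    half = trials$half,
    set_size = trials$set_size,
    target_lateral_angle = trials$target_lateral_angle,
    target_vertical_angle = trials$target_vertical_angle,
    correct = as.integer(correct),
    rt_s = rt
  )

  sizes <- analysis_set_sizes()
  orient <- tidyr::expand_grid(source = c("headset", "gaze"), set_size = sizes) %>%
    dplyr::mutate(
      player_id = player_id,
      mean_lateral_angle_deg =
        profile$lateral_bias_mean +
          ifelse(.data$source == "gaze", profile$gaze_bias_extra, 0) +
          profile$lateral_bias_slope * .data$set_size +
          stats::rnorm(dplyr::n(), 0, profile$angle_noise_sd),
      n_frames = 60L * .data$set_size
    ) %>%
    dplyr::select(dplyr::all_of(orientation_schema))

  frames <- NULL
  if (profile$n_frames_per_level > 0) {
    nf <- profile$n_frames_per_level
    grid <- tidyr::expand_grid(
      source = c("headset", "gaze", "controller"),
      set_size = sizes
    )
    frames <- grid[rep(seq_len(nrow(grid)), each = nf), ]
    mu <- profile$lateral_bias_mean +
      ifelse(frames$source == "gaze", profile$gaze_bias_extra, 0) +
      profile$lateral_bias_slope * frames$set_size
    # wide per-frame spread: attention roams the scene around the bias centre
    frames$lateral_angle <- pmin(
      179.5, pmax(-179.5, stats::rnorm(nrow(frames), mu, 20))
    )
    frames$vertical_angle <- pmin(
      89, pmax(-89, stats::rnorm(nrow(frames), -5, 10))
    )
    frames <- dplyr::mutate(frames, player_id = player_id, .before = 1)
  }

  covariates <- simulate_covariates(
    player_id, group,
    preset = if (is.na(preset)) if (group == "control") "control" else "typical" else preset,
    pen_paper_rate = profile$pen_paper_rate
  )

  neglect_cohort(trials_tbl, orient, covariates = covariates, frames = frames)
}

#' Simulate a full control + patient cohort
#'
#' Controls use the `control` preset; patients are allocated across
#' `patient_mix` presets by largest-remainder apportionment of the weights, so
#' the default mix reproduces a realistic inpatient composition: mostly
#' typical (non-neglect) patients, some mild single-feature anomalies, and a
#' minority of neglect presets of both sides. Per-player seeds are derived
#' deterministically from `seed`, so cohorts are reproducible independent of
#' iteration order.
#'
#' @param n_controls,n_patients Cohort sizes (each >= 1).
#' @param patient_mix Named numeric weights over presets from
#'   [profile_library()]. Default mirrors a 51-patient inpatient sample:
#'   `c(typical = 29, minor = 9, loc = 5, lo = 1, lc = 2, l = 1, ro = 1,
#'   rc = 3)`.
#' @param seed Master integer seed.
#' @param profiles Optional preset library (defaults to [profile_library()]).
#' @param n_frames_per_level Raycast frames per (source, set size) per player;
#'   0 disables frame output.
#' @return A [neglect_cohort()] with `n_controls + n_patients` players.
#' @export
simulate_cohort <- function(n_controls = 30, n_patients = 51,
                            patient_mix = NULL, seed = 1,
                            profiles = profile_library(),
                            n_frames_per_level = 0) {
  if (n_controls < 1 || n_patients < 1) {
    stop("simulate_cohort(): need at least one control and one patient.", call. = FALSE)
  }
  if (is.null(patient_mix)) {
    patient_mix <- c(
      typical = 29, minor = 9, loc = 5, lo = 1, lc = 2, l = 1, ro = 1, rc = 3
    )
  }
  patient_mix <- patient_mix[patient_mix > 0]
  if (!length(patient_mix) || any(patient_mix < 0) || sum(patient_mix) <= 0) {
    stop("simulate_cohort(): patient_mix must have nonnegative weights summing > 0.",
      call. = FALSE
    )
  }
  unknown <- setdiff(names(patient_mix), names(profiles))
  if (length(unknown)) {
    stop(
      "simulate_cohort(): unknown presets in patient_mix: ",
      paste(unknown, collapse = ", "), call. = FALSE
    )
  }

  # largest-remainder apportionment of n_patients across presets
  quota <- n_patients * patient_mix / sum(patient_mix)
  counts <- floor(quota)
  rem <- n_patients - sum(counts)
  if (rem > 0) {
    order_frac <- order(quota - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  patient_presets <- rep(names(counts), counts)

  set_frames <- function(pr) {
    pr$n_frames_per_level <- as.integer(n_frames_per_level)
    pr
  }
  id_width <- max(2, nchar(max(n_controls, n_patients)))
  sessions <- c(
    purrr::map(seq_len(n_controls), function(i) {
      simulate_player(
        set_frames(profiles$control),
        group = "control",
        seed = derive_seed(seed, i),
        player_id = sprintf("C%0*d", id_width, i),
        preset = "control"
      )
    }),
    purrr::map(seq_len(n_patients), function(i) {
      simulate_player(
        set_frames(profiles[[patient_presets[i]]]),
        group = "patient",
        seed = derive_seed(seed, n_controls + i),
        player_id = sprintf("P%0*d", id_width, i),
        preset = patient_presets[i]
      )
    })
  )

  frames <- purrr::map(sessions, "frames")
  frames <- if (all(purrr::map_lgl(frames, is.null))) NULL else dplyr::bind_rows(frames)
  neglect_cohort(
    trials = dplyr::bind_rows(purrr::map(sessions, "trials")),
    orientation = dplyr::bind_rows(purrr::map(sessions, "orientation")),
    covariates = dplyr::bind_rows(purrr::map(sessions, "covariates")),
    frames = frames
  )
}
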