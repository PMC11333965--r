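# Shared fixtures, all built in code.

# Minimal trial row builder
trial_row <- function(player_id = "P01", group = "patient", level_index = 2L,
                      half = 1L, set_size = 8L, lat = 25, vert = 0,
                      correct = 1L, rt = 1.0) {
  tibble::tibble(
    player_id = player_id, group = group, level_index = level_index,
    half = half, set_size = set_size, target_lateral_angle = lat,
    target_vertical_angle = vert, correct = correct, rt_s = rt
  )
}

# One-player 12-trial session with hand-computable features:
#   acc left 4/6, right 5/6; pooled correct RTs keep everything;
#   accuracy by set size 100/75/50 %; per-level RT means 1.0/1.3/1.7 s;
#   headset means (2,4,6) deg, gaze means (-1,-2,-3) deg.
fixture_session <- function(player_id = "P01", group = "patient") {
  rows <- list(
    trial_row(player_id, group, 2L, 1L, 8L, -25, 0, 1L, 1.0),
    trial_row(player_id, group, 2L, 1L, 8L, -25, 15, 1L, 1.2),
    trial_row(player_id, group, 2L, 1L, 8L, 25, 0, 1L, 0.8),
    trial_row(player_id, group, 2L, 1L, 8L, 25, -15, 1L, 1.0),
    trial_row(player_id, group, 3L, 1L, 16L, -37.5, 0, 1L, 1.5),
    trial_row(player_id, group, 3L, 1L, 16L, -37.5, 0, 0L, 2.0),
    trial_row(player_id, group, 3L, 1L, 16L, 37.5, 0, 1L, 1.1),
    trial_row(player_id, group, 3L, 1L, 16L, 37.5, 15, 1L, 1.3),
    trial_row(player_id, group, 4L, 1L, 24L, -50, 0, 0L, 3.0),
    trial_row(player_id, group, 4L, 1L, 24L, -50, 0, 1L, 2.0),
    trial_row(player_id, group, 4L, 1L, 24L, 50, 0, 1L, 1.4),
    trial_row(player_id, group, 4L, 1L, 24L, 50, 0, 0L, 2.2)
  )
  orientation <- tibble::tibble(
    player_id = player_id,
    source = rep(c("headset", "gaze"), each = 3),
    set_size = rep(c(8L, 16L, 24L), 2),
    mean_lateral_angle_deg = c(2, 4, 6, -1, -2, -3),
    n_frames = 100L
  )
  neglect_cohort(dplyr::bind_rows(rows), orientation)
}

# Deterministic zero-noise profile: every trial correct, exact RTs and angles
noiseless_profile <- function(...) {
  sim_profile(
    accuracy_base = 1, accuracy_slope_per_item = 0, rt_slope_per_item = 0.02,
    angle_noise_sd = 0, rt_noise_log_sd = 0, lapse_rate = 0,
    trials_per_level = 8, ...
  )
}

# Small mixed cohort for recovery-style tests
recovery_mix <- function() {
  c(typical = 9, minor = 2, loc = 1, lo = 1, ro = 1, lc = 1, rc = 1)
}

small_cohort <- function(seed = 1) {
  simulate_cohort(
    n_controls = 10, n_patients = 16,
    patient_mix = recovery_mix(), seed = seed
  )
}

# Labels realising a 3x3 cross-tabulation with rows (7,1,1),(6,28,8),(0,0,0):
# binary reference vs three-class labels for 51 patients.
reference_study_labels <- function() {
  truth <- c(
    rep("neglect", 13), rep("non_neglect", 29), rep("minor_atypicality", 9)
  )
  predictor <- c(
    rep("neglect", 7), rep("non_neglect", 6), # truth neglect
    rep("neglect", 1), rep("non_neglect", 28), # truth non-neglect
    rep("neglect", 1), rep("non_neglect", 8) # truth minor
  )
  list(truth = truth, predictor = predictor)
}
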