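#' Simulation configuration for a synthetic assembly cohort
#'
#' Builds the configuration object consumed by the cohort simulator. Defaults
#' reproduce the study conditions of the motivating manual-assembly experiment:
#' three informational assistance systems (AR glasses, tablet, paper) as a
#' between-subject factor and four assembly models `M1`--`M4` of increasing
#' complexity as the within-subject factor. Per-cell heart-rate and
#' pupil-diameter means, mean segment durations, perceived-complexity means and
#' area-of-interest (AOI) dwell-share targets all default to the calibration
#' tables shipped with the package (see [calibration_tables()]).
#'
#' @param n_participants Number of participants to simulate.
#' @param systems Character vector of assistance-system labels.
#' @param system_weights Assignment probabilities for `systems`; participants
#'   are assigned round-robin when weights are equal, otherwise by weighted
#'   sampling.
#' @param model_mean_duration_s Named numeric, mean assembly duration (s) per
#'   model `M1`--`M4`.
#' @param duration_cv Coefficient of variation of assembly durations.
#' @param hr_mean_bpm `systems x models` matrix of mean heart rate (bpm).
#' @param hr_between_sd_bpm SD (bpm) of the stable per-participant heart-rate
#'   offset (between-person variability).
#' @param rr_phi Lag-1 autocorrelation of the RR fluctuation process,
#'   in `[0, 1)`.
#' @param rr_innovation_sd_ms Innovation SD (ms) of the AR(1) RR fluctuations.
#'   The default is calibrated so that RMSSD of a clean simulated series is
#'   close to the 20--34 ms range typical of the task:
#'   `RMSSD = rr_innovation_sd_ms * sqrt(2 / (1 + rr_phi))`.
#' @param artifact_rate Per-beat probability of injecting a beat artifact
#'   (ectopic displacement or missed beat), logged as ground truth.
#' @param ecg_noise_sd White-noise SD of the rendered ECG trace (template
#'   amplitude is 1).
#' @param pupil_mean_mm `systems x models` matrix of mean pupil diameter (mm).
#' @param pupil_between_sd_mm SD (mm) of the per-participant pupil offset.
#' @param pupil_drift_sd_mm SD of the slow common (binocular) pupil
#'   fluctuation.
#' @param pupil_eye_noise_sd_mm SD of independent per-eye measurement noise.
#' @param blink_rate_hz Rate of blink gaps (runs of invalid samples) per
#'   second.
#' @param blink_duration_range_s Range (s) of blink-gap durations.
#' @param outlier_rate Per-sample probability of an isolated pupil outlier.
#' @param aoi_dwell_target_pct `models x AOI` matrix of target dwell-time
#'   percentages (of segment duration) used to calibrate the AOI fixation
#'   chain; rows need not sum to 100 (saccade and background time fill the
#'   remainder).
#' @param aoi_fix_duration_ms Named numeric, mean fixation duration (ms) per
#'   AOI label (including `background`).
#' @param aoi_fix_duration_sdlog Log-scale SD of the log-normal fixation
#'   durations.
#' @param aoi_stickiness Self-transition bonus of the AOI chain, in `[0, 1)`;
#'   higher values produce longer same-AOI runs without changing long-run
#'   occupancy.
#' @param aoi_transition_override Optional named list (per model) of
#'   `list(transition = <row-stochastic matrix>, start = <probability
#'   vector>)` replacing the calibrated chain of [aoi_chain()].
#' @param saccade_duration_ms Mean saccade duration (ms).
#' @param saccade_duration_sdlog Log-scale SD of saccade durations (0 makes
#'   them deterministic).
#' @param spv_mean_deg_s,spv_sd_deg_s Mean and SD of saccadic peak velocity
#'   (deg/s).
#' @param failure_rates Data frame of Poisson failure means per system and
#'   complexity level with columns `system`, `complexity`, `wrong_part`,
#'   `wrong_orientation`.
#' @param complexity_rating_means Named numeric `c(low = , high = )`, mean
#'   perceived-complexity rating on the 1--100 scale per complexity block.
#' @param complexity_rating_sd Rating SD.
#' @param prop_female Proportion of female participants (metadata only; no
#'   physiological effect).
#' @param baseline_duration_s Duration (s) of the seated rest recording
#'   appended after the four models; excluded from all workload references.
#' @param gap_s Optional gap (s) inserted between consecutive model segments;
#'   gap time carries no samples and is ignored by all statistics.
#' @param seed Integer seed; all per-participant streams are derived from it.
#'
#' @return A list of class `"mwl_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 6, seed = 1)
#' cfg$hr_mean_bpm
sim_config <- function(n_participants = 30,
                       systems = c("AR", "tablet", "paper"),
                       system_weights = NULL,
                       model_mean_duration_s = c(M1 = 128, M2 = 165,
                                                 M3 = 564, M4 = 682),
                       duration_cv = 0.2,
                       hr_mean_bpm = default_hr_grid(),
                       hr_between_sd_bpm = 3,
                       rr_phi = 0.6,
                       rr_innovation_sd_ms = 22.4,
                       artifact_rate = 0.005,
                       ecg_noise_sd = 0.05,
                       pupil_mean_mm = default_pupil_grid(),
                       pupil_between_sd_mm = 0.25,
                       pupil_drift_sd_mm = 0.05,
                       pupil_eye_noise_sd_mm = 0.02,
                       blink_rate_hz = 0.2,
                       blink_duration_range_s = c(0.1, 0.3),
                       outlier_rate = 0.002,
                       aoi_dwell_target_pct = default_aoi_dwell_targets(),
                       aoi_fix_duration_ms = c(assistance_system = 240,
                                               assembly_object = 380,
                                               assembly_parts = 200,
                                               tools = 180,
                                               assembly_tablet = 250,
                                               background = 200),
                       aoi_fix_duration_sdlog = 0.4,
                       aoi_stickiness = 0.3,
                       aoi_transition_override = NULL,
                       saccade_duration_ms = 50,
                       saccade_duration_sdlog = 0.2,
                       spv_mean_deg_s = 185,
                       spv_sd_deg_s = 40,
                       failure_rates = default_failure_rates(),
                       complexity_rating_means = c(low = 26.59, high = 53.52),
                       complexity_rating_sd = 12,
                       prop_female = 0.6,
                       baseline_duration_s = 300,
                       gap_s = 0,
                       seed = 1L) {
  if (is.null(system_weights)) {
    system_weights <- rep(1 / length(systems), length(systems))
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    systems = systems,
    system_weights = system_weights / sum(system_weights),
    models = paste0("M", 1:4),
    model_mean_duration_s = model_mean_duration_s,
    duration_cv = duration_cv,
    hr_mean_bpm = hr_mean_bpm,
    hr_between_sd_bpm = hr_between_sd_bpm,
    rr_phi = rr_phi,
    rr_innovation_sd_ms = rr_innovation_sd_ms,
    artifact_rate = artifact_rate,
    ecg_noise_sd = ecg_noise_sd,
    pupil_mean_mm = pupil_mean_mm,
    pupil_between_sd_mm = pupil_between_sd_mm,
    pupil_drift_sd_mm = pupil_drift_sd_mm,
    pupil_eye_noise_sd_mm = pupil_eye_noise_sd_mm,
    pupil_rate_hz = 60,
    blink_rate_hz = blink_rate_hz,
    blink_duration_range_s = blink_duration_range_s,
    outlier_rate = outlier_rate,
    aoi_dwell_target_pct = aoi_dwell_target_pct,
    aoi_fix_duration_ms = aoi_fix_duration_ms,
    aoi_fix_duration_sdlog = aoi_fix_duration_sdlog,
    aoi_stickiness = aoi_stickiness,
    aoi_transition_override = aoi_transition_override,
    saccade_duration_ms = saccade_duration_ms,
    saccade_duration_sdlog = saccade_duration_sdlog,
    spv_mean_deg_s = spv_mean_deg_s,
    spv_sd_deg_s = spv_sd_deg_s,
    failure_rates = failure_rates,
    complexity_rating_means = complexity_rating_means,
    complexity_rating_sd = complexity_rating_sd,
    prop_female = prop_female,
    baseline_duration_s = baseline_duration_s,
    gap_s = gap_s,
    ecg_sampling_rate_hz = 1000,
    seed = as.integer(seed)
  )
  class(cfg) <- "mwl_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1,
    length(cfg$systems) == length(cfg$system_weights),
    all(cfg$system_weights >= 0),
    all(cfg$model_mean_duration_s > 0),
    cfg$duration_cv >= 0,
    all(cfg$hr_mean_bpm > 0),
    cfg$rr_phi >= 0, cfg$rr_phi < 1,
    cfg$rr_innovation_sd_ms >= 0,
    cfg$artifact_rate >= 0, cfg$artifact_rate <= 1,
    all(cfg$pupil_mean_mm > 1), all(cfg$pupil_mean_mm < 9),
    cfg$blink_rate_hz >= 0,
    cfg$outlier_rate >= 0, cfg$outlier_rate <= 1,
    all(cfg$aoi_dwell_target_pct >= 0),
    all(rowSums(cfg$aoi_dwell_target_pct) < 100),
    all(cfg$aoi_fix_duration_ms > 0),
    cfg$aoi_stickiness >= 0, cfg$aoi_stickiness < 1,
    cfg$complexity_rating_sd >= 0,
    cfg$prop_female >= 0, cfg$prop_female <= 1,
    cfg$gap_s >= 0
  )
  if (!identical(rownames(cfg$hr_mean_bpm), cfg$systems) ||
      !identical(colnames(cfg$hr_mean_bpm), cfg$models)) {
    stop("hr_mean_bpm must be a systems x models matrix with dimnames")
  }
  invisible(cfg)
}

#' Default per-cell heart-rate grid (bpm)
#'
#' Mean heart rate per assistance system and assembly model used to calibrate
#' the simulator, taken from the summary tables of the motivating study.
#'
#' @return A `3 x 4` matrix (systems x models).
#' @export
default_hr_grid <- function() {
  matrix(
    c(93.71, 92.52, 95.16, 96.17,
      97.50, 95.34, 96.98, 97.29,
      93.02, 91.22, 93.69, 93.73),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("AR", "tablet", "paper"), paste0("M", 1:4))
  )
}

#' Default per-cell pupil-diameter grid (mm)
#'
#' @return A `3 x 4` matrix (systems x models) of mean pupil diameters.
#' @export
default_pupil_grid <- function() {
  matrix(
    c(3.29, 3.46, 3.58, 3.41,
      3.43, 3.52, 3.44, 3.42,
      3.54, 3.66, 3.58, 3.53),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("AR", "tablet", "paper"), paste0("M", 1:4))
  )
}

#' Default AOI dwell-share targets (% of segment duration)
#'
#' Long-run dwell-time percentages the simulated gaze chain is calibrated to
#' per model. M1 and M4 follow the pooled values observed in the motivating
#' study (most dwell on the assistance system, the assembly object and the
#' parts area in M1; a strong shift toward the assembly object by M4); M2 and
#' M3 are linear interpolations between them.
#'
#' @return A `4 x 5` matrix (models x AOI labels).
#' @export
default_aoi_dwell_targets <- function() {
  labels <- c("assistance_system", "assembly_object", "assembly_parts",
              "tools", "assembly_tablet")
  m1 <- c(25.85, 23.93, 19.81, 1.68, 4.83)
  m4 <- c(20.46, 48.63, 9.85, 1.10, 0.17)
  w <- c(0, 1 / 3, 2 / 3, 1)
  out <- t(vapply(w, function(a) (1 - a) * m1 + a * m4, numeric(5)))
  dimnames(out) <- list(paste0("M", 1:4), labels)
  out
}

#' Default failure-rate table
#'
#' Poisson means of assembly failures per assistance system and complexity
#' level, split into wrong-part and wrong-orientation failures. Calibrated so
#' that systems barely differ at low complexity while at high complexity the
#' paper instructions yield the fewest orientation failures and AR the most.
#'
#' @return A tibble with columns `system`, `complexity`, `wrong_part`,
#'   `wrong_orientation`.
#' @export
default_failure_rates <- function() {
  tibble::tibble(
    system = rep(c("AR", "tablet", "paper"), each = 2),
    complexity = rep(c("low", "high"), 3),
    wrong_part = c(0.1, 0.5, 0.1, 0.5, 0.1, 0.5),
    wrong_orientation = c(0.1, 1.2, 0.1, 0.9, 0.1, 0.5)
  )
}

#' Published-style summary tables used for calibration and aggregation checks
#'
#' Per-group summary tables of the motivating assembly study: mean assembly
#' times by gender, and the percentage of working time spent in heart-rate and
#' pupil over/underload states by assistance system. Group sizes accompany
#' each table so that sample-size-weighted overall rows can be recomputed with
#' [weighted_overall()].
#'
#' @return A list of three tibbles: `assembly_time_by_gender` (n = 39 female,
#'   27 male), `hr_state_pct_by_system` (n = 22/22/21 for AR/tablet/paper) and
#'   `pr_state_pct_by_system` (n = 21/19/19).
#' @export
#' @examples
#' tabs <- calibration_tables()
#' with(
#'   subset(tabs$hr_state_pct_by_system, state == "underload" & model == "M2"),
#'   weighted_overall(value, n)
#' )
calibration_tables <- function() {
  models <- paste0("M", 1:4)
  list(
    assembly_time_by_gender = tibble::tibble(
      gender = rep(c("female", "male"), each = 4),
      n = rep(c(39L, 27L), each = 4),
      model = rep(models, 2),
      value = c(126.46, 164.64, 561.33, 686.97,
                129.89, 165.48, 567.22, 675.15)
    ),
    hr_state_pct_by_system = tibble::tibble(
      system = rep(c("AR", "tablet", "paper"), each = 8),
      n = rep(c(22L, 22L, 21L), each = 8),
      state = rep(rep(c("underload", "overload"), each = 4), 3),
      model = rep(models, 6),
      value = c(20.04, 28.02, 11.26, 9.45,
                10.45, 12.30, 14.21, 21.62,
                9.97, 21.06, 9.79, 11.73,
                20.21, 14.52, 15.38, 17.21,
                16.37, 23.27, 10.27, 12.21,
                16.08, 11.47, 16.11, 19.97)
    ),
    pr_state_pct_by_system = tibble::tibble(
      system = rep(c("AR", "tablet", "paper"), each = 8),
      n = rep(c(21L, 19L, 19L), each = 8),
      state = rep(rep(c("underload", "overload"), each = 4), 3),
      model = rep(models, 6),
      value = c(10.57, 18.20, 11.15, 13.68,
                34.53, 6.16, 9.57, 17.46,
                19.74, 25.03, 14.33, 12.53,
                10.05, 6.34, 8.62, 12.49,
                16.78, 24.52, 16.65, 9.03,
                13.19, 4.83, 8.07, 15.82)
    )
  )
}
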