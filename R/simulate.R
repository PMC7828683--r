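#' Build a session schedule for one participant
#'
#' Four model segments `M1`..`M4` in fixed order (low-complexity models
#' first), back-to-back apart from an optional configured gap, followed by an
#' optional seated baseline recording. Segment durations are drawn from a
#' normal distribution with the configured per-model mean and coefficient of
#' variation; non-positive draws are redrawn (at most 10 times, then an
#' error). Deterministic given `(config$seed, participant_index)`.
#'
#' @param config A [sim_config()].
#' @param participant_index 1-based participant index, `<= n_participants`.
#' @return A list of class `mwl_schedule` with `participant_id`, `system`,
#'   `participant_index`, `gender`, `segments` (tibble `model`, `t_start_s`,
#'   `t_end_s`, half-open `[start, end)`) and `baseline` (`c(start, end)` or
#'   `NULL`).
#' @export
build_schedule <- function(config, participant_index) {
  stopifnot(participant_index >= 1,
            participant_index <= config$n_participants)
  idx <- as.integer(participant_index)
  system <- assign_system(config, idx)
  withr::with_seed(substream_seed(config$seed, idx, 1L), {
    durs <- vapply(config$models, function(m) {
      mu <- config$model_mean_duration_s[[m]]
      sd <- config$duration_cv * mu
      for (k in 1:11) {
        if (k == 11) stop("could not draw a positive segment duration")
        d <- stats::rnorm(1, mu, sd)
        if (d > 0) break
      }
      d
    }, numeric(1))
    gender <- if (stats::runif(1) < config$prop_female) "female" else "male"
  })
  starts <- cumsum(c(0, unname(durs[-4]) + config$gap_s))
  segments <- tibble::tibble(
    model = config$models,
    t_start_s = starts,
    t_end_s = starts + unname(durs)
  )
  baseline <- NULL
  if (config$baseline_duration_s > 0) {
    b0 <- segments$t_end_s[4] + config$gap_s
    baseline <- c(b0, b0 + config$baseline_duration_s)
  }
  structure(
    list(participant_id = sprintf("P%03d", idx),
         participant_index = idx,
         system = system,
         gender = gender,
         segments = segments,
         baseline = baseline),
    class = "mwl_schedule"
  )
}

assign_system <- function(config, idx) {
  w <- config$system_weights
  k <- length(config$systems)
  if (all(abs(w - 1 / k) < 1e-12)) {
    config$systems[(idx - 1) %% k + 1]
  } else {
    withr::with_seed(substream_seed(config$seed, idx, 2L),
                     sample(config$systems, 1, prob = w))
  }
}

#' Simulate an RR-interval series for a scheduled session
#'
#' Per segment, RR intervals fluctuate around `60000 / HR` bpm-for-the-cell
#' (plus a stable per-participant offset) following a lag-1 autoregressive
#' process; each segment starts with an anchor beat at its start time so
#' beats cover every segment. Beat artifacts (ectopic displacement or missed
#' beat) are injected at the configured per-beat rate and logged as ground
#' truth.
#'
#' @param schedule A [build_schedule()] result.
#' @param config The matching [sim_config()].
#' @return An [rr_series()] with a `true_artifact` column and attributes
#'   `truth` (list with `beats_true` and `artifacts` tibbles) and
#'   `participant_id`.
#' @export
simulate_rr <- function(schedule, config) {
  idx <- schedule$participant_index
  hr_row <- config$hr_mean_bpm[schedule$system, ]
  if (any(hr_row <= 0)) stop("configured heart rate must be positive")
  withr::with_seed(substream_seed(config$seed, idx, 3L), {
    hr_offset <- stats::rnorm(1, 0, config$hr_between_sd_bpm)
    segs <- schedule$segments
    if (!is.null(schedule$baseline)) {
      segs <- rbind(segs, tibble::tibble(model = "baseline",
                                         t_start_s = schedule$baseline[1],
                                         t_end_s = schedule$baseline[2]))
    }
    phi <- config$rr_phi
    sig <- config$rr_innovation_sd_ms
    beats <- numeric(0)
    truth_beats <- numeric(0)
    art_t <- numeric(0)
    art_type <- character(0)
    for (s in seq_len(nrow(segs))) {
      hr <- if (segs$model[s] == "baseline") {
        mean(hr_row) + hr_offset - 10  # rest: lower than task HR
      } else {
        hr_row[[segs$model[s]]] + hr_offset
      }
      m <- 60000 / hr
      dur_ms <- (segs$t_end_s[s] - segs$t_start_s[s]) * 1000
      n_max <- ceiling(dur_ms / m * 1.3) + 20
      eps <- stats::rnorm(n_max, 0, sig)
      dev0 <- stats::rnorm(1, 0, sig / sqrt(1 - phi^2))
      dev <- as.numeric(stats::filter(eps, phi, method = "recursive",
                                      init = dev0))
      rr <- pmax(m + dev, 250)
      bt <- segs$t_start_s[s] + cumsum(rr) / 1000
      bt <- bt[bt < segs$t_end_s[s]]
      seg_true <- c(segs$t_start_s[s], bt)
      truth_beats <- c(truth_beats, seg_true)
      obs <- seg_true
      if (config$artifact_rate > 0 && length(obs) > 2) {
        hit <- which(stats::runif(length(obs) - 2) <
                       config$artifact_rate) + 1
        for (j in hit) {
          if (stats::runif(1) < 0.5) {
            art_t <- c(art_t, obs[j]); art_type <- c(art_type, "missed")
            obs[j] <- NA
          } else {
            gap <- obs[j] - obs[j - 1]
            obs[j] <- obs[j] - 0.3 * gap
            art_t <- c(art_t, obs[j]); art_type <- c(art_type, "ectopic")
          }
        }
        obs <- obs[!is.na(obs)]
      }
      beats <- c(beats, obs)
    }
  })
  beats <- sort(beats)
  rr <- rr_series(beats)
  mods <- sort(art_t)
  rr$true_artifact <- interval_touches(beats, mods)
  attr(rr, "truth") <- list(
    beats_true = tibble::tibble(t_s = truth_beats),
    artifacts = tibble::tibble(t_s = art_t, type = art_type)
  )
  attr(rr, "participant_id") <- schedule$participant_id
  rr
}

# TRUE for intervals whose bounding beats include (or straddle) a modified
# beat time.
interval_touches <- function(beats, mods) {
  n <- length(beats)
  out <- rep(FALSE, n)
  if (!length(mods) || n < 2) return(out)
  is_mod <- beats %in% mods
  for (i in 2:n) {
    out[i] <- is_mod[i] || is_mod[i - 1] ||
      any(mods > beats[i - 1] & mods < beats[i])
  }
  out
}

#' Render a synthetic ECG trace from beat times
#'
#' Sum of unimodal (Gaussian) R-wave templates of amplitude 1 and width 20 ms
#' centred at the beat times, plus white noise.
#'
#' @param rr An [rr_series()] or numeric vector of beat times (s).
#' @param sampling_rate_hz Sampling rate, `>= 250`.
#' @param noise_sd White-noise SD (template amplitude is 1).
#' @param t_range Optional `c(from, to)`; defaults to the beat range padded by
#'   0.5 s (required when there are no beats).
#' @return A tibble `t_s`, `amplitude` with attributes `sampling_rate_hz` and
#'   `beats_true`.
#' @export
render_ecg <- function(rr, sampling_rate_hz = 1000, noise_sd = 0.05,
                       t_range = NULL) {
  stopifnot(sampling_rate_hz >= 250)
  beats <- if (inherits(rr, "rr_series") || is.data.frame(rr)) {
    rr$t_beat_s
  } else {
    as.numeric(rr)
  }
  if (is.null(t_range)) {
    if (!length(beats)) stop("t_range is required when there are no beats")
    t_range <- c(min(beats) - 0.5, max(beats) + 0.5)
  }
  t_s <- seq(t_range[1], t_range[2], by = 1 / sampling_rate_hz)
  amp <- stats::rnorm(length(t_s), 0, noise_sd)
  sd_s <- 0.020 / 4  # 20 ms template width = +/- 2 SD
  halfwin <- ceiling(4 * sd_s * sampling_rate_hz)
  for (b in beats) {
    c0 <- round((b - t_range[1]) * sampling_rate_hz) + 1
    lo <- max(1, c0 - halfwin)
    hi <- min(length(t_s), c0 + halfwin)
    if (lo > hi) next
    amp[lo:hi] <- amp[lo:hi] + exp(-((t_s[lo:hi] - b)^2) / (2 * sd_s^2))
  }
  out <- tibble::tibble(t_s = t_s, amplitude = amp)
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  attr(out, "beats_true") <- beats
  out
}

#' Simulate a binocular pupil trace
#'
#' 60 Hz samples over all model segments: both eyes share a common workload
#' signal (cell mean + participant offset + slow AR(1) fluctuation) plus
#' independent per-eye noise. Blinks appear as runs of invalid samples
#' (validity 0, diameter 0); isolated outlier samples are injected at the
#' configured rate. The noiseless common signal is retained as ground truth.
#'
#' @inheritParams simulate_rr
#' @return A tibble `t_s`, `left_mm`, `right_mm`, `left_valid`, `right_valid`
#'   with attributes `truth` (tibble `t_s`, `signal_mm`) and
#'   `participant_id`.
#' @export
simulate_pupil <- function(schedule, config) {
  idx <- schedule$participant_index
  base_row <- config$pupil_mean_mm[schedule$system, ]
  withr::with_seed(substream_seed(config$seed, idx, 5L), {
    offset <- stats::rnorm(1, 0, config$pupil_between_sd_mm)
    dt <- 1 / config$pupil_rate_hz
    phi <- 0.99
    innov <- config$pupil_drift_sd_mm * sqrt(1 - phi^2)
    segs <- schedule$segments
    all_t <- list(); all_sig <- list()
    for (s in seq_len(nrow(segs))) {
      t_s <- seq(segs$t_start_s[s], segs$t_end_s[s] - dt / 2, by = dt)
      n <- length(t_s)
      d0 <- stats::rnorm(1, 0, config$pupil_drift_sd_mm)
      eps <- stats::rnorm(n, 0, innov)
      drift <- as.numeric(stats::filter(eps, phi, method = "recursive",
                                        init = d0))
      all_t[[s]] <- t_s
      all_sig[[s]] <- base_row[[segs$model[s]]] + offset + drift
    }
    t_s <- unlist(all_t)
    sig <- unlist(all_sig)
    n <- length(t_s)
    left <- sig + stats::rnorm(n, 0, config$pupil_eye_noise_sd_mm)
    right <- sig + stats::rnorm(n, 0, config$pupil_eye_noise_sd_mm)
    lv <- rep(1L, n); rv <- rep(1L, n)
    # blinks: both eyes invalid
    total_s <- sum(segs$t_end_s - segs$t_start_s)
    n_blinks <- stats::rpois(1, config$blink_rate_hz * total_s)
    if (n_blinks > 0) {
      b_start <- sort(stats::runif(n_blinks, min(t_s), max(t_s)))
      b_dur <- stats::runif(n_blinks, config$blink_duration_range_s[1],
                            config$blink_duration_range_s[2])
      for (b in seq_len(n_blinks)) {
        hit <- t_s >= b_start[b] & t_s < b_start[b] + b_dur[b]
        lv[hit] <- 0L; rv[hit] <- 0L
      }
    }
    if (config$outlier_rate > 0) {
      for (eye in c("left", "right")) {
        o <- which(stats::runif(n) < config$outlier_rate & lv == 1L)
        if (length(o)) {
          bump <- sample(c(-1, 1), length(o), replace = TRUE) *
            stats::runif(length(o), 0.8, 1.5)
          if (eye == "left") left[o] <- left[o] + bump
          else right[o] <- right[o] + bump
        }
      }
    }
    left[lv == 0L] <- 0
    right[rv == 0L] <- 0
  })
  out <- tibble::tibble(t_s = t_s, left_mm = left, right_mm = right,
                        left_valid = lv, right_valid = rv)
  attr(out, "truth") <- tibble::tibble(t_s = t_s, signal_mm = sig)
  attr(out, "participant_id") <- schedule$participant_id
  out
}

#' Simulate a gaze event stream
#'
#' Alternating fixation/saccade events tile each model segment. Fixation AOI
#' labels follow a first-order chain whose transition matrix is calibrated so
#' long-run dwell-time shares match the configured per-model targets (see
#' [aoi_chain()]); fixation durations are log-normal per AOI and saccade peak
#' velocities normal. The true AOI chain is retained as ground truth.
#'
#' @inheritParams simulate_rr
#' @return A tibble `kind`, `t_start_s`, `t_end_s`, `duration_ms`, `aoi`,
#'   `peak_velocity_deg_s` with attribute `participant_id`.
#' @export
simulate_gaze <- function(schedule, config) {
  idx <- schedule$participant_index
  labels <- c(colnames(config$aoi_dwell_target_pct), "background")
  mu <- config$aoi_fix_duration_ms[labels]
  sdlog <- config$aoi_fix_duration_sdlog
  meanlog <- log(mu) - sdlog^2 / 2
  sac_sdlog <- config$saccade_duration_sdlog
  sac_meanlog <- log(config$saccade_duration_ms) - sac_sdlog^2 / 2
  seg_out <- list()
  withr::with_seed(substream_seed(config$seed, idx, 7L), {
    for (s in seq_len(nrow(schedule$segments))) {
      seg <- schedule$segments[s, ]
      chain <- aoi_chain(config, seg$model)
      seg_dur <- seg$t_end_s - seg$t_start_s
      n_max <- ceiling(seg_dur * 1000 / (min(mu) * 0.5)) + 10
      states <- integer(n_max)
      states[1] <- sample.int(length(labels), 1, prob = chain$pi)
      for (k in 2:n_max) {
        states[k] <- sample.int(length(labels), 1,
                                prob = chain$transition[states[k - 1], ])
      }
      fd <- stats::rlnorm(n_max, meanlog[states], sdlog) / 1000
      sac <- stats::rlnorm(n_max, sac_meanlog, sac_sdlog) / 1000
      spv <- pmax(stats::rnorm(n_max, config$spv_mean_deg_s,
                               config$spv_sd_deg_s), 20)
      cyc_end <- cumsum(fd + sac)
      fix_start <- seg$t_start_s + c(0, cyc_end[-n_max])
      sac_start <- fix_start + fd
      keep_f <- fix_start < seg$t_end_s
      keep_s <- sac_start < seg$t_end_s
      ev <- rbind(
        tibble::tibble(kind = "fixation",
                       t_start_s = fix_start[keep_f],
                       t_end_s = pmin(sac_start[keep_f], seg$t_end_s),
                       aoi = labels[states[keep_f]],
                       peak_velocity_deg_s = NA_real_),
        tibble::tibble(kind = "saccade",
                       t_start_s = sac_start[keep_s],
                       t_end_s = pmin((sac_start + sac)[keep_s],
                                      seg$t_end_s),
                       aoi = NA_character_,
                       peak_velocity_deg_s = spv[keep_s])
      )
      seg_out[[s]] <- ev[order(ev$t_start_s), ]
    }
  })
  out <- dplyr::bind_rows(seg_out)
  out$duration_ms <- (out$t_end_s - out$t_start_s) * 1000
  out <- out[out$duration_ms >= 1,
             c("kind", "t_start_s", "t_end_s", "duration_ms", "aoi",
               "peak_velocity_deg_s")]
  attr(out, "participant_id") <- schedule$participant_id
  out
}

#' AOI fixation chain calibrated to dwell-share targets
#'
#' Solves for the fixation-count occupancy `pi` over the AOI labels (plus
#' background) such that, with the configured mean fixation durations and
#' saccade duration, the long-run dwell-time percentage of each labelled AOI
#' equals its configured target. The transition matrix is
#' `(1 - stickiness) * 1 pi' + stickiness * I`, which keeps `pi` stationary
#' for any stickiness while producing same-AOI runs.
#'
#' @param config A [sim_config()].
#' @param model Model label, one of `M1`..`M4`.
#' @return A list with `labels`, `pi` (stationary fixation occupancy) and
#'   `transition` (row-stochastic matrix).
#' @export
aoi_chain <- function(config, model) {
  d <- config$aoi_dwell_target_pct[model, ]
  labels <- c(names(d), "background")
  ov <- config$aoi_transition_override[[model]]
  if (!is.null(ov)) {
    if (any(ov$transition < 0) ||
        any(abs(rowSums(ov$transition) - 1) > 1e-9)) {
      stop("override transition matrix rows must be stochastic")
    }
    return(list(labels = rownames(ov$transition),
                pi = ov$start / sum(ov$start),
                transition = ov$transition))
  }
  mu <- config$aoi_fix_duration_ms[labels]
  mu_bg <- mu[["background"]]
  s <- config$saccade_duration_ms
  # mean event-cycle time T solves pi constraints; see vignette
  T_cycle <- (mu_bg + s) /
    (1 - sum(d) / 100 + mu_bg * sum(d / mu[names(d)]) / 100)
  pi_lab <- d * T_cycle / (100 * mu[names(d)])
  pi_bg <- 1 - sum(pi_lab)
  if (pi_bg < 0) stop("dwell targets infeasible for given fixation durations")
  p <- c(pi_lab, background = pi_bg)
  rho <- config$aoi_stickiness
  trans <- (1 - rho) * matrix(p, nrow = length(p), ncol = length(p),
                              byrow = TRUE) + rho * diag(length(p))
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-9))
  dimnames(trans) <- list(labels, labels)
  list(labels = labels, pi = p, transition = trans)
}

#' Simulate performance records for a scheduled session
#'
#' Assembly time equals the segment length; failure counts are Poisson with
#' the configured per-system, per-complexity means; perceived complexity is
#' rated once per complexity block (the same value is attached to both models
#' of a block) on the 1--100 scale.
#'
#' @inheritParams simulate_rr
#' @return A tibble `participant_id`, `model`, `assembly_time_s`,
#'   `wrong_part`, `wrong_orientation`, `perceived_complexity`.
#' @export
simulate_performance <- function(schedule, config) {
  idx <- schedule$participant_index
  complexity <- c(M1 = "low", M2 = "low", M3 = "high", M4 = "high")
  fr <- config$failure_rates
  withr::with_seed(substream_seed(config$seed, idx, 9L), {
    ratings <- pmin(pmax(stats::rnorm(
      2, config$complexity_rating_means[c("low", "high")],
      config$complexity_rating_sd), 1), 100)
    names(ratings) <- c("low", "high")
    rows <- lapply(seq_len(4), function(s) {
      m <- schedule$segments$model[s]
      cx <- complexity[[m]]
      r <- fr[fr$system == schedule$system & fr$complexity == cx, ]
      tibble::tibble(
        participant_id = schedule$participant_id,
        model = m,
        assembly_time_s = schedule$segments$t_end_s[s] -
          schedule$segments$t_start_s[s],
        wrong_part = stats::rpois(1, r$wrong_part),
        wrong_orientation = stats::rpois(1, r$wrong_orientation),
        perceived_complexity = ratings[[cx]]
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulate a complete cohort
#'
#' One bundle per participant: schedule, RR series, optional ECG trace,
#' pupil trace, gaze event stream and performance records. System assignment,
#' gender and every signal are reproducible from the config seed; each
#' participant uses independent derived substreams, so enlarging the cohort
#' never reshuffles earlier participants.
#'
#' @param config A [sim_config()].
#' @param signals Character subset of `c("rr", "ecg", "pupil", "gaze")`
#'   selecting which signals to generate (schedules and performance are always
#'   generated).
#' @return A list of class `mwl_cohort` with elements `config`,
#'   `participants` (tibble), `schedules`, `rr`, `ecg`, `pupil`, `gaze`
#'   (named lists keyed by participant id) and `performance` (tibble).
#' @export
simulate_cohort <- function(config,
                            signals = c("rr", "pupil", "gaze")) {
  if (config$n_participants < 1) stop("n_participants must be >= 1")
  ids <- character(config$n_participants)
  schedules <- vector("list", config$n_participants)
  rr <- list(); ecg <- list(); pupil <- list(); gaze <- list()
  perf <- list()
  for (i in seq_len(config$n_participants)) {
    sch <- build_schedule(config, i)
    ids[i] <- sch$participant_id
    schedules[[i]] <- sch
    if ("rr" %in% signals) rr[[sch$participant_id]] <-
        simulate_rr(sch, config)
    if ("ecg" %in% signals) {
      if (is.null(rr[[sch$participant_id]])) {
        rr[[sch$participant_id]] <- simulate_rr(sch, config)
      }
      ecg[[sch$participant_id]] <- withr::with_seed(
        substream_seed(config$seed, i, 11L),
        render_ecg(rr[[sch$participant_id]],
                   sampling_rate_hz = config$ecg_sampling_rate_hz,
                   noise_sd = config$ecg_noise_sd))
    }
    if ("pupil" %in% signals) pupil[[sch$participant_id]] <-
        simulate_pupil(sch, config)
    if ("gaze" %in% signals) gaze[[sch$participant_id]] <-
        simulate_gaze(sch, config)
    perf[[i]] <- simulate_performance(sch, config)
  }
  names(schedules) <- ids
  structure(
    list(config = config,
         participants = tibble::tibble(
           participant_id = ids,
           system = vapply(schedules, function(s) s$system, character(1)),
           gender = vapply(schedules, function(s) s$gender, character(1))
         ),
         schedules = schedules, rr = rr, ecg = ecg, pupil = pupil,
         gaze = gaze, performance = dplyr::bind_rows(perf)),
    class = "mwl_cohort"
  )
}

#' Write a cohort to CSV files
#'
#' Writes `schedule.csv`, `rr.csv`, optional `ecg.csv`, `pupil.csv`,
#' `gaze_events.csv`, `performance.csv` and ground-truth tables under
#' `truth/`. All times are seconds from session start; files are UTF-8 with a
#' header row, so identical cohorts serialize byte-identically.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  sched <- dplyr::bind_rows(lapply(cohort$schedules, function(s) {
    dplyr::mutate(s$segments, participant_id = s$participant_id,
                  system = s$system, .before = 1)
  }))
  readr::write_csv(sched, file.path(dir, "schedule.csv"))
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  if (length(cohort$rr)) {
    rr <- dplyr::bind_rows(lapply(names(cohort$rr), function(id) {
      x <- cohort$rr[[id]]
      tibble::tibble(participant_id = id, t_beat_s = x$t_beat_s,
                     rr_ms = x$rr_ms, true_artifact = x$true_artifact)
    }))
    readr::write_csv(rr, file.path(dir, "rr.csv"))
    truth <- dplyr::bind_rows(lapply(names(cohort$rr), function(id) {
      tb <- attr(cohort$rr[[id]], "truth")$beats_true
      tibble::tibble(participant_id = id, t_s = tb$t_s)
    }))
    readr::write_csv(truth, file.path(dir, "truth", "beats_true.csv"))
  }
  if (length(cohort$ecg)) {
    ecg <- dplyr::bind_rows(lapply(names(cohort$ecg), function(id) {
      tibble::tibble(participant_id = id, t_s = cohort$ecg[[id]]$t_s,
                     amplitude = cohort$ecg[[id]]$amplitude)
    }))
    readr::write_csv(ecg, file.path(dir, "ecg.csv"))
  }
  if (length(cohort$pupil)) {
    pup <- dplyr::bind_rows(lapply(names(cohort$pupil), function(id) {
      dplyr::mutate(cohort$pupil[[id]], participant_id = id, .before = 1)
    }))
    readr::write_csv(pup, file.path(dir, "pupil.csv"))
  }
  if (length(cohort$gaze)) {
    gz <- dplyr::bind_rows(lapply(names(cohort$gaze), function(id) {
      dplyr::mutate(cohort$gaze[[id]], participant_id = id, .before = 1)
    }))
    readr::write_csv(gz, file.path(dir, "gaze_events.csv"))
  }
  readr::write_csv(cohort$performance, file.path(dir, "performance.csv"))
  invisible(dir)
}
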