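test_that("schedules are ordered M1..M4 with configured durations", {
  cfg <- sim_config(n_participants = 2, duration_cv = 0, seed = 3)
  sch <- build_schedule(cfg, 1)
  expect_equal(sch$segments$model, paste0("M", 1:4))
  expect_equal(sch$segments$t_end_s - sch$segments$t_start_s,
               c(128, 165, 564, 682), ignore_attr = TRUE)
  expect_equal(sch$segments$t_start_s[-1], sch$segments$t_end_s[-4])
  # determinism; under noise, different participants get different draws
  expect_identical(build_schedule(cfg, 1), sch)
  cfg2 <- sim_config(n_participants = 2, duration_cv = 0.2, seed = 3)
  expect_false(identical(build_schedule(cfg2, 2)$segments,
                         build_schedule(cfg2, 1)$segments))
})

test_that("segment durations recover the configured mean under noise", {
  cfg <- sim_config(n_participants = 1000, duration_cv = 0.2, seed = 9)
  m1 <- vapply(1:1000, function(i) {
    s <- build_schedule(cfg, i)$segments
    s$t_end_s[1] - s$t_start_s[1]
  }, numeric(1))
  se <- 0.2 * 128 / sqrt(1000)
  expect_lt(abs(mean(m1) - 128), 3 * se)
})

test_that("noise-free RR simulation yields exactly the configured rate", {
  grid <- default_hr_grid()
  grid[, ] <- 60
  cfg <- small_config(hr_mean_bpm = grid, hr_between_sd_bpm = 0,
                      rr_innovation_sd_ms = 0, artifact_rate = 0,
                      duration_cv = 0)
  rr <- simulate_rr(build_schedule(cfg, 1), cfg)
  expect_true(all(abs(rr$rr_ms[-1] - 1000) < 1e-9))
  expect_false(any(rr$true_artifact))
})

test_that("RR simulation covers every segment and hits the target mean HR", {
  cfg <- sim_config(n_participants = 1,
                    model_mean_duration_s = c(M1 = 300, M2 = 300,
                                              M3 = 300, M4 = 300),
                    hr_between_sd_bpm = 0, artifact_rate = 0,
                    baseline_duration_s = 0, seed = 21)
  sch <- build_schedule(cfg, 1)  # AR system
  rr <- simulate_rr(sch, cfg)
  seg <- sch$segments[1, ]  # AR M1 target 93.71 bpm
  in_seg <- rr$t_beat_s > seg$t_start_s & rr$t_beat_s <= seg$t_end_s
  hr_emp <- 60000 / mean(rr$rr_ms[in_seg], na.rm = TRUE)
  expect_lt(abs(hr_emp - 93.71), 1)
  # anchor beat at every segment start, last beat close to segment end
  for (s in 1:4) {
    expect_true(any(abs(rr$t_beat_s - sch$segments$t_start_s[s]) < 1e-9))
    expect_gt(max(rr$t_beat_s[rr$t_beat_s < sch$segments$t_end_s[s]]),
              sch$segments$t_end_s[s] - 3)
  }
})

test_that("injected artifact count follows the configured rate", {
  cfg <- sim_config(n_participants = 1, artifact_rate = 0.01,
                    baseline_duration_s = 0, hr_between_sd_bpm = 0,
                    seed = 13)
  rr <- simulate_rr(build_schedule(cfg, 1), cfg)
  truth <- attr(rr, "truth")
  n_beats <- nrow(truth$beats_true)
  n_art <- nrow(truth$artifacts)
  ci <- qbinom(c(0.005, 0.995), n_beats, 0.01)
  expect_gte(n_art, ci[1])
  expect_lte(n_art, ci[2])
  expect_gte(sum(rr$true_artifact, na.rm = TRUE), n_art)
})

test_that("ECG rendering centres templates on beats", {
  tr <- render_ecg(c(1.0), noise_sd = 0)
  expect_lt(abs(tr$t_s[which.max(tr$amplitude)] - 1.0), 0.001)
  noise <- render_ecg(numeric(0), noise_sd = 0.05, t_range = c(0, 10))
  expect_lt(abs(mean(noise$amplitude)), 3 * 0.05 / sqrt(nrow(noise)))
})

test_that("noise-free pupil trace is constant at the configured baseline", {
  cfg <- small_config(pupil_between_sd_mm = 0, pupil_drift_sd_mm = 0,
                      pupil_eye_noise_sd_mm = 0, blink_rate_hz = 0,
                      outlier_rate = 0)
  sch <- build_schedule(cfg, 1)  # AR
  pp <- simulate_pupil(sch, cfg)
  m1 <- pp[pp$t_s < sch$segments$t_end_s[1], ]
  expect_true(all(abs(m1$left_mm - 3.29) < 1e-9))
  expect_true(all(abs(m1$right_mm - 3.29) < 1e-9))
})

test_that("blink gap count falls in its binomial 99% interval", {
  # rate chosen so ~30 blinks are expected over the session
  cfg <- small_config(outlier_rate = 0)
  total <- sum(c(40, 40, 60, 60))
  cfg$blink_rate_hz <- 30 / total
  sch <- build_schedule(cfg, 2)
  pp <- simulate_pupil(sch, cfg)
  runs <- rle(pp$left_valid == 0)
  n_gaps <- sum(runs$values)
  ci <- qpois(c(0.005, 0.995), 30)
  expect_gte(n_gaps, ci[1])
  expect_lte(n_gaps, ci[2])
})

test_that("gaze streams tile segments with alternating sorted events", {
  cfg <- small_config()
  sch <- build_schedule(cfg, 1)
  gz <- simulate_gaze(sch, cfg)
  expect_true(!is.unsorted(gz$t_start_s))
  expect_true(all(gz$t_end_s[-nrow(gz)] <= gz$t_start_s[-1] + 1e-9))
  expect_true(all(gz$duration_ms >= 1))
  expect_equal(gz$duration_ms, (gz$t_end_s - gz$t_start_s) * 1000)
  # every event lies inside exactly one segment
  segs <- sch$segments
  owner <- vapply(gz$t_start_s, function(t) {
    sum(t >= segs$t_start_s & t < segs$t_end_s)
  }, numeric(1))
  expect_true(all(owner == 1))
})

test_that("identity transition override locks gaze to one AOI", {
  labs <- c(aoi_labels(), "background")
  ident <- diag(6)
  dimnames(ident) <- list(labs, labs)
  start <- c(1, 0, 0, 0, 0, 0)
  ov <- setNames(rep(list(list(transition = ident, start = start)), 4),
                 paste0("M", 1:4))
  cfg <- small_config(aoi_transition_override = ov)
  gz <- simulate_gaze(build_schedule(cfg, 1), cfg)
  fix <- gz[gz$kind == "fixation", ]
  expect_true(all(fix$aoi == "assistance_system"))
  bad <- ident
  bad[1, 1] <- 0.5
  ov_bad <- list(M1 = list(transition = bad, start = start))
  cfg_bad <- small_config(aoi_transition_override = ov_bad)
  expect_error(simulate_gaze(build_schedule(cfg_bad, 1), cfg_bad),
               "stochastic")
})

test_that("degenerate event durations force the fixation count", {
  labs <- c(aoi_labels(), "background")
  unif <- matrix(1 / 6, 6, 6, dimnames = list(labs, labs))
  ov <- setNames(rep(list(list(transition = unif, start = rep(1 / 6, 6))),
                     4), paste0("M", 1:4))
  cfg <- sim_config(
    n_participants = 1, duration_cv = 0,
    model_mean_duration_s = c(M1 = 10, M2 = 10, M3 = 10, M4 = 10),
    aoi_fix_duration_ms = c(assistance_system = 200, assembly_object = 200,
                            assembly_parts = 200, tools = 200,
                            assembly_tablet = 200, background = 200),
    aoi_fix_duration_sdlog = 0, saccade_duration_sdlog = 0,
    saccade_duration_ms = 50, baseline_duration_s = 0, seed = 2,
    aoi_transition_override = ov
  )
  gz <- simulate_gaze(build_schedule(cfg, 1), cfg)
  segs <- build_schedule(cfg, 1)$segments
  n_fix_m1 <- sum(gz$kind == "fixation" & gz$t_start_s < segs$t_end_s[1])
  expect_equal(n_fix_m1, 40)  # 10 s / (200 + 50) ms
})

test_that("long-run M4 dwell share of the assembly object matches the
           calibration target", {
  cfg <- sim_config(n_participants = 10, duration_cv = 0,
                    baseline_duration_s = 0, seed = 17)
  dwell <- vapply(1:10, function(i) {
    sch <- build_schedule(cfg, i)
    gz <- simulate_gaze(sch, cfg)
    am <- aoi_metrics(gz, sch$segments[4, ])
    am$dwell_pct[am$aoi == "assembly_object"]
  }, numeric(1))
  expect_lt(abs(mean(dwell) - 48.63), 5)
})

test_that("cohorts assign systems evenly and serialize deterministically", {
  cfg <- small_config(n_participants = 6)
  co <- simulate_cohort(cfg, signals = "rr")
  expect_equal(unname(table(co$participants$system)[c("AR", "tablet",
                                                      "paper")]),
               rep(2L, 3), ignore_attr = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(simulate_cohort(cfg, signals = "rr"), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  expect_error(simulate_cohort(sim_config(n_participants = 0)),
               ">= 1")
})

test_that("perceived complexity separates the two blocks participant-wise", {
  cfg <- sim_config(n_participants = 30, seed = 5)
  co <- simulate_cohort(cfg, signals = character(0))
  perf <- co$performance
  by_p <- split(perf, perf$participant_id)
  wins <- vapply(by_p, function(p) {
    mean(p$perceived_complexity[p$model %in% c("M3", "M4")]) >
      mean(p$perceived_complexity[p$model %in% c("M1", "M2")])
  }, logical(1))
  # with the configured effect (53.52 - 26.59) and rating SD, a participant
  # ranks the blocks correctly with p = pnorm(diff / (sd * sqrt(2)));
  # require at least the binomial 0.1% quantile of 30 participants
  p_win <- pnorm((53.52 - 26.59) / (12 * sqrt(2)))
  expect_gte(sum(wins), qbinom(0.001, 30, p_win))
})

test_that("raising one model's configured HR raises its estimated HR", {
  diffs <- vapply(1:20, function(s) {
    base <- small_config(seed = 100 + s)
    grid <- default_hr_grid()
    grid[, "M3"] <- grid[, "M3"] + 3
    up <- small_config(seed = 100 + s, hr_mean_bpm = grid)
    est <- function(cfg) {
      sch <- build_schedule(cfg, 1)
      rr <- clean_rr(simulate_rr(sch, cfg))
      ht <- hr_state_table(rr, sch)
      ht$hr_bpm[ht$model == "M3"]
    }
    est(up) - est(base)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})
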