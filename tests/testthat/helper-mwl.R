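# Build an rr_series from a vector of RR intervals (ms), first beat at t0.
make_rr <- function(rr_ms, t0 = 0, artifact = NULL) {
  beats <- t0 + cumsum(c(0, rr_ms)) / 1000
  if (!is.null(artifact)) artifact <- c(FALSE, artifact)
  rr_series(beats, artifact = artifact)
}

# Scaled-down config: short sessions, no baseline, for fast structural tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 3,
         model_mean_duration_s = c(M1 = 40, M2 = 40, M3 = 60, M4 = 60),
         baseline_duration_s = 0,
         seed = 11),
    list(...)
  )
  do.call(sim_config, args)
}

# Long-format toy dataset for the split-plot ANOVA: 2 groups x 2 conditions
# x 3 subjects per group; F values frozen from an independent computation.
anova_toy <- function() {
  d <- expand.grid(participant_id = paste0("s", 1:6),
                   model = c("c1", "c2"), stringsAsFactors = FALSE)
  d$system <- rep(rep(c("g1", "g2"), each = 3), 2)
  d$value <- c(10, 11, 9, 13, 12, 14, 12, 14, 11, 18, 16, 17)
  d
}

# Split-plot F statistics via R's independent aov() QR path.
aov_oracle <- function(data) {
  d <- data
  d$participant_id <- factor(d$participant_id)
  d$model <- factor(d$model)
  d$system <- factor(d$system)
  fit <- summary(stats::aov(value ~ system * model + Error(participant_id),
                            data = d))
  s1 <- fit[["Error: participant_id"]][[1]]
  s2 <- fit[["Error: Within"]][[1]]
  c(between = s1["system", "F value"],
    within = s2["model", "F value"],
    interaction = s2["system:model", "F value"])
}

# Run-length brute force for AOI visit/revisit/dwell metrics.
aoi_brute_force <- function(labs, dur_ms, aoi) {
  sel <- labs == aoi
  visits <- 0L
  prev <- ""
  for (i in seq_along(labs)) {
    if (labs[i] == aoi && prev != aoi) visits <- visits + 1L
    prev <- labs[i]
  }
  list(n = sum(sel), dwell_ms = sum(dur_ms[sel]),
       revisits = max(visits - 1L, 0L))
}

# Gaze stream of pure fixations (200 ms) + saccades (50 ms) with given AOIs.
make_fix_stream <- function(aois, fix_ms = NULL, t0 = 0) {
  n <- length(aois)
  if (is.null(fix_ms)) fix_ms <- rep(200, n)
  starts <- t0 + cumsum(c(0, head(fix_ms, -1) + 50)) / 1000
  fix <- tibble::tibble(kind = "fixation", t_start_s = starts,
                        t_end_s = starts + fix_ms / 1000,
                        duration_ms = fix_ms, aoi = aois,
                        peak_velocity_deg_s = NA_real_)
  sac <- tibble::tibble(kind = "saccade",
                        t_start_s = fix$t_end_s[-n],
                        t_end_s = fix$t_end_s[-n] + 0.05,
                        duration_ms = 50, aoi = NA_character_,
                        peak_velocity_deg_s = 150)
  out <- rbind(fix, sac)
  out[order(out$t_start_s), ]
}
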