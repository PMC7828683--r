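#' Whole-session reference statistics for over/underload classification
#'
#' Weighted mean and population (divide-by-N) weighted standard deviation of
#' a signal over the concatenation of all model segments. The reference
#' deliberately covers the whole assembly time -- all four models, excluding
#' the seated baseline, artifacts and missing samples -- so the one-SD
#' thresholds are anchored to each participant's own working range.
#'
#' @param values Numeric signal values (heart rate in bpm or pupil diameter
#'   in mm).
#' @param weights Time credited to each value in seconds (HR windows use
#'   their stride span, pupil samples the sampling interval). Defaults to
#'   equal weights.
#' @param signal Optional label (`"HR"` or `"PR"`) stored on the result.
#' @param participant_id Optional id stored on the result.
#' @return A list of class `workload_reference` with `mean`, `sd`, `signal`,
#'   `participant_id`.
#' @export
#' @examples
#' reference_stats(c(90, 100), weights = c(3, 1))  # mean 92.5, sd 4.33
reference_stats <- function(values, weights = NULL, signal = NULL,
                            participant_id = NULL) {
  keep <- !is.na(values)
  values <- values[keep]
  if (is.null(weights)) weights <- rep(1, length(values))
  else weights <- weights[keep]
  stopifnot(length(weights) == length(values), all(weights >= 0))
  if (length(values) < 2) stop("need at least 2 values for a reference")
  if (sum(weights) == 0) stop("all weights are zero")
  m <- sum(weights * values) / sum(weights)
  s <- sqrt(sum(weights * (values - m)^2) / sum(weights))
  structure(list(mean = m, sd = s, signal = signal,
                 participant_id = participant_id),
            class = "workload_reference")
}

#' Classify signal values into workload states
#'
#' A value more than one reference SD above the reference mean is `over`
#' (mental overload), more than one SD below is `under`; everything else --
#' including values exactly at a threshold -- is `normal` (strict
#' inequalities).
#'
#' @param values Numeric signal values.
#' @param ref A [reference_stats()] result.
#' @return Factor with levels `under`, `normal`, `over` (`NA` values stay
#'   `NA`).
#' @export
classify_states <- function(values, ref) {
  out <- rep(NA_character_, length(values))
  ok <- !is.na(values)
  out[ok] <- ifelse(values[ok] > ref$mean + ref$sd, "over",
                    ifelse(values[ok] < ref$mean - ref$sd, "under",
                           "normal"))
  factor(out, levels = c("under", "normal", "over"))
}

#' Percentage of time per workload state
#'
#' `100 * (weighted time in state) / (total weighted time)`, so the three
#' percentages always partition 100.
#'
#' @param states Factor from [classify_states()].
#' @param weights Time credited to each value (s); defaults to equal
#'   weights.
#' @return A one-row tibble `under_pct`, `normal_pct`, `over_pct` (all `NA`
#'   with a warning when no time is credited).
#' @export
state_time_percentages <- function(states, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(states))
  stopifnot(length(weights) == length(states))
  ok <- !is.na(states) & !is.na(weights)
  total <- sum(weights[ok])
  if (length(states) == 0 || total <= 0) {
    undefined_value("state_time_percentages")
    return(tibble::tibble(under_pct = NA_real_, normal_pct = NA_real_,
                          over_pct = NA_real_))
  }
  pct <- function(lv) 100 * sum(weights[ok][states[ok] == lv]) / total
  tibble::tibble(under_pct = pct("under"), normal_pct = pct("normal"),
                 over_pct = pct("over"))
}

#' Heart-rate over/underload time percentages per model
#'
#' Runs the full state quantification for one participant: sliding heart
#' rate per model segment (windows never straddle segment boundaries), a
#' whole-assembly-time reference (windows weighted by their stride span),
#' strict one-SD classification, and percentage of time per state and model.
#'
#' @param rr An [rr_series()] (after [clean_rr()]).
#' @param schedule The participant's [build_schedule()] result.
#' @param window,stride Passed to [sliding_hr()].
#' @return A tibble `model`, `hr_bpm` (time-weighted segment mean),
#'   `under_pct`, `normal_pct`, `over_pct`.
#' @export
hr_state_table <- function(rr, schedule, window = 20, stride = 5) {
  segs <- schedule$segments
  per_seg <- lapply(seq_len(nrow(segs)), function(s) {
    sub <- rr[rr$t_beat_s >= segs$t_start_s[s] &
                rr$t_beat_s <= segs$t_end_s[s], ]
    if (nrow(sub)) {
      sub$rr_ms[1] <- NA
      sub$artifact[1] <- NA
    }
    hr <- suppressWarnings(sliding_hr(sub, window = window,
                                      stride = stride))
    hr$model <- rep(segs$model[s], nrow(hr))
    hr
  })
  all_hr <- dplyr::bind_rows(per_seg)
  if (!nrow(all_hr)) stop("no HR windows in any segment")
  ref <- reference_stats(all_hr$hr_bpm, all_hr$stride_span_s,
                         signal = "HR",
                         participant_id = schedule$participant_id)
  states <- classify_states(all_hr$hr_bpm, ref)
  dplyr::bind_rows(lapply(segs$model, function(m) {
    sel <- all_hr$model == m
    out <- state_time_percentages(states[sel], all_hr$stride_span_s[sel])
    w <- all_hr$stride_span_s[sel]
    tibble::tibble(model = m,
                   hr_bpm = if (any(sel))
                     sum(all_hr$hr_bpm[sel] * w) / sum(w) else NA_real_,
                   under_pct = out$under_pct,
                   normal_pct = out$normal_pct,
                   over_pct = out$over_pct)
  }))
}

#' Pupil over/underload time percentages per model
#'
#' Same quantification as [hr_state_table()] for the cleaned pupil trace;
#' samples carry equal weight (the sampling interval).
#'
#' @param clean Output of [preprocess_pupil()].
#' @param schedule The participant's [build_schedule()] result.
#' @return A tibble `model`, `pr_mm`, `under_pct`, `normal_pct`, `over_pct`.
#' @export
pupil_state_table <- function(clean, schedule) {
  segs <- schedule$segments
  model <- rep(NA_character_, nrow(clean))
  for (s in seq_len(nrow(segs))) {
    model[clean$t_s >= segs$t_start_s[s] &
            clean$t_s < segs$t_end_s[s]] <- segs$model[s]
  }
  keep <- !is.na(model) & !is.na(clean$diameter_mm)
  vals <- clean$diameter_mm[keep]
  model <- model[keep]
  ref <- reference_stats(vals, signal = "PR",
                         participant_id = schedule$participant_id)
  states <- classify_states(vals, ref)
  dplyr::bind_rows(lapply(segs$model, function(m) {
    sel <- model == m
    out <- state_time_percentages(states[sel])
    tibble::tibble(model = m,
                   pr_mm = if (any(sel)) mean(vals[sel]) else NA_real_,
                   under_pct = out$under_pct,
                   normal_pct = out$normal_pct,
                   over_pct = out$over_pct)
  }))
}
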