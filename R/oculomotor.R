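#' Preprocess a binocular pupil trace
#'
#' Per eye: samples outside the physiological diameter range or flagged
#' invalid are discarded; outliers are removed by a rolling-median rule
#' (deviation from the median over `median_window_s` seconds larger than
#' `outlier_dev_mm`); interior gaps up to `max_gap_s` are filled by linear
#' interpolation; leading and trailing gaps are never extrapolated. The two
#' cleaned eyes are then averaged sample-wise into a single diameter. When
#' one eye is missing and uninterpolable at a timestamp, the other eye is
#' used alone; when both are missing the sample stays `NA`.
#'
#' @param trace Tibble with columns `t_s`, `left_mm`, `right_mm`,
#'   `left_valid`, `right_valid` (as produced by [simulate_pupil()]).
#' @param max_gap_s Longest gap (s) that is interpolated.
#' @param outlier_dev_mm Outlier threshold on deviation from the rolling
#'   median.
#' @param median_window_s Rolling-median window length (s).
#' @param range_mm Admissible diameter range (mm).
#' @return A tibble `t_s`, `diameter_mm`, `interpolated` (logical: value at
#'   this timestamp relies on interpolation in at least one used eye).
#' @export
preprocess_pupil <- function(trace, max_gap_s = 1, outlier_dev_mm = 0.5,
                             median_window_s = 1, range_mm = c(1, 9)) {
  t_s <- trace$t_s
  dt <- stats::median(diff(t_s))
  clean_eye <- function(v, valid) {
    ok <- valid == 1 & !is.na(v) & v >= range_mm[1] & v <= range_mm[2]
    if (sum(ok) < 2) stop("fewer than 2 valid samples in one eye")
    # rolling median on a provisionally filled series as outlier reference
    filled <- stats::approx(t_s[ok], v[ok], xout = t_s, rule = 2)$y
    k <- max(3, round(median_window_s / dt))
    if (k %% 2 == 0) k <- k + 1
    k <- min(k, if (length(filled) %% 2 == 1) length(filled)
             else length(filled) - 1)
    med <- stats::runmed(filled, k, endrule = "median")
    ok <- ok & abs(v - med) <= outlier_dev_mm
    if (sum(ok) < 2) stop("fewer than 2 usable samples in one eye")
    out <- ifelse(ok, v, NA_real_)
    interp <- stats::approx(t_s[ok], v[ok], xout = t_s, rule = 1)$y
    # fill only interior gaps short enough to bridge
    runs <- rle(!ok)
    pos <- cumsum(c(1, runs$lengths))
    interp_flag <- rep(FALSE, length(v))
    for (r in seq_along(runs$lengths)) {
      if (!runs$values[r]) next
      i0 <- pos[r]; i1 <- pos[r] + runs$lengths[r] - 1
      if (i0 == 1 || i1 == length(v)) next  # leading/trailing gap
      gap <- t_s[i1 + 1] - t_s[i0 - 1]
      if (gap <= max_gap_s) {
        out[i0:i1] <- interp[i0:i1]
        interp_flag[i0:i1] <- TRUE
      }
    }
    list(value = out, interpolated = interp_flag)
  }
  left <- clean_eye(trace$left_mm, trace$left_valid)
  right <- clean_eye(trace$right_mm, trace$right_valid)
  both <- !is.na(left$value) & !is.na(right$value)
  diameter <- ifelse(both, (left$value + right$value) / 2,
                     ifelse(!is.na(left$value), left$value, right$value))
  interpolated <- !is.na(diameter) &
    ((both & (left$interpolated | right$interpolated)) |
       (!both & ifelse(!is.na(left$value), left$interpolated,
                       right$interpolated)))
  tibble::tibble(t_s = t_s, diameter_mm = diameter,
                 interpolated = interpolated)
}

#' Fixation and saccade summaries for one segment
#'
#' Events belong to the segment containing their start time (half-open
#' `[start, end)`).
#'
#' @param stream Gaze event tibble (see [simulate_gaze()]).
#' @param segment Numeric `c(start, end)` in seconds, or a one-row tibble
#'   with `t_start_s`, `t_end_s`.
#' @return A one-row tibble `mean_fd_ms`, `mean_spv_deg_s`, `n_fix`,
#'   `n_sacc`; means are `NA` when no event of that kind falls in the
#'   segment.
#' @export
segment_event_stats <- function(stream, segment) {
  seg <- segment_bounds(segment)
  ev <- stream[stream$t_start_s >= seg[1] & stream$t_start_s < seg[2], ]
  fix <- ev[ev$kind == "fixation", ]
  sac <- ev[ev$kind == "saccade", ]
  tibble::tibble(
    mean_fd_ms = if (nrow(fix)) mean(fix$duration_ms) else NA_real_,
    mean_spv_deg_s = if (nrow(sac)) mean(sac$peak_velocity_deg_s)
                     else NA_real_,
    n_fix = nrow(fix),
    n_sacc = nrow(sac)
  )
}

segment_bounds <- function(segment) {
  if (is.data.frame(segment)) {
    seg <- c(segment$t_start_s[1], segment$t_end_s[1])
  } else {
    seg <- as.numeric(segment)
  }
  stopifnot(length(seg) == 2, seg[2] > seg[1])
  seg
}

#' Mean pupil diameter per model segment
#'
#' Sample mean of the cleaned diameter over each segment of a schedule
#' (missing samples excluded).
#'
#' @param clean Output of [preprocess_pupil()].
#' @param schedule A [build_schedule()] result.
#' @return A tibble `model`, `pr_mm`, `n_samples`.
#' @export
pupil_segment_means <- function(clean, schedule) {
  segs <- schedule$segments
  dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(s) {
    hit <- clean$t_s >= segs$t_start_s[s] & clean$t_s < segs$t_end_s[s] &
      !is.na(clean$diameter_mm)
    tibble::tibble(model = segs$model[s],
                   pr_mm = if (any(hit)) mean(clean$diameter_mm[hit])
                           else NA_real_,
                   n_samples = sum(hit))
  }))
}
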