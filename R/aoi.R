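#' Default area-of-interest labels
#'
#' The five labelled workspace regions of the assembly station; fixations
#' outside them carry the implicit `background` label.
#'
#' @return Character vector of AOI labels.
#' @export
aoi_labels <- function() {
  c("assistance_system", "assembly_object", "assembly_parts", "tools",
    "assembly_tablet")
}

#' Per-AOI gaze-usage metrics for one segment
#'
#' For each AOI: dwell time (summed fixation time), dwell percentage of the
#' full segment duration, fixation count and share, average fixation
#' duration, and revisits. A *visit* is a maximal run of consecutive
#' fixations in the same AOI -- saccades between them never break a visit,
#' only a fixation in a different AOI does -- and `revisits = visits - 1`
#' (0 for unvisited AOIs). Background fixations count in the fixation-share
#' denominator but get no row unless `include_background = TRUE`.
#'
#' @param stream Gaze event tibble (see [simulate_gaze()]); fixations belong
#'   to the segment containing their start.
#' @param segment `c(start, end)` seconds or a one-row tibble with
#'   `t_start_s`, `t_end_s`.
#' @param aois Character vector of AOI labels to report.
#' @param include_background Also report the implicit background area.
#' @return A tibble with one row per AOI: `aoi`, `dwell_time_s`,
#'   `dwell_pct`, `n_fixations`, `fixation_pct`,
#'   `avg_fixation_duration_ms`, `revisits`.
#' @export
aoi_metrics <- function(stream, segment, aois = aoi_labels(),
                        include_background = FALSE) {
  seg <- segment_bounds(segment)
  seg_len <- seg[2] - seg[1]
  fix <- stream[stream$kind == "fixation" &
                  stream$t_start_s >= seg[1] & stream$t_start_s < seg[2], ]
  labs <- ifelse(is.na(fix$aoi) | !(fix$aoi %in% aois), "background",
                 fix$aoi)
  labs <- labs[order(fix$t_start_s)]
  dur <- fix$duration_ms[order(fix$t_start_s)]
  n_all <- length(labs)
  report <- if (include_background) c(aois, "background") else aois
  visits <- visit_counts(labs)
  dplyr::bind_rows(lapply(report, function(a) {
    sel <- labs == a
    n <- sum(sel)
    dwell_ms <- sum(dur[sel])
    n_visits <- visits[[a]] %||% 0L
    tibble::tibble(
      aoi = a,
      dwell_time_s = dwell_ms / 1000,
      dwell_pct = 100 * (dwell_ms / 1000) / seg_len,
      n_fixations = n,
      fixation_pct = if (n_all) 100 * n / n_all else 0,
      avg_fixation_duration_ms = if (n) dwell_ms / n else NA_real_,
      revisits = max(n_visits - 1L, 0L)
    )
  }))
}

# Number of maximal same-label runs per label in a fixation label sequence.
visit_counts <- function(labs) {
  if (!length(labs)) return(list())
  r <- rle(labs)
  out <- lapply(split(r$lengths, r$values), length)
  out
}

#' Dwell and fixation-share shift between two models
#'
#' Per-AOI differences (`to` minus `from`, by default M4 minus M1) of dwell
#' and fixation percentages, quantifying how gaze redistributes as assembly
#' complexity grows.
#'
#' @param metrics Tibble of [aoi_metrics()] rows carrying a `model` column
#'   (and optionally `participant_id`; rows are averaged per AOI and model
#'   first).
#' @param from,to Model labels to compare.
#' @return A tibble `aoi`, `delta_dwell_pct`, `delta_fixation_pct`.
#' @export
aoi_shift <- function(metrics, from = "M1", to = "M4") {
  if (!all(c(from, to) %in% metrics$model)) {
    stop(sprintf("both models (%s, %s) must be present", from, to))
  }
  avg <- dplyr::summarise(
    dplyr::group_by(metrics, .data$model, .data$aoi),
    dwell_pct = mean(.data$dwell_pct),
    fixation_pct = mean(.data$fixation_pct),
    .groups = "drop"
  )
  a <- avg[avg$model == from, ]
  b <- avg[avg$model == to, ]
  m <- merge(a, b, by = "aoi", suffixes = c("_from", "_to"))
  tibble::tibble(
    aoi = m$aoi,
    delta_dwell_pct = m$dwell_pct_to - m$dwell_pct_from,
    delta_fixation_pct = m$fixation_pct_to - m$fixation_pct_from
  )
}
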