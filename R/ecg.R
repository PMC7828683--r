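#' RR-interval series
#'
#' Container for beat times and RR intervals. RR intervals are defined as
#' `RR[i] = t[i] - t[i-1]` in milliseconds; the first beat carries no
#' interval. Artifact-flagged intervals stay in the table (so time accounting
#' is preserved) but are excluded from every indicator.
#'
#' @param t_beat_s Strictly increasing beat times in seconds.
#' @param artifact Optional logical per beat marking the interval *ending* at
#'   that beat as an artifact; defaults to all `FALSE`.
#' @return A tibble of class `rr_series` with columns `t_beat_s`, `rr_ms`,
#'   `artifact` (first row has `rr_ms = NA`).
#' @export
#' @examples
#' rr_series(c(0, 0.8, 1.65, 2.5))
rr_series <- function(t_beat_s, artifact = NULL) {
  stopifnot(is.numeric(t_beat_s))
  if (is.unsorted(t_beat_s, strictly = TRUE)) {
    stop("beat times must be strictly increasing")
  }
  n <- length(t_beat_s)
  rr_ms <- c(NA_real_, diff(t_beat_s) * 1000)
  if (is.null(artifact)) artifact <- rep(FALSE, n)
  stopifnot(length(artifact) == n)
  artifact[1] <- NA
  out <- tibble::tibble(t_beat_s = as.numeric(t_beat_s), rr_ms = rr_ms,
                        artifact = as.logical(artifact))
  class(out) <- c("rr_series", class(out))
  out
}

# Logical index of usable (clean) intervals.
clean_idx <- function(rr) {
  !is.na(rr$rr_ms) & !is.na(rr$artifact) & !rr$artifact
}

#' Detect R peaks in an ECG trace
#'
#' Dynamic-threshold moving-window detector: the rectified signal's rolling
#' upper quantile (envelope) over `window_s` seconds defines a local
#' threshold; strict local maxima above `threshold_coef` times that envelope
#' are peak candidates, and a refractory period keeps only the largest
#' candidate within any `refractory_s` span.
#'
#' @param trace A tibble with columns `t_s`, `amplitude` and attribute
#'   `sampling_rate_hz` (as produced by [render_ecg()]), or any uniformly
#'   sampled data frame with those columns.
#' @param threshold_coef Fraction of the local envelope a peak must exceed.
#' @param window_s Moving-window length for the envelope, seconds.
#' @param refractory_s Minimum separation between accepted peaks, seconds.
#' @param envelope_prob Quantile used for the envelope (1 = rolling maximum).
#' @return Strictly increasing numeric vector of beat times (s); empty for a
#'   flat trace.
#' @export
detect_r_peaks <- function(trace, threshold_coef = 0.5, window_s = 2,
                           refractory_s = 0.25, envelope_prob = 1) {
  t_s <- trace$t_s
  y <- trace$amplitude
  n <- length(y)
  fs <- attr(trace, "sampling_rate_hz") %||%
    (1 / stats::median(diff(t_s)))
  if (n / fs < 2) stop("trace must be at least 2 s long")
  if (all(y == y[1])) return(numeric(0))

  # envelope on a strided grid, interpolated back to every sample
  half <- round(window_s * fs / 2)
  stride <- max(1, round(fs / 8))
  centers <- unique(c(seq(1, n, by = stride), n))
  env <- vapply(centers, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::quantile(abs(y[lo:hi]), probs = envelope_prob, names = FALSE)
  }, numeric(1))
  thr <- stats::approx(centers, env, xout = seq_len(n), rule = 2)$y *
    threshold_coef

  i <- 2:(n - 1)
  cand <- i[y[i] > y[i - 1] & y[i] > y[i + 1] & y[i] > thr[i] & y[i] > 0]
  if (!length(cand)) return(numeric(0))

  # refractory: accept candidates from largest down, suppress neighbours
  cand <- cand[order(y[cand], decreasing = TRUE)]
  accepted <- numeric(0)
  min_gap <- refractory_s
  for (idx in cand) {
    tt <- t_s[idx]
    if (!length(accepted) || all(abs(accepted - tt) >= min_gap)) {
      accepted <- c(accepted, tt)
    }
  }
  sort(accepted)
}

#' Flag implausible RR intervals
#'
#' Automated surrogate for manual beat correction: flags intervals outside a
#' physiological range and intervals deviating from the running median of the
#' last `median_width` clean intervals by more than `max_rel_dev`. Flagged
#' intervals are marked `artifact = TRUE`, never deleted.
#'
#' @param rr An [rr_series()].
#' @param range_ms Admissible RR range in ms.
#' @param max_rel_dev Maximal relative deviation from the running median.
#' @param median_width Number of preceding clean intervals in the running
#'   median.
#' @return The series with updated `artifact` flags.
#' @export
clean_rr <- function(rr, range_ms = c(300, 2000), max_rel_dev = 0.3,
                     median_width = 11) {
  art <- rr$artifact
  x <- rr$rr_ms
  hist_buf <- numeric(0)
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    bad <- isTRUE(art[i])
    if (!bad && (x[i] < range_ms[1] || x[i] > range_ms[2])) bad <- TRUE
    if (!bad && length(hist_buf) >= 3) {
      med <- stats::median(hist_buf)
      if (abs(x[i] - med) / med > max_rel_dev) bad <- TRUE
    }
    art[i] <- bad
    if (!bad) {
      hist_buf <- c(hist_buf, x[i])
      if (length(hist_buf) > median_width) {
        hist_buf <- hist_buf[-1]
      }
    }
  }
  rr$artifact <- art
  rr
}

#' Sliding-window heart rate
#'
#' Continuous heart rate over windows of `window` consecutive clean RR
#' intervals advancing by `stride` intervals (the default 20-beat window with
#' 5-beat stride corresponds to 75% overlap). `HR = 60000 / mean(RR in
#' window)`; each window is stamped with the time of its last beat and carries
#' the duration covered by its stride (sum of the newest `stride` intervals),
#' used downstream as a time weight.
#'
#' @param rr An [rr_series()] (typically restricted to one model segment).
#' @param window,stride Window length and advance, in clean intervals.
#' @return A tibble `window_end_s`, `hr_bpm`, `stride_span_s`; zero rows (with
#'   a warning) when fewer than `window` clean intervals exist.
#' @export
sliding_hr <- function(rr, window = 20, stride = 5) {
  ok <- clean_idx(rr)
  vals <- rr$rr_ms[ok]
  ends <- rr$t_beat_s[ok]
  n <- length(vals)
  empty <- tibble::tibble(window_end_s = numeric(0), hr_bpm = numeric(0),
                          stride_span_s = numeric(0))
  if (n < window) {
    warning(sprintf("only %d clean RR intervals (< %d); empty HR series",
                    n, window), call. = FALSE)
    return(empty)
  }
  starts <- seq(1, n - window + 1, by = stride)
  tibble::tibble(
    window_end_s = ends[starts + window - 1],
    hr_bpm = vapply(starts, function(s) {
      60000 / mean(vals[s:(s + window - 1)])
    }, numeric(1)),
    stride_span_s = vapply(starts, function(s) {
      sum(vals[(s + window - stride):(s + window - 1)]) / 1000
    }, numeric(1))
  )
}

#' Root mean square of successive RR differences
#'
#' `RMSSD = sqrt(mean((RR[i+1] - RR[i])^2))` over pairs of adjacent clean
#' intervals; pairs spanning an artifact-flagged interval are dropped, not
#' bridged.
#'
#' @param rr An [rr_series()].
#' @return RMSSD in ms, or `NA` with a warning when fewer than two adjacent
#'   clean intervals exist.
#' @export
#' @examples
#' rmssd(rr_series(cumsum(c(0, rep(c(0.8, 0.85), 5)))))  # 50 ms
rmssd <- function(rr) {
  ok <- clean_idx(rr)
  d <- successive_diffs(rr$rr_ms, ok)
  if (length(d) < 1) return(undefined_value("rmssd"))
  sqrt(mean(d^2))
}

# Differences between adjacent clean intervals only.
successive_diffs <- function(x, ok) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  i <- seq_len(n - 1)
  keep <- ok[i] & ok[i + 1]
  (x[i + 1] - x[i])[keep]
}

#' Relative RR intervals
#'
#' The normalized successive RR change
#' `rr[i] = 2 * (RR[i] - RR[i-1]) / (RR[i] + RR[i-1]) * 100` (percent),
#' computed for adjacent clean interval pairs. Values with `|rr| >=
#' artifact_cut_pct` are flagged and excluded from [rrhrv()]. The series is
#' invariant under rescaling of all RR intervals, which makes the derived
#' rrHRV summary robust to overall heart-rate shifts.
#'
#' @param rr An [rr_series()].
#' @param artifact_cut_pct Exclusion threshold for the return map, percent.
#' @return A tibble `rr_rel_pct`, `retained`.
#' @export
relative_rr <- function(rr, artifact_cut_pct = 20) {
  ok <- clean_idx(rr)
  x <- rr$rr_ms
  n <- length(x)
  if (n < 3) {
    return(tibble::tibble(rr_rel_pct = numeric(0), retained = logical(0)))
  }
  i <- 2:(n - 1)
  keep <- ok[i] & ok[i + 1]
  prev <- x[i][keep]
  cur <- x[i + 1][keep]
  rel <- 2 * (cur - prev) / (cur + prev) * 100
  tibble::tibble(rr_rel_pct = rel, retained = abs(rel) < artifact_cut_pct)
}

#' rrHRV: variability of the relative-RR return map
#'
#' Builds return-map points `P[i] = (rr[i], rr[i+1])` from successive retained
#' relative-RR values and summarizes their spread as the median Euclidean
#' distance from the component-wise median point. Being built on relative RR,
#' the measure is unchanged by rescaling all RR intervals (overall heart-rate
#' shifts).
#'
#' @param x An [rr_series()], the output of [relative_rr()], or a numeric
#'   vector of retained relative-RR values (percent).
#' @return rrHRV in percent units, or `NA` with a warning when fewer than 3
#'   retained values exist.
#' @export
rrhrv <- function(x) {
  if (inherits(x, "rr_series")) x <- relative_rr(x)
  if (is.data.frame(x)) x <- x$rr_rel_pct[x$retained]
  stopifnot(is.numeric(x))
  if (length(x) < 3) return(undefined_value("rrhrv"))
  p1 <- x[-length(x)]
  p2 <- x[-1]
  cx <- stats::median(p1)
  cy <- stats::median(p2)
  stats::median(sqrt((p1 - cx)^2 + (p2 - cy)^2))
}
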