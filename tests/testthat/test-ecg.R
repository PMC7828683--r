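test_that("rr_series validates beat times and derives intervals", {
  rr <- rr_series(c(0, 0.8, 1.65))
  expect_equal(rr$rr_ms, c(NA, 800, 850))
  expect_error(rr_series(c(0, 1, 1)), "strictly increasing")
})

test_that("rmssd matches closed forms and hand calculations", {
  expect_equal(rmssd(make_rr(rep(800, 20))), 0)
  expect_equal(rmssd(make_rr(rep(c(800, 850), 10))), 50)
  expect_equal(rmssd(make_rr(c(800, 820, 790, 810))),
               sqrt((400 + 900 + 400) / 3))
  expect_warning(out <- rmssd(make_rr(800)), "too few")
  expect_true(is.na(out))
})

test_that("rmssd drops difference pairs spanning flagged intervals", {
  rr_ms <- c(800, 820, 1700, 810, 830)
  art <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  flagged <- make_rr(rr_ms, artifact = art)
  # only (800,820) and (810,830) remain adjacent clean pairs
  expect_equal(rmssd(flagged), sqrt((20^2 + 20^2) / 2))
})

test_that("relative RR follows the normalized-change formula", {
  rel <- relative_rr(make_rr(c(800, 800, 1000)))
  expect_equal(rel$rr_rel_pct, c(0, 2 * 200 / 1800 * 100))
  expect_equal(rel$retained, c(TRUE, FALSE))  # 22.22% >= 20% cut
})

test_that("relative RR and rrHRV are invariant under RR rescaling while
           rmssd scales and HR divides", {
  set.seed(42)
  base <- 800 + as.numeric(arima.sim(list(ar = 0.5), 60, sd = 15))
  for (k in c(0.5, 2, 3)) {
    a <- make_rr(base)
    b <- make_rr(k * base)
    expect_equal(relative_rr(b)$rr_rel_pct, relative_rr(a)$rr_rel_pct)
    expect_equal(rrhrv(b), rrhrv(a))
    expect_equal(rmssd(b), k * rmssd(a))
    expect_equal(sliding_hr(b)$hr_bpm, sliding_hr(a)$hr_bpm / k)
  }
})

test_that("indicators are invariant to shifting all beat times", {
  set.seed(7)
  base <- 850 + rnorm(50, 0, 20)
  a <- make_rr(base)
  b <- make_rr(base, t0 = 123.456)
  expect_equal(rmssd(a), rmssd(b))
  expect_equal(rrhrv(a), rrhrv(b))
  expect_equal(sliding_hr(a)$hr_bpm, sliding_hr(b)$hr_bpm)
})

test_that("rrHRV reproduces the brute-force regression fixture", {
  rr <- make_rr(c(800, 820, 790, 810, 805, 830, 795, 815, 800, 825))
  # frozen from an independent enumeration of the return map
  expect_equal(rrhrv(rr), 4.210737283616612, tolerance = 1e-12)
  expect_equal(rrhrv(make_rr(rep(900, 10))), 0)
  expect_warning(out <- rrhrv(c(1, 2)), "too few")
  expect_true(is.na(out))
})

test_that("sliding HR windows advance by 5 beats and use the window mean", {
  hr <- sliding_hr(make_rr(rep(1000, 100)))
  expect_equal(nrow(hr), 17)  # floor((100 - 20) / 5) + 1
  expect_true(all(hr$hr_bpm == 60))
  expect_equal(hr$stride_span_s, rep(5, 17))
  # alternating 500/1000 ms: mean 750 ms -> 80 bpm
  hr2 <- sliding_hr(make_rr(rep(c(500, 1000), 10)))
  expect_equal(hr2$hr_bpm, 80)
  expect_warning(empty <- sliding_hr(make_rr(rep(800, 10))), "clean RR")
  expect_equal(nrow(empty), 0)
})

test_that("sliding HR window count follows the closed form for n = 20..200", {
  for (n in seq(20, 200, by = 7)) {
    hr <- sliding_hr(make_rr(rep(900, n)))
    expect_equal(nrow(hr), floor((n - 20) / 5) + 1)
  }
})

test_that("sliding HR skips artifact-flagged intervals", {
  rr_ms <- rep(1000, 30)
  art <- rep(FALSE, 30)
  art[c(5, 15)] <- TRUE
  hr <- sliding_hr(make_rr(rr_ms, artifact = art))
  expect_equal(nrow(hr), floor((28 - 20) / 5) + 1)
  expect_true(all(hr$hr_bpm == 60))
})

test_that("clean_rr flags range violations and median outliers only", {
  smooth <- make_rr(seq(800, 900, length.out = 40))
  expect_false(any(clean_rr(smooth)$artifact[-1]))
  merged <- make_rr(c(rep(850, 10), 1700, rep(850, 10)))
  expect_equal(which(clean_rr(merged)$artifact), 12)
  short <- make_rr(c(rep(850, 5), 250, rep(850, 5)))
  expect_true(clean_rr(short)$artifact[7])
})

test_that("R-peak detection locates template beats and rejects flat traces", {
  tr <- render_ecg(1.0, sampling_rate_hz = 1000, noise_sd = 0,
                   t_range = c(0, 3))
  peaks <- detect_r_peaks(tr)
  expect_length(peaks, 1)
  expect_lt(abs(peaks - 1.0), 0.001)
  flat <- tibble::tibble(t_s = seq(0, 3, by = 0.001),
                         amplitude = 0)
  attr(flat, "sampling_rate_hz") <- 1000
  expect_length(detect_r_peaks(flat), 0)
  expect_error(detect_r_peaks(tr[1:100, ]), "2 s")
})

test_that("render + detect round-trips the generator RR within 2 ms RMS", {
  set.seed(5)
  rr_ms <- 1000 + as.numeric(arima.sim(list(ar = 0.6), 118, sd = 20))
  truth <- make_rr(rr_ms)
  tr <- render_ecg(truth, noise_sd = 0.05)
  beats <- detect_r_peaks(tr)
  expect_equal(length(beats), nrow(truth))
  rec <- rr_series(beats)
  err <- rec$rr_ms[-1] - truth$rr_ms[-1]
  expect_lt(sqrt(mean(err^2)), 2)
})
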