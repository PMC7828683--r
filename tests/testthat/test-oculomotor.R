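# 60 Hz binocular trace builder
make_trace <- function(left, right = left, lv = NULL, rv = NULL) {
  n <- length(left)
  tibble::tibble(t_s = (seq_len(n) - 1) / 60,
                 left_mm = left, right_mm = right,
                 left_valid = lv %||% rep(1L, n),
                 right_valid = rv %||% rep(1L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("binocular averaging is the sample-wise mean of both eyes", {
  tr <- make_trace(rep(3.0, 120), rep(3.4, 120))
  out <- preprocess_pupil(tr)
  expect_equal(out$diameter_mm, rep(3.2, 120))
  expect_false(any(out$interpolated))
})

test_that("interior gaps are linearly interpolated, edges are not", {
  left <- rep(3.0, 60)
  left[20:24] <- 0
  lv <- rep(1L, 60); lv[20:24] <- 0L
  left[19] <- 3.0; left[25] <- 3.6
  # make the surrounding ramp smooth enough not to trip the outlier rule
  left[26:60] <- 3.6
  tr <- make_trace(left, left, lv = lv, rv = lv)
  out <- preprocess_pupil(tr)
  expect_equal(out$diameter_mm[20:24], c(3.1, 3.2, 3.3, 3.4, 3.5))
  expect_true(all(out$interpolated[20:24]))
  # leading gap stays missing
  lv2 <- rep(1L, 60); lv2[1:5] <- 0L
  tr2 <- make_trace(rep(3.2, 60), lv = lv2, rv = lv2)
  out2 <- preprocess_pupil(tr2)
  expect_true(all(is.na(out2$diameter_mm[1:5])))
  expect_false(anyNA(out2$diameter_mm[6:60]))
})

test_that("gaps longer than max_gap_s are left missing", {
  lv <- rep(1L, 300)
  lv[100:180] <- 0L  # 81 samples = 1.35 s gap
  tr <- make_trace(rep(3.0, 300), lv = lv, rv = lv)
  out <- preprocess_pupil(tr)
  expect_true(all(is.na(out$diameter_mm[100:180])))
})

test_that("isolated outliers are removed and bridged", {
  left <- rep(3.0, 120)
  left[60] <- 4.4
  tr <- make_trace(left, rep(3.0, 120))
  out <- preprocess_pupil(tr)
  expect_equal(out$diameter_mm, rep(3.0, 120))
})

test_that("one-eye fallback keeps coverage when the other eye drops out", {
  lv <- rep(1L, 120)
  lv[50:120] <- 0L  # long trailing left-eye loss
  tr <- make_trace(rep(3.0, 120), rep(3.4, 120), lv = lv)
  out <- preprocess_pupil(tr)
  expect_equal(out$diameter_mm[1:49], rep(3.2, 49))
  expect_equal(out$diameter_mm[50:120], rep(3.4, 71))
})

test_that("preprocessing is idempotent and bounded by the two eyes", {
  cfg <- small_config(seed = 31)
  pp <- simulate_pupil(build_schedule(cfg, 1), cfg)
  out <- preprocess_pupil(pp)
  again <- preprocess_pupil(
    tibble::tibble(t_s = out$t_s, left_mm = out$diameter_mm,
                   right_mm = out$diameter_mm,
                   left_valid = as.integer(!is.na(out$diameter_mm)),
                   right_valid = as.integer(!is.na(out$diameter_mm))))
  expect_equal(again$diameter_mm, out$diameter_mm, tolerance = 1e-12)
  both <- pp$left_valid == 1 & pp$right_valid == 1 & !out$interpolated &
    !is.na(out$diameter_mm)
  lo <- pmin(pp$left_mm, pp$right_mm)[both]
  hi <- pmax(pp$left_mm, pp$right_mm)[both]
  expect_true(all(out$diameter_mm[both] >= lo - 1e-9 &
                    out$diameter_mm[both] <= hi + 1e-9))
})

test_that("cleaned trace converges to the ground-truth signal as noise
           vanishes", {
  errs <- vapply(c(0.1, 0.02, 0.002), function(sd) {
    cfg <- small_config(pupil_eye_noise_sd_mm = sd, outlier_rate = 0,
                        seed = 19)
    sch <- build_schedule(cfg, 1)
    pp <- simulate_pupil(sch, cfg)
    truth <- attr(pp, "truth")
    out <- preprocess_pupil(pp)
    ok <- !is.na(out$diameter_mm) & !out$interpolated
    sqrt(mean((out$diameter_mm[ok] - truth$signal_mm[ok])^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("segment event stats average the right events", {
  st <- make_fix_stream(rep("assembly_object", 2))
  expect_equal(segment_event_stats(st, c(0, 10))$mean_fd_ms, 200)
  st2 <- make_fix_stream(rep("tools", 3), fix_ms = c(150, 250, 230))
  out <- segment_event_stats(st2, c(0, 10))
  expect_equal(out$mean_fd_ms, 210)
  expect_equal(out$n_fix, 3)
  # a segment beyond all events: sentinels and zero counts
  empty <- segment_event_stats(st2, c(100, 110))
  expect_true(is.na(empty$mean_fd_ms) && is.na(empty$mean_spv_deg_s))
  expect_equal(empty$n_fix + empty$n_sacc, 0)
})

test_that("events partition across adjacent segments by start time", {
  set.seed(4)
  st <- make_fix_stream(sample(aoi_labels(), 40, replace = TRUE),
                        fix_ms = runif(40, 100, 400))
  cuts <- c(0, sort(runif(3, 0, max(st$t_end_s))), max(st$t_end_s) + 1)
  counts <- vapply(seq_len(4), function(k) {
    s <- segment_event_stats(st, c(cuts[k], cuts[k + 1]))
    s$n_fix + s$n_sacc
  }, numeric(1))
  expect_equal(sum(counts), nrow(st))
})
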