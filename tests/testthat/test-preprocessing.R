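# Baseline removal, R-peak detection, foot detection, ectopic exclusion
# and episode selection.

test_that("baseline removal attenuates the stop band and passes the beat band", {
  fs <- 1000
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  # constant (DC) is removed essentially exactly
  expect_lt(max(abs(remove_baseline(rep(2.5, length(t)), fs))), 1e-6)
  # slow wander at 0.02 Hz is strongly attenuated
  expect_lt(max(abs(remove_baseline(sin(2 * pi * 0.02 * t), fs))), 0.1)
  # a 1 Hz (beat-band) component passes with its amplitude preserved;
  # amplitude measured away from the documented edge-transient region
  y <- remove_baseline(sin(2 * pi * 1 * t), fs)
  interior <- y[(30 * fs):(length(y) - 30 * fs)]
  expect_lt(abs(max(abs(interior)) - 1), 0.05)
  expect_error(remove_baseline(numeric(0), fs), "non-empty")
})

test_that("R-peaks are recovered at the annotated samples", {
  tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0.01),
                             train_spec(n_beats = 12, seed = 6))
  r <- detect_r_peaks(tr$ecg, tr$fs)
  expect_length(r, 12)
  expect_true(all(abs(r - tr$truth$r_peaks) <= 2))
  expect_true(all(diff(r) > 0))
})

test_that("R-peak detection is scale invariant and rejects silence", {
  tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0.01),
                             train_spec(n_beats = 8, seed = 7))
  expect_identical(detect_r_peaks(tr$ecg, tr$fs),
                   detect_r_peaks(tr$ecg * 37.5, tr$fs))
  expect_error(detect_r_peaks(rep(0, 10000), 1000), "detection failed")
})

test_that("feet are localized near the annotated beat onsets", {
  # noiseless: every boundary within +/- 5 samples
  tr0 <- generate_pulse_train(pulse_ground_truth(noise_sd = 0),
                              train_spec(n_beats = 12, seed = 8))
  ann0 <- annotate_record(tr0)
  err0 <- ann0$beat_annotations$foot - tr0$truth$feet
  expect_true(all(abs(err0) <= 5))
  # at noise_sd 0.02 the onset corner is soft: the error median stays
  # within +/- 5 samples and no boundary drifts beyond 15
  errs <- unlist(lapply(1:4, function(s) {
    tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0.02),
                               train_spec(n_beats = 12, seed = 10 + s))
    ann <- annotate_record(tr)
    ann$beat_annotations$foot - tr$truth$feet
  }))
  expect_lte(median(abs(errs)), 5)
  expect_true(all(abs(errs) <= 15))
})

test_that("foot detection ignores constant offsets and flags falling windows", {
  tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0.01),
                             train_spec(n_beats = 10, seed = 9))
  rapw <- remove_baseline(tr$rapw, tr$fs)
  r <- detect_r_peaks(remove_baseline(tr$ecg, tr$fs), tr$fs)
  expect_equal(detect_pulse_feet(rapw, tr$fs, r),
               detect_pulse_feet(rapw + 11.3, tr$fs, r))
  # monotonically decreasing signal has no rising edge anywhere
  fall <- seq(1, 0, length.out = 8000)
  feet <- detect_pulse_feet(fall, 1000, r_peaks = c(1000, 2800, 4600, 6400))
  expect_true(all(is.na(feet)))
})

test_that("ectopic exclusion flags the beats bounding an anomalous interval", {
  # perfectly regular rhythm: nothing flagged
  r <- seq(0, by = 800, length.out = 15)
  expect_false(any(exclude_ectopic(r)))
  # one interval shortened by 40%: its two bounding beats are flagged
  r2 <- cumsum(c(0, rep(800, 5), 480, rep(800, 7)))
  mask <- exclude_ectopic(r2)
  expect_equal(which(mask), c(6L, 7L))
  expect_error(exclude_ectopic(c(0, 800)), "at least 3")
})

test_that("small physiological RR jitter is almost never flagged", {
  flagged <- vapply(1:60, function(s) {
    set.seed(s)
    rr <- rnorm(14, 0.8, 0.008)      # 1% jitter
    any(exclude_ectopic(cumsum(c(0, rr)) * 1000))
  }, logical(1))
  expect_gte(mean(!flagged), 0.99)
})

test_that("episode selection returns the earliest clean run", {
  rapw <- as.numeric(1:15000)
  feet <- seq(0, by = 1000, length.out = 15)
  # 12 feet, no flags: episodes are beats 1..10 (feet 1..11 consumed)
  sel <- segment_and_select(rapw, feet[1:12], rep(FALSE, 12), k = 10)
  expect_equal(sel$start_beat, 1)
  expect_length(sel$episodes, 10)
  expect_equal(lengths(sel$episodes), rep(1000L, 10))
  # a flagged third beat in 15 pushes the run to beat 4
  mask <- rep(FALSE, 15); mask[3] <- TRUE
  sel2 <- segment_and_select(rapw, feet, mask, k = 10)
  expect_equal(sel2$start_beat, 4)
  # too few clean beats: informative selection error
  expect_error(segment_and_select(rapw, feet[1:10], rep(FALSE, 10), k = 10),
               "longest clean run: 9")
})

test_that("episode concatenation reproduces the spanned segment exactly", {
  tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0.01),
                             train_spec(n_beats = 13, seed = 12))
  ann <- annotate_record(tr)
  sel <- segment_and_select(ann$rapw, ann$beat_annotations$foot,
                            ann$beat_annotations$ectopic, k = 10)
  span <- ann$rapw[(sel$feet_used[1] + 1):sel$feet_used[11]]
  expect_identical(unlist(sel$episodes), span)
})
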