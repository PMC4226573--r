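# Synthetic episode, train and cohort generators.

test_that("zero-noise episode equals the model curve exactly", {
  gt <- example_truth(noise_sd = 0)
  ep <- generate_pulse_episode(gt, 1000, seed = 1)
  expect_identical(ep, model_curve(gt))
  expect_equal(max(abs(ep - model_curve(gt))), 0)
})

test_that("the early-episode maximum matches a brute-force scan", {
  # the superimposed curve peaks after C1 because the second sub-wave's
  # left flank adds to the first; the brute-force scan is the oracle
  gt <- example_truth(noise_sd = 0)
  ep <- generate_pulse_episode(gt, 1000, seed = 1)
  best_n <- 1; best_v <- -Inf
  for (n in 1:200) {
    v <- 0
    for (k in 1:3) v <- v + gt$H[k] * exp(-(n - gt$C[k])^2 / (2 * gt$W[k]^2))
    if (v > best_v) { best_v <- v; best_n <- n }
  }
  expect_equal(which.max(ep[1:200]), best_n)
  expect_equal(best_n, 171)   # frozen from the scan above
  expect_true(all(ep[best_n] >= ep[1:200]))
})

test_that("episode noise is reproducible from the seed", {
  gt <- example_truth(noise_sd = 0.01)
  expect_identical(generate_pulse_episode(gt, 1000, seed = 7),
                   generate_pulse_episode(gt, 1000, seed = 7))
  expect_false(identical(generate_pulse_episode(gt, 1000, seed = 7),
                         generate_pulse_episode(gt, 1000, seed = 8)))
})

test_that("train ground-truth feet are strictly increasing, one per beat", {
  tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0),
                             train_spec(n_beats = 12, seed = 2))
  expect_length(tr$truth$feet, 12)
  expect_true(all(diff(tr$truth$feet) > 0))
  expect_length(tr$ecg, length(tr$rapw))
})

test_that("an ectopic beat shortens exactly one interval by 40%", {
  tr <- generate_pulse_train(pulse_ground_truth(noise_sd = 0),
                             train_spec(n_beats = 12, rr_jitter_sd = 0.005,
                                        ectopic_beats = 5L, seed = 3))
  rr <- diff(tr$truth$feet)
  short <- rr <= 0.62 * median(rr)
  expect_equal(sum(short), 1L)
  expect_equal(which(short), 5L)
})

test_that("baseline wander in the train is removed to within tolerance", {
  gt_w <- pulse_ground_truth(noise_sd = 0, baseline_amp = 0.2, baseline_freq = 0.02)
  gt_0 <- pulse_ground_truth(noise_sd = 0, baseline_amp = 1e-9, baseline_freq = 0.02)
  spec <- train_spec(n_beats = 12, seed = 4)
  with_w <- generate_pulse_train(gt_w, spec)
  without <- generate_pulse_train(gt_0, spec)
  clean_w <- remove_baseline(with_w$rapw, with_w$fs)
  clean_0 <- remove_baseline(without$rapw, without$fs)
  expect_lt(max(abs(clean_w - clean_0)), 0.05)
})

test_that("cohort cells have the specified sizes and 190 subjects total", {
  coh <- generate_cohort(reference_cohort_spec(seed = 1))
  expect_equal(nrow(coh), 190)
  counts <- as.vector(t(table(coh$sex, coh$sbp_category)))
  expect_equal(counts, c(22, 29, 33, 21, 17, 25, 25, 18))
  # factor labels partition the rows
  expect_false(any(is.na(coh$sex)) || any(is.na(coh$sbp_category)))
})

test_that("cohort sampling is deterministic and respects cell means", {
  expect_identical(generate_cohort(reference_cohort_spec(seed = 5)),
                   generate_cohort(reference_cohort_spec(seed = 5)))
  # degenerate SDs reproduce the cell means exactly
  spec <- reference_cohort_spec(seed = 1)
  sds <- grep("_sd$", names(spec$cells))
  spec$cells[sds] <- 0
  coh <- generate_cohort(spec)
  men_low <- coh[coh$sex == "men" & coh$sbp_category == "<=110", ]
  expect_true(all(men_low$C_ref_forw == 124))
  expect_true(all(men_low$H1 == 0.73))
  # with real SDs the cell mean stays within normal-theory bounds
  # (124 +/- 3 * 16 / sqrt(22)) for almost every seed
  hits <- vapply(1:40, function(s) {
    x <- generate_cohort(reference_cohort_spec(seed = s))
    m <- mean(x$C_ref_forw[x$sex == "men" & x$sbp_category == "<=110"])
    abs(m - 124) <= 3 * 16 / sqrt(22)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort SBP draws are consistent with their category label", {
  coh <- generate_cohort(reference_cohort_spec(seed = 9))
  expect_equal(as.character(assign_sbp_category(coh$sbp)),
               as.character(coh$sbp_category))
})

test_that("negative SDs and malformed specs are rejected", {
  spec <- reference_cohort_spec()
  cells <- spec$cells
  cells$C1_sd[1] <- -1
  expect_error(cohort_spec(cells), "SD")
  expect_error(cohort_spec(data.frame(sex = "men")), "data frame with columns")
})

test_that("record round-trips through CSV with its sidecar", {
  tr <- generate_pulse_train(pulse_ground_truth(), train_spec(n_beats = 4, seed = 1))
  path <- file.path(tempdir(), "rec.csv")
  write_raw_record(tr, path)
  back <- read_raw_record(path)
  expect_equal(back$fs, tr$fs)
  expect_equal(back$rapw, tr$rapw, tolerance = 1e-12)
  expect_equal(back$truth$feet, tr$truth$feet)
  unlink(c(path, paste0(path, ".json")))
  expect_error(read_raw_record(file.path(tempdir(), "absent.csv")), "not found")
})
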