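test_that("default schedule has the TOVA structure: 648 trials, 324 targets, 21.6 min", {
  s <- make_schedule(cohort_spec(), seed = 1)
  tr <- s$trials
  expect_equal(nrow(tr), 648)
  expect_equal(sum(tr$stimulus == "target"), 324)
  expect_equal(nrow(tr) * s$trial_period / 60, 21.6)
  # constant inter-onset interval, duration = n * period
  expect_equal(unique(diff(tr$onset_s)), 2)
  expect_equal(tr$onset_s[1], 0)
  # quarter target counts follow the infrequent/frequent halves
  counts <- tapply(tr$stimulus == "target", tr$quarter, sum)
  expect_equal(as.numeric(counts), c(36, 36, 126, 126))
  expect_equal(as.numeric(table(tr$quarter)), rep(162, 4))
})

test_that("degenerate all-target schedule has onsets 0,2,4,6", {
  spec <- cohort_spec(n_trials = 4, n_targets = 4)
  s <- make_schedule(spec, seed = 3)
  expect_equal(s$trials$onset_s, c(0, 2, 4, 6))
  expect_true(all(s$trials$stimulus == "target"))
})

test_that("infeasible quarter ratios raise an error naming the quarter", {
  spec <- cohort_spec(n_trials = 648, n_targets = 324,
                      quarter_target_ratios = c(1, 0, 0, 0))
  expect_error(make_schedule(spec), "quarter 1")
  spec0 <- cohort_spec(quarter_target_ratios = c(0, 0, 0, 0))
  expect_error(make_schedule(spec0), "zero")
})

test_that("schedule randomization is seed-deterministic and quarter-local", {
  spec <- cohort_spec()
  s1 <- make_schedule(spec, seed = 11)
  s2 <- make_schedule(spec, seed = 11)
  s3 <- make_schedule(spec, seed = 12)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$trials$stimulus, s3$trials$stimulus))
})

test_that("noiseless and fully-omitting responders behave as configured", {
  s <- make_schedule(cohort_spec(n_trials = 40, n_targets = 20), seed = 2)
  perfect <- simulate_responses(s, control_profile(omission_rate = 0,
                                                   commission_rate = 0), seed = 1)
  expect_equal(sum(perfect$trials$classification == "target_correct"), 20)
  expect_equal(sum(perfect$trials$classification == "commission"), 0)
  blind <- simulate_responses(s, control_profile(omission_rate = 1), seed = 1)
  expect_equal(sum(blind$trials$classification == "target_correct"), 0)
  expect_equal(sum(blind$trials$classification == "omission"), 20)
  lat <- perfect$trials$press_latency_ms[perfect$trials$stimulus == "target"]
  expect_true(all(lat >= 100 & lat <= 1900))
})

test_that("empirical omission rate converges to the profile rate (binomial check)", {
  s <- make_schedule(cohort_spec(), seed = 5)
  prof <- mdd_profile()  # omission 7.29%
  n_seeds <- 400
  om <- vapply(seq_len(n_seeds), function(k) {
    ses <- simulate_responses(s, prof, seed = k)
    mean(ses$trials$classification[ses$trials$stimulus == "target"] == "omission")
  }, numeric(1))
  p <- prof$omission_rate
  mc_se <- sqrt(p * (1 - p) / (n_seeds * 324))
  expect_lt(abs(mean(om) - p), 5 * mc_se)
})

test_that("clean recordings have line power far below alpha power", {
  spec <- cohort_spec(fs = 256, rest_duration = 40,
                      control = control_profile(blink_rate = 0,
                                                drift_amplitude = 0,
                                                line_amplitude = 0))
  rec <- simulate_recording(NULL, spec$control, spec, seed = 4)
  p60 <- mean(apply(rec$data, 1, periodogram_band, fs = 256, lo = 59, hi = 61))
  palpha <- mean(apply(rec$data, 1, periodogram_band, fs = 256, lo = 8, hi = 12))
  expect_lt(10 * log10(p60 / palpha), -40)
})

test_that("per-channel band power matches the profile within 10% at 300 s", {
  spec <- crossover_spec(fs = 256, rest_duration = 300, seed = 7)
  rec <- simulate_recording(NULL, spec$control, spec, seed = 7)
  bp <- spec$control$band_power_profile
  for (b in seq_along(qeeg_bands())) {
    band <- qeeg_bands()[[b]]
    est <- apply(rec$data, 1, periodogram_band, fs = 256,
                 lo = band[1], hi = band[2])
    expect_lt(max(abs(est / bp[, b] - 1)), 0.10)
  }
})

test_that("recordings with line/drift/blink carry those artifact signatures", {
  spec <- cohort_spec(fs = 256, rest_duration = 40,
                      control = control_profile(blink_rate = 20,
                                                drift_amplitude = 20,
                                                line_amplitude = 10))
  rec <- simulate_recording(NULL, spec$control, spec, seed = 8)
  # 60 Hz present
  p60 <- periodogram_band(rec$data[1, ], 256, 59.5, 60.5)
  expect_gt(p60, 1)
  # drift present below 0.5 Hz
  pdrift <- periodogram_band(rec$data[1, ], 256, 0.01, 0.5)
  expect_gt(pdrift, 50)
  # blinks load frontal channels hardest
  blink <- rec$aux$blink
  expect_gt(abs(cor(rec$data["Fp1", ], blink)), abs(cor(rec$data["Pz", ], blink)))
})

test_that("simulate_recording is a pure function of (inputs, seed)", {
  spec <- quick_spec()
  r1 <- simulate_recording(NULL, spec$control, spec, seed = 42)
  r2 <- simulate_recording(NULL, spec$control, spec, seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(NULL, spec$control, spec, seed = 43)
  expect_false(identical(r1$data, r3$data))
})

test_that("generate_cohort produces the configured arms and is reproducible", {
  spec <- quick_spec(seed = 9)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$subjects), 4)
  expect_equal(sum(co$subjects$group == "control"), 2)
  expect_length(co$recordings, 4)
  expect_equal(co$recordings[[1]]$resting$state_tag, "resting")
  expect_equal(co$recordings[[1]]$tova$state_tag, "tova")
  # patient-only cohort is fine
  co0 <- generate_cohort(crossover_spec(n_control = 0, n_patient = 1, fs = 64,
                                        n_trials = 4, n_targets = 2,
                                        rest_duration = 10, seed = 2))
  expect_equal(nrow(co0$subjects), 1)
  expect_equal(co0$subjects$group, "mdd")
  # same seed -> byte-identical manifests
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort_subject streams the same subjects generate_cohort stores", {
  spec <- quick_spec(seed = 31)
  co <- generate_cohort(spec)
  sub2 <- cohort_subject(spec, 2)
  expect_identical(co$recordings[[sub2$subject_id]]$tova$data, sub2$tova$data)
  expect_identical(co$sessions[[sub2$subject_id]]$trials, sub2$session$trials)
})
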