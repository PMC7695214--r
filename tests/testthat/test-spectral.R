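test_that("band power of a pure 6 Hz tone lands in theta with A^2/2 scaling", {
  A <- 3
  ts <- make_trialset(function(e, nc, ns)
    matrix(rep(A * sin(2 * pi * 6 * seq_len(ns) / 256), each = nc), nc),
    n_epochs = 2)
  bp <- band_power(ts)
  expect_lt(max(abs(bp[, , "theta"] / (A^2 / 2) - 1)), 0.02)
  for (b in c("delta", "alpha", "beta"))
    expect_lt(max(bp[, , b]), 0.01 * min(bp[, , "theta"]))
})

test_that("band power is zero for silence and flat for white noise", {
  ts0 <- make_trialset(function(e, nc, ns) matrix(0, nc, ns), n_epochs = 1)
  expect_true(all(band_power(ts0) == 0))
  set.seed(4)
  tsw <- make_trialset(function(e, nc, ns) matrix(rnorm(nc * ns), nc),
                       n_epochs = 200, n_ch = 2)
  bp <- apply(band_power(tsw), 3, mean)
  # flat spectrum: power proportional to the number of 0.5 Hz bins per
  # half-open band (delta [1,4) holds 6, the 4 Hz-wide bands hold 8)
  per_bin <- bp / c(delta = 6, theta = 8, alpha = 8, beta = 8)
  expect_lt(max(abs(per_bin / mean(per_bin) - 1)), 0.05)
  ts_short <- trial_set(array(0, c(2, 100, 1)), "resting", 256, c("A", "B"))
  expect_error(band_power(ts_short), "1 s")
})

test_that("condition aggregation averages epochs and normalizes per channel", {
  ep <- array(0, c(2, 512, 3))
  ep[, , 1] <- matrix(sin(2 * pi * 6 * seq_len(512) / 256), 2, 512, byrow = TRUE)
  ep[, , 2] <- 3 * ep[, , 1]  # power 9p
  ep[, , 3] <- ep[, , 1]
  ts <- trial_set(ep, c("target_correct", "target_correct", "omission"),
                  256, c("A", "B"))
  bp <- band_power(ts, taper = "none")
  one <- aggregate_condition(bp, ts$classes, "omission")
  expect_equal(one$abs, bp[3, , ], ignore_attr = TRUE)
  two <- aggregate_condition(bp, ts$classes, "target_correct")
  expect_equal(two$abs, (bp[1, , ] + bp[2, , ]) / 2, ignore_attr = TRUE)
  expect_equal(unname(rowSums(two$rel)), c(1, 1))
  expect_error(aggregate_condition(bp, ts$classes, "resting"), "no epochs")
  # zero-power channel has undefined relative power
  ep0 <- ep; ep0[2, , ] <- 0
  ts0 <- trial_set(ep0, ts$classes, 256, c("A", "B"))
  agg0 <- aggregate_condition(band_power(ts0), ts0$classes, "target_correct")
  expect_true(all(is.na(agg0$rel[2, ])))
})

test_that("neighbor averaging reproduces the documented F3 rule", {
  m <- matrix(0, 19, 1, dimnames = list(tova_montage(), "theta"))
  m["F3", 1] <- 10
  out <- neighbor_average(m)
  expect_equal(out["F3", 1], 2)  # (10 + 0 + 0 + 0 + 0) / 5
  # the F3 contribution also spreads into each of its neighbors' means
  expect_equal(out["Fz", 1], 10 / 6)  # Fz has 5 neighbors
  # constant field is a fixed point
  cm <- matrix(4.2, 19, 4, dimnames = list(tova_montage(), names(qeeg_bands())))
  expect_equal(neighbor_average(cm), cm)
})

test_that("neighbor averaging validates the adjacency map", {
  m <- matrix(1, 19, 1, dimnames = list(tova_montage(), "theta"))
  bad <- default_adjacency(); bad$F3 <- c(bad$F3, "XX")
  expect_error(neighbor_average(m, bad), "XX")
  asym <- default_adjacency(); asym$F3 <- setdiff(asym$F3, "Fp1")
  expect_error(neighbor_average(m, asym), "symmetric")
  # empty neighbor list leaves the channel unchanged
  iso <- default_adjacency()
  for (nb in iso$O2) iso[[nb]] <- setdiff(iso[[nb]], "O2")
  iso$O2 <- character(0)
  m2 <- matrix(rnorm(19), 19, 1, dimnames = list(tova_montage(), "theta"))
  expect_equal(neighbor_average(m2, iso)["O2", 1], m2["O2", 1])
})

test_that("the default adjacency is symmetric with no self-neighbors", {
  expect_silent(qeegtova:::validate_adjacency(default_adjacency()))
})

test_that("z-scores and cordance satisfy their algebra", {
  abs_r <- matrix(rep(c(2, -2), c(10, 9)) * 3 + 5, 19, 1,
                  dimnames = list(tova_montage(), "theta"))
  rel_r <- matrix(0.25, 19, 1, dimnames = list(tova_montage(), "theta"))
  z <- zscore_cordance(abs_r, rel_r)
  # two-point pattern maps to a two-level z pattern with population SD
  mu <- mean(abs_r); s <- sqrt(mean((abs_r - mu)^2))
  expect_equal(z$z_abs[, 1], (abs_r[, 1] - mu) / s)
  # uniform relative power -> z_rel undefined -> NA propagates
  expect_true(all(is.na(z$z_rel)))
  # random tables: z columns have mean 0, population SD 1; cordance sums
  set.seed(2)
  a <- matrix(rexp(19 * 4), 19, 4, dimnames = list(tova_montage(), names(qeeg_bands())))
  r <- matrix(runif(19 * 4), 19, 4, dimnames = dimnames(a))
  z2 <- zscore_cordance(a, r)
  expect_lt(max(abs(colMeans(z2$z_abs))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(z2$z_abs^2)) - 1)), 1e-10)
  expect_equal(z2$cordance, z2$z_abs + z2$z_rel)
  expect_lt(max(abs(colMeans(z2$cordance))), 1e-10)
})

test_that("cordance is invariant to a global gain change", {
  spec <- quick_spec(seed = 21)
  sub <- cohort_subject(spec, 1)
  ts <- resting_segment(sub$resting, spec$trial_period)
  t1 <- cordance_table(ts, "resting")
  ts10 <- ts; ts10$epochs <- ts$epochs * 10
  t2 <- cordance_table(ts10, "resting")
  expect_lt(max(abs(t2$cordance - t1$cordance)), 1e-6)
})

test_that("elevated frontal theta in the patient profile raises F7 theta cordance", {
  spec <- cohort_spec(n_control = 6, n_patient = 6, fs = 64, rest_duration = 40,
                      n_trials = 4, n_targets = 2,
                      control = control_profile(blink_rate = 0, drift_amplitude = 0,
                                                line_amplitude = 0),
                      patient = mdd_profile(blink_rate = 0, drift_amplitude = 0,
                                            line_amplitude = 0),
                      seed = 5)
  f7 <- sapply(seq_len(12), function(i) {
    sub <- cohort_subject(spec, i)
    ts <- resting_segment(sub$resting, spec$trial_period)
    ct <- cordance_table(ts, "resting")
    ct$cordance[ct$channel == "F7" & ct$band == "theta"]
  })
  expect_gt(mean(f7[7:12]), mean(f7[1:6]))
})
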