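# Independent oracles used across the suite. These deliberately use naive
# formulations (double loops, direct FFT sums) so they stay independent of
# the implementation paths they check.

# literal O(n^2) enumeration of the mean pattern-match fraction
apen_brute <- function(x, m, r, self_matches = TRUE, chebyshev = TRUE) {
  n <- length(x)
  nw <- n - m + 1
  total <- 0
  for (i in seq_len(nw)) {
    for (j in seq_len(nw)) {
      if (!self_matches && i == j) next
      d <- x[i:(i + m - 1)] - x[j:(j + m - 1)]
      dist <- if (chebyshev) max(abs(d)) else sqrt(sum(d^2))
      if (dist < r) total <- total + 1
    }
  }
  total / (nw * nw)
}

# plain one-sided periodogram band power (rectangular window, Parseval
# normalized so a full-scale sinusoid of amplitude A has power A^2/2)
periodogram_band <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- abs(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  mult <- ifelse(f == 0 | abs(f - fs / 2) < 1e-12, 1, 2)
  sum((p * mult)[half & f >= lo & f < hi])
}

# fixed-length epoch set built directly from a signal generator function
make_trialset <- function(gen, n_epochs, fs = 256, trial_period = 2,
                          n_ch = 19, classes = rep("resting", n_epochs)) {
  spt <- round(trial_period * fs)
  ep <- array(0, dim = c(n_ch, spt, n_epochs))
  for (e in seq_len(n_epochs)) ep[, , e] <- gen(e, n_ch, spt)
  trial_set(ep, classes, fs, tova_montage()[seq_len(n_ch)])
}

# small artifact-free cohort spec used by several modules
quick_spec <- function(..., seed = 1L) {
  crossover_spec(n_control = 2, n_patient = 2, fs = 64, n_trials = 8,
                 n_targets = 4, rest_duration = 20, seed = seed, ...)
}
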