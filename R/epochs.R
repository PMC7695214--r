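#' Trial set container
#'
#' Fixed-length epochs cut from a recording: a channels x samples x trials
#' array plus a per-epoch class label (`target_correct`, `nontarget_correct`,
#' `omission`, `commission`, or `resting`).
#'
#' @param epochs 3D array, channels x samples_per_trial x n_epochs.
#' @param classes Character vector of per-epoch labels.
#' @param fs Sampling rate, Hz.
#' @param labels Channel labels.
#' @param subject_id,state_tag Carried over from the recording.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(epochs, classes, fs, labels,
                      subject_id = NA_character_, state_tag = "tova") {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[3] == length(classes),
            dim(epochs)[1] == length(labels))
  structure(list(epochs = epochs, classes = classes, fs = fs,
                 labels = labels, samples_per_trial = dim(epochs)[2],
                 subject_id = subject_id, state_tag = state_tag),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d epochs of %d x %d (%s)\n",
              dim(x$epochs)[3], dim(x$epochs)[1], dim(x$epochs)[2], x$state_tag))
  tab <- table(x$classes)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Partition a task recording into per-trial epochs
#'
#' Cuts one epoch per trial, starting at the stimulus onset and lasting the
#' inter-stimulus period (half-open window, so 2 s at 256 Hz gives exactly
#' 19 x 512 epochs). The response classification is copied from the session.
#'
#' @param rec A task-state [eeg_recording()].
#' @param session A [tova_session()] with responses.
#' @return A [trial_set()].
#' @export
segment <- function(rec, session) {
  tr <- session$trials
  if (!("classification" %in% names(tr)))
    stop("session has no responses; run simulate_responses() first")
  spt <- round(session$trial_period * rec$fs)
  n_ch <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  starts <- round(tr$onset_s * rec$fs) + 1L
  ends <- starts + spt - 1L
  too_late <- which(ends > n_samp)
  if (length(too_late) > 0)
    stop("trial ", tr$trial_index[too_late[1]],
         " extends beyond the recording end (needs sample ", ends[too_late[1]],
         " of ", n_samp, ")")
  epochs <- array(0, dim = c(n_ch, spt, nrow(tr)))
  for (i in seq_len(nrow(tr)))
    epochs[, , i] <- rec$data[, starts[i]:ends[i]]
  trial_set(epochs, tr$classification, rec$fs, rec$labels,
            subject_id = rec$subject_id, state_tag = "tova")
}

#' Cut a resting recording into consecutive windows
#'
#' The resting baseline is split into consecutive non-overlapping windows of
#' the same length as task trials (default 2 s), all labeled `resting`; a
#' trailing remainder shorter than one window is dropped.
#'
#' @param rec A resting-state [eeg_recording()].
#' @param trial_period Window length in seconds.
#' @param min_duration Minimum recording length in seconds.
#' @return A [trial_set()].
#' @export
resting_segment <- function(rec, trial_period = 2.0,
                            min_duration = trial_period) {
  if (duration_s(rec) < min_duration)
    stop("resting recording too short: ", round(duration_s(rec), 2),
         " s < ", min_duration, " s")
  spt <- round(trial_period * rec$fs)
  n_win <- floor(ncol(rec$data) / spt)
  if (n_win < 1) stop("recording shorter than one window")
  epochs <- array(rec$data[, seq_len(n_win * spt)],
                  dim = c(nrow(rec$data), spt, n_win))
  trial_set(epochs, rep("resting", n_win), rec$fs, rec$labels,
            subject_id = rec$subject_id, state_tag = "resting")
}

#' Behavioral TOVA scores
#'
#' The five TOVA metrics: omission rate (% of targets without a press),
#' commission rate (% of nontargets with a press), mean response time and
#' response-time variability (mean and SD of correct-target latencies, ms),
#' and d-prime (difference of normal quantiles of hit and false-alarm
#' rates, each clipped to `[1/(2N), 1 - 1/(2N)]` before the quantile).
#'
#' @param session A [tova_session()] with responses.
#' @return A one-row data frame with columns `omission_rate`,
#'   `commission_rate`, `mean_rt`, `rt_variability`, `d_prime` (rates in
#'   percent; `mean_rt`/`rt_variability` are `NA` when no correct target
#'   exists).
#' @export
score_tova <- function(session) {
  tr <- session$trials
  if (!("classification" %in% names(tr))) stop("session has no responses")
  n_t <- sum(tr$stimulus == "target")
  n_nt <- sum(tr$stimulus == "nontarget")
  if (n_t < 1 || n_nt < 1)
    stop("session needs at least one target and one nontarget trial")
  n_om <- sum(tr$classification == "omission")
  n_com <- sum(tr$classification == "commission")
  lat <- tr$press_latency_ms[tr$classification == "target_correct"]
  clip <- function(p, N) pmin(pmax(p, 1 / (2 * N)), 1 - 1 / (2 * N))
  hit <- clip((n_t - n_om) / n_t, n_t)
  fa <- clip(n_com / n_nt, n_nt)
  data.frame(
    omission_rate = 100 * n_om / n_t,
    commission_rate = 100 * n_com / n_nt,
    mean_rt = if (length(lat) > 0) mean(lat) else NA_real_,
    rt_variability = if (length(lat) > 1) stats::sd(lat)
                     else if (length(lat) == 1) 0 else NA_real_,
    d_prime = stats::qnorm(hit) - stats::qnorm(fa))
}
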