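#' EEG recording container
#'
#' A labeled multichannel time series: a channels x samples matrix in
#' microvolts plus sampling rate and a state tag (`"resting"` or `"tova"`).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels, one per row of `data`.
#' @param state_tag `"resting"` or `"tova"`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = rownames(data),
                          state_tag = c("resting", "tova"),
                          subject_id = NA_character_) {
  state_tag <- match.arg(state_tag)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (is.null(labels)) stop("channel labels are required")
  if (length(labels) != nrow(data))
    stop("length(labels) must equal nrow(data): ",
         length(labels), " vs ", nrow(data))
  if (anyNA(data)) stop("recording contains NA values")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive number")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         state_tag = state_tag, subject_id = subject_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), state: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$state_tag))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' @export
plot.eeg_recording <- function(x, channels = x$labels[1:min(4, length(x$labels))],
                               t_max = min(10, duration_s(x)), ...) {
  idx <- match(channels, x$labels)
  n <- floor(t_max * x$fs)
  tt <- seq_len(n) / x$fs
  sep <- 3 * stats::median(apply(x$data[idx, seq_len(n), drop = FALSE], 1, stats::sd))
  if (!is.finite(sep) || sep == 0) sep <- 1
  graphics::plot(NULL, xlim = c(0, t_max), ylim = c(0, (length(idx) + 1) * sep),
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (k in seq_along(idx)) {
    graphics::lines(tt, x$data[idx[k], seq_len(n)] -
                      mean(x$data[idx[k], seq_len(n)]) + k * sep)
    graphics::mtext(channels[k], side = 2, at = k * sep, las = 1, line = 0.5, cex = 0.8)
  }
  invisible(x)
}

#' Write / read a recording as long CSV
#'
#' Interchange format: columns `time_s`, `channel`, `uV`, written channel-major.
#' Sampling rate and state tag are recovered from the time grid and a header
#' comment line.
#'
#' @param rec An [eeg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_recording_csv`); an [eeg_recording()]
#'   (`read_recording_csv`).
#' @export
write_recording_csv <- function(rec, path) {
  n <- ncol(rec$data)
  df <- data.frame(
    time_s = rep(seq(0, by = 1 / rec$fs, length.out = n), times = nrow(rec$data)),
    channel = rep(rec$labels, each = n),
    uV = as.vector(t(rec$data)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eeg_recording fs=%g state=%s subject=%s",
                     rec$fs, rec$state_tag, rec$subject_id), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# eeg_recording"))
    stop("not a recording CSV (missing header comment): ", path)
  get_field <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
  fs <- as.numeric(get_field("fs"))
  state <- get_field("state")
  subject <- get_field("subject")
  df <- utils::read.csv(path, comment.char = "#")
  labels <- unique(df$channel)
  n <- nrow(df) / length(labels)
  data <- matrix(df$uV, nrow = length(labels), ncol = n, byrow = TRUE)
  eeg_recording(data, fs, labels, state_tag = state,
                subject_id = if (subject == "NA") NA_character_ else subject)
}

#' TOVA session container
#'
#' A stimulus schedule (one row per trial) with optional behavioral
#' responses. Columns: `trial_index` (1-based), `onset_s` (relative to task
#' start), `stimulus` (`"target"`/`"nontarget"`), `quarter` (1..4) and, once
#' responses are simulated or recorded, `press_latency_ms` (NA when no press)
#' and `classification` (`target_correct`, `nontarget_correct`, `omission`,
#' `commission`).
#'
#' @param trials Data frame as described above.
#' @param trial_period Inter-stimulus period in seconds.
#' @param subject_id Optional subject identifier.
#' @return An object of class `tova_session`.
#' @export
tova_session <- function(trials, trial_period, subject_id = NA_character_) {
  stopifnot(is.data.frame(trials),
            all(c("trial_index", "onset_s", "stimulus", "quarter") %in% names(trials)))
  if (!all(trials$stimulus %in% c("target", "nontarget")))
    stop("stimulus must be 'target' or 'nontarget'")
  structure(list(trials = trials, trial_period = trial_period,
                 subject_id = subject_id),
            class = "tova_session")
}

#' @export
print.tova_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<tova_session> %d trials (%d targets), period %g s, duration %.1f min\n",
              nrow(tr), sum(tr$stimulus == "target"), x$trial_period,
              nrow(tr) * x$trial_period / 60))
  if ("classification" %in% names(tr)) {
    tab <- table(tr$classification)
    cat("  responses:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  responses: none (schedule only)\n")
  invisible(x)
}

#' Write / read a TOVA session as CSV
#' @param session A [tova_session()].
#' @param path CSV path.
#' @return `path` invisibly, or a [tova_session()].
#' @export
write_session_csv <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tova_session trial_period=%g subject=%s",
                     session$trial_period, session$subject_id), con)
  utils::write.csv(session$trials, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# tova_session")) stop("not a session CSV: ", path)
  tp <- as.numeric(sub(".*trial_period=([^ ]+).*", "\\1", hdr))
  subject <- sub(".*subject=([^ ]+).*", "\\1", hdr)
  trials <- utils::read.csv(path, comment.char = "#")
  tova_session(trials, tp, if (subject == "NA") NA_character_ else subject)
}
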