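#' Preprocessing filter configuration
#'
#' Parameters for the three-stage cleaning chain: cascaded median filters
#' for baseline wander (0.2 s and 0.04 s windows), a linear-phase FIR
#' band-reject for 60 Hz line interference, and ICA + recursive least
#' squares (RLS) for EOG cancellation from the four EOG-related frontal
#' channels.
#'
#' @param median_window_large,median_window_small Median windows in seconds.
#' @param notch_center,notch_halfwidth Band-reject center and half-width, Hz.
#' @param fir_order FIR order (taps - 1); Hamming-window design.
#' @param rls_forgetting RLS forgetting factor in (0, 1].
#' @param rls_order Number of reference taps in the RLS canceller.
#' @param eog_channels Labels of the EOG-related channels.
#' @param eog_min_cor Minimum absolute correlation between an independent
#'   component and the low-frequency frontal envelope for it to be accepted
#'   as the EOG reference; below it the recording passes through unchanged.
#' @param eog_lowfreq_frac Minimum fraction of component power below 4 Hz.
#' @param ica_seed Seed for the deterministic ICA initialization.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(median_window_large = 0.2, median_window_small = 0.04,
                          notch_center = 60, notch_halfwidth = 2,
                          fir_order = 500,
                          rls_forgetting = 0.999, rls_order = 3,
                          eog_channels = c("Fp1", "Fp2", "F7", "F8"),
                          eog_min_cor = 0.6, eog_lowfreq_frac = 0.5,
                          ica_seed = 1L) {
  stopifnot(median_window_large > 0, median_window_small > 0,
            notch_center > 0, notch_halfwidth > 0, fir_order >= 8,
            rls_forgetting > 0, rls_forgetting <= 1, rls_order >= 1)
  structure(list(median_window_large = median_window_large,
                 median_window_small = median_window_small,
                 notch_center = notch_center, notch_halfwidth = notch_halfwidth,
                 fir_order = fir_order,
                 rls_forgetting = rls_forgetting, rls_order = rls_order,
                 eog_channels = eog_channels, eog_min_cor = eog_min_cor,
                 eog_lowfreq_frac = eog_lowfreq_frac, ica_seed = ica_seed),
            class = "filter_config")
}

# window length in samples, forced odd (median filters need odd windows)
odd_window <- function(seconds, fs) {
  k <- max(3L, round(seconds * fs))
  if (k %% 2 == 0) k <- k + 1L
  as.integer(k)
}

# running median with reflect padding (avoids boundary spikes entering epochs)
reflect_runmed <- function(x, k) {
  n <- length(x)
  if (k >= n) stop("median window (", k, " samples) must be shorter than the signal (",
                   n, " samples)")
  p <- (k - 1L) / 2L
  xp <- c(x[(p + 1):2], x, x[(n - 1):(n - p)])
  out <- stats::runmed(xp, k, endrule = "keep")
  out[(p + 1):(p + n)]
}

#' Remove baseline wander with cascaded median filters
#'
#' Per channel, the baseline estimate is a cascade of a small-window median
#' filter followed by a large-window one; the estimate is subtracted from
#' the signal. Default windows are 0.04 s and 0.2 s.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [filter_config()].
#' @return An [eeg_recording()] of the same shape.
#' @export
remove_baseline <- function(rec, cfg = filter_config()) {
  k_small <- odd_window(cfg$median_window_small, rec$fs)
  k_large <- odd_window(cfg$median_window_large, rec$fs)
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    base <- reflect_runmed(reflect_runmed(rec$data[i, ], k_small), k_large)
    out$data[i, ] <- rec$data[i, ] - base
  }
  out
}

# Hamming-window FIR band-stop coefficients for the notch
design_notch <- function(cfg, fs) {
  if (cfg$notch_center >= fs / 2)
    stop("notch center ", cfg$notch_center, " Hz is at or above Nyquist (",
         fs / 2, " Hz)")
  edges <- c(cfg$notch_center - cfg$notch_halfwidth,
             cfg$notch_center + cfg$notch_halfwidth) / (fs / 2)
  as.numeric(signal::fir1(cfg$fir_order, edges, type = "stop"))
}

# zero-phase application of a linear-phase (symmetric) FIR: multiply the
# signal spectrum by the filter's real zero-phase frequency response
# (circular convolution; the symmetric taps make the rotated response real)
fir_apply <- function(x, b) {
  n <- length(x)
  m <- length(b)
  if (m > n) stop("signal shorter than the FIR filter (", n, " < ", m, " samples)")
  delay <- (m - 1) / 2
  Hb <- stats::fft(c(b, numeric(n - m)))
  rot <- exp(2i * pi * (seq_len(n) - 1) * delay / n)
  H <- Re(Hb * rot)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Remove line interference with a linear-phase FIR band-reject filter
#'
#' Applies a Hamming-window FIR band-stop (default 60 +/- 2 Hz, order 500)
#' per channel with zero net delay. At the default order the stop-band
#' attenuation at the notch center exceeds 40 dB and the pass-band ripple
#' outside center +/- 3 half-widths stays below 1 dB.
#'
#' @inheritParams remove_baseline
#' @return An [eeg_recording()] of the same shape.
#' @export
remove_line <- function(rec, cfg = filter_config()) {
  b <- design_notch(cfg, rec$fs)
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- fir_apply(rec$data[i, ], b)
  out
}

# FFT low-pass (< cutoff Hz) used to build the frontal EOG envelope
fft_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs < cutoff | (fs - freqs) < cutoff
  xf <- stats::fft(x)
  xf[!keep] <- 0
  Re(stats::fft(xf, inverse = TRUE)) / n
}

# fraction of (non-DC) spectral power below `cutoff` Hz
lowfreq_fraction <- function(x, fs, cutoff) {
  n <- length(x)
  xf <- abs(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(freqs, fs - freqs)
  tot <- sum(xf[-1])
  if (tot == 0) return(0)
  sum(xf[-1][f_fold[-1] < cutoff]) / tot
}

#' Remove EOG artifacts by ICA projection and RLS adaptive filtering
#'
#' Decomposes the four EOG-related channels (default Fp1, Fp2, F7, F8) by
#' ICA; identifies the EOG reference as the component maximally correlated
#' with the low-frequency (< 4 Hz) frontal envelope, provided it is
#' low-frequency dominated; then, for every channel, runs a recursive
#' least-squares adaptive filter with the reference as regressor and
#' subtracts the fitted contribution. When no component qualifies as ocular
#' (e.g. a blink-free recording) the input is returned unchanged with
#' attribute `eog_removed = FALSE`.
#'
#' @inheritParams remove_baseline
#' @return An [eeg_recording()] of the same shape; attribute `eog_removed`
#'   says whether a reference was found and cancelled.
#' @export
remove_eog <- function(rec, cfg = filter_config()) {
  missing_ch <- setdiff(cfg$eog_channels, rec$labels)
  if (length(missing_ch) > 0)
    stop("EOG channel(s) not present in recording: ",
         paste(missing_ch, collapse = ", "))
  if (duration_s(rec) < 30)
    stop("recording too short for ICA-based EOG removal (",
         round(duration_s(rec), 1), " s < 30 s)")
  eog_idx <- match(cfg$eog_channels, rec$labels)
  E <- rec$data[eog_idx, , drop = FALSE]
  # whiten only the numerically independent directions; frontal channels
  # can be near-collinear, and null directions would just amplify noise
  ev <- eigen(tcrossprod(E - rowMeans(E)) / ncol(E), symmetric = TRUE,
              only.values = TRUE)$values
  rank_E <- max(1L, sum(ev > 1e-8 * ev[1]))
  ic <- fast_ica(E, n_comp = min(rank_E, nrow(E)), seed = cfg$ica_seed)
  envelope <- fft_lowpass(colMeans(E), rec$fs, 4)
  cors <- apply(ic$sources, 1, function(s) stats::cor(s, envelope))
  lff <- apply(ic$sources, 1, lowfreq_fraction, fs = rec$fs, cutoff = 4)
  ok <- lff > cfg$eog_lowfreq_frac & abs(cors) >= cfg$eog_min_cor
  if (!any(ok)) {
    attr(rec, "eog_removed") <- FALSE
    return(rec)
  }
  pick <- which(ok)[which.max(abs(cors)[ok])]
  ref <- ic$sources[pick, ] * sign(cors[pick])
  ref <- ref / stats::sd(ref)
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- rls_cancel(rec$data[i, ], ref,
                                cfg$rls_forgetting, cfg$rls_order)
  attr(out, "eog_removed") <- TRUE
  out
}

#' Full preprocessing chain
#'
#' Baseline-wander removal (cascaded median filters), 60 Hz band-reject,
#' then ICA + RLS EOG cancellation, in that order.
#'
#' @inheritParams remove_baseline
#' @return A cleaned [eeg_recording()] of the same shape.
#' @export
preprocess <- function(rec, cfg = filter_config()) {
  remove_eog(remove_line(remove_baseline(rec, cfg), cfg), cfg)
}
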