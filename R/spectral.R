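#' Per-epoch absolute band power
#'
#' Computes, per channel and epoch, the periodogram power summed over each
#' half-open frequency band (delta `[1,4)`, theta `[4,8)`, alpha `[8,12)`,
#' beta `[12,16)` Hz). The periodogram is Parseval-normalized so that the
#' power of a pure sinusoid of amplitude A concentrated in a band is A^2/2;
#' an optional Hann taper (power-normalized) is applied by default.
#'
#' @param ts A [trial_set()].
#' @param bands Named list of `c(lo, hi)` band edges, Hz.
#' @param taper `"hann"` or `"none"`.
#' @return Array `n_epochs x n_channels x n_bands` of absolute power (uV^2).
#' @export
band_power <- function(ts, bands = qeeg_bands(), taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n_ep <- dim(ts$epochs)[3]
  if (n_ep < 1) stop("empty trial set")
  n <- ts$samples_per_trial
  if (n < ts$fs) stop("epochs must be at least 1 s long for band power")
  w <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) else rep(1, n)
  wnorm <- mean(w^2)
  freqs <- (seq_len(n) - 1) * ts$fs / n
  # one-sided bin weights: doubled except DC and (even n) Nyquist
  half <- freqs <= ts$fs / 2
  mult <- ifelse(freqs == 0 | abs(freqs - ts$fs / 2) < 1e-12, 1, 2)
  band_bins <- lapply(bands, function(b) which(half & freqs >= b[1] & freqs < b[2]))
  out <- array(0, dim = c(n_ep, dim(ts$epochs)[1], length(bands)),
               dimnames = list(NULL, ts$labels, names(bands)))
  for (e in seq_len(n_ep)) {
    X <- ts$epochs[, , e, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    Xw <- sweep(X, 2, w, `*`)
    P <- abs(t(stats::mvfft(t(Xw))))^2 / (n^2 * wnorm)
    for (b in seq_along(bands)) {
      idx <- band_bins[[b]]
      out[e, , b] <- if (length(idx) > 0)
        as.numeric(P[, idx, drop = FALSE] %*% mult[idx]) else 0
    }
  }
  out
}

#' Aggregate per-epoch power into one condition's band-power table
#'
#' Averages absolute power across the epochs of one response condition
#' (correct targets, correct nontargets, or resting windows) and derives
#' relative power as each band's fraction of the four-band total per
#' channel.
#'
#' @param bp Per-epoch power array from [band_power()].
#' @param classes Per-epoch class labels.
#' @param condition Class label to aggregate (`"target_correct"`,
#'   `"nontarget_correct"`, or `"resting"`).
#' @return List with `abs` and `rel` (channels x bands matrices), `n_epochs`,
#'   and `condition`. Channels whose four-band total is zero get `NA`
#'   relative power.
#' @export
aggregate_condition <- function(bp, classes, condition) {
  idx <- which(classes == condition)
  if (length(idx) == 0) stop("no epochs with class '", condition, "'")
  abs_p <- apply(bp[idx, , , drop = FALSE], c(2, 3), mean)
  tot <- rowSums(abs_p)
  rel <- abs_p / tot
  rel[tot == 0, ] <- NA_real_
  list(abs = abs_p, rel = rel, n_epochs = length(idx), condition = condition)
}

#' Neighbor-average (reorganize) a channels x bands table
#'
#' Replaces each channel's value with the mean of itself and its adjacent
#' electrodes, independently per band: the reorganized value at c0 is
#' (c0 + sum of neighbors) / (number of neighbors + 1). With the default
#' adjacency, F3 becomes (F3 + Fp1 + F7 + Fz + C3)/5. A channel with an
#' empty neighbor list is left unchanged.
#'
#' @param mat Channels x bands matrix with channel rownames.
#' @param adjacency Named list of neighbor labels; see [default_adjacency()].
#' @return Matrix of the same shape.
#' @export
neighbor_average <- function(mat, adjacency = default_adjacency()) {
  labels <- rownames(mat)
  if (is.null(labels)) stop("matrix must have channel rownames")
  validate_adjacency(adjacency, labels)
  out <- mat
  for (ch in labels) {
    nb <- adjacency[[ch]]
    out[ch, ] <- colMeans(mat[c(ch, nb), , drop = FALSE])
  }
  out
}

#' Z-scores across channels and cordance
#'
#' Z-scores the reorganized absolute and relative power across the 19
#' channels (population SD), independently per band, and sums them into
#' cordance: `cordance = z_abs + z_rel`.
#'
#' @param abs_r,rel_r Reorganized channels x bands matrices from
#'   [neighbor_average()].
#' @return List with `z_abs`, `z_rel`, `cordance` (channels x bands). Bands
#'   with zero variance across channels come back `NA`.
#' @export
zscore_cordance <- function(abs_r, rel_r) {
  zscore <- function(m) {
    apply(m, 2, function(v) {
      mu <- mean(v)
      s <- sqrt(mean((v - mu)^2))
      if (!is.finite(s) || s == 0) return(rep(NA_real_, length(v)))
      (v - mu) / s
    })
  }
  z_abs <- zscore(abs_r)
  z_rel <- zscore(rel_r)
  rownames(z_abs) <- rownames(abs_r); rownames(z_rel) <- rownames(rel_r)
  list(z_abs = z_abs, z_rel = z_rel, cordance = z_abs + z_rel)
}

#' Full band-power / cordance table for one subject and condition
#'
#' Chains [band_power()], [aggregate_condition()], [neighbor_average()] and
#' [zscore_cordance()] into the tidy per-channel, per-band table.
#'
#' @param ts A [trial_set()].
#' @param condition Class label to aggregate.
#' @param adjacency Neighbor map, default [default_adjacency()].
#' @param subject_id Subject identifier for the output rows.
#' @return Data frame with columns `subject_id`, `condition`, `channel`,
#'   `band`, `abs_power`, `rel_power`, `abs_reorg`, `rel_reorg`, `z_abs`,
#'   `z_rel`, `cordance`.
#' @export
cordance_table <- function(ts, condition, adjacency = default_adjacency(),
                           subject_id = ts$subject_id) {
  bp <- band_power(ts)
  agg <- aggregate_condition(bp, ts$classes, condition)
  abs_r <- neighbor_average(agg$abs, adjacency)
  rel_r <- neighbor_average(agg$rel, adjacency)
  z <- zscore_cordance(abs_r, rel_r)
  bands <- colnames(agg$abs)
  data.frame(
    subject_id = subject_id, condition = condition,
    channel = rep(rownames(agg$abs), times = length(bands)),
    band = rep(bands, each = nrow(agg$abs)),
    abs_power = as.vector(agg$abs), rel_power = as.vector(agg$rel),
    abs_reorg = as.vector(abs_r), rel_reorg = as.vector(rel_r),
    z_abs = as.vector(z$z_abs), z_rel = as.vector(z$z_rel),
    cordance = as.vector(z$cordance))
}
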