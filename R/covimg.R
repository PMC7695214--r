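#' Per-trial trace-normalized covariance matrix
#'
#' For one epoch X (channels x samples), computes X X' / trace(X X'): the
#' raw (non-mean-subtracted) scatter between every channel pair, normalized
#' to unit trace. A mean-centered variant is available by flag.
#'
#' @param epoch Channels x samples numeric matrix.
#' @param center Subtract each channel's mean first (default `FALSE`, the
#'   raw-scatter form).
#' @return Symmetric channels x channels matrix with trace 1.
#' @export
trial_cov <- function(epoch, center = FALSE) {
  if (!is.matrix(epoch) || ncol(epoch) < 2)
    stop("epoch must be a matrix with at least 2 samples")
  if (center) epoch <- epoch - rowMeans(epoch)
  S <- tcrossprod(epoch)
  tr <- sum(diag(S))
  if (tr == 0) stop("all-zero epoch: trace of the scatter matrix is zero")
  S / tr
}

#' Trial-averaged covariance for one response class
#'
#' Elementwise mean of the per-trial trace-normalized covariance matrices
#' over the epochs of one class (signal averaging across trials).
#'
#' @param ts A [trial_set()].
#' @param class_filter Class to average (`"target_correct"`,
#'   `"nontarget_correct"`, or `"resting"`).
#' @param center Passed to [trial_cov()].
#' @return List with `raw` (channels x channels, trace 1) and `n_trials_used`.
#' @export
average_cov <- function(ts, class_filter, center = FALSE) {
  idx <- which(ts$classes == class_filter)
  if (length(idx) == 0) stop("no epochs with class '", class_filter, "'")
  acc <- matrix(0, dim(ts$epochs)[1], dim(ts$epochs)[1])
  for (i in idx) acc <- acc + trial_cov(ts$epochs[, , i], center = center)
  raw <- acc / length(idx)
  dimnames(raw) <- list(ts$labels, ts$labels)
  list(raw = raw, n_trials_used = length(idx))
}

# discrete cumulative-histogram equalization over 256 levels
equalize_hist <- function(img8) {
  v <- as.integer(img8)
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(v)
  cdf_min <- cdf[which(h > 0)[1]]
  if (cdf_min >= 1) return(img8)  # single occupied level
  lut <- round_half_up(255 * (cdf - cdf_min) / (1 - cdf_min))
  out <- matrix(lut[v + 1L], nrow = nrow(img8))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(img8)
  out
}

#' Map a covariance matrix to 8-bit and equalize
#'
#' Linear min-max mapping of the raw matrix to integer levels 0..255
#' (rounded half up), followed by standard cumulative-histogram
#' equalization over the 256 levels. A constant matrix maps to all-zero
#' with attribute `degenerate = TRUE`.
#'
#' @param raw Numeric matrix (finite values).
#' @return List with `image8` and `equalized` (integer matrices in 0..255).
#' @export
to_image <- function(raw) {
  if (any(!is.finite(raw))) stop("raw covariance matrix contains non-finite values")
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) {
    img8 <- matrix(0L, nrow(raw), ncol(raw), dimnames = dimnames(raw))
    out <- list(image8 = img8, equalized = img8)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  img8 <- round_half_up((raw - lo) / (hi - lo) * 255)
  storage.mode(img8) <- "integer"
  dimnames(img8) <- dimnames(raw)
  list(image8 = img8, equalized = equalize_hist(img8))
}

#' Build the covariance-matrix image for one subject and condition
#'
#' Chains [average_cov()] and [to_image()]: per-trial trace-normalized
#' covariance, averaged across the class's trials, mapped to 8-bit and
#' histogram-equalized. Rows/columns follow the fixed front-to-occipital
#' electrode order.
#'
#' @inheritParams average_cov
#' @param subject_id Subject identifier.
#' @return An object of class `covariance_image` with fields `raw`,
#'   `image8`, `equalized`, `n_trials_used`, `condition`, `subject_id`.
#' @export
covariance_image <- function(ts, class_filter, center = FALSE,
                             subject_id = ts$subject_id) {
  avg <- average_cov(ts, class_filter, center = center)
  img <- to_image(avg$raw)
  structure(list(raw = avg$raw, image8 = img$image8,
                 equalized = img$equalized,
                 n_trials_used = avg$n_trials_used,
                 condition = class_filter, subject_id = subject_id),
            class = "covariance_image")
}

#' @export
print.covariance_image <- function(x, ...) {
  cat(sprintf("<covariance_image> %dx%d, %s, %d trials averaged (subject %s)\n",
              nrow(x$raw), ncol(x$raw), x$condition, x$n_trials_used,
              x$subject_id))
  invisible(x)
}

#' @export
plot.covariance_image <- function(x, which = c("equalized", "image8", "raw"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), ]),
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste0(which, " (", x$condition, ")"), ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 1, cex.axis = 0.6)
  invisible(x)
}
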