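#' Configuration for the two-scale approximate-entropy score
#'
#' @param m1,m2 Pattern lengths (defaults 20 and 50: 20 is the distance
#'   between consecutive diagonal elements of the reshaped 19 x 19 image,
#'   50 guarantees inclusion of adjacent-channel information).
#' @param r Similarity threshold. `NULL` (default) means 0.2 x SD of the
#'   sequence, the classical approximate-entropy convention; a number is
#'   used as an absolute threshold in the sequence's units.
#' @param norm Window distance: `"chebyshev"` (max, default) or
#'   `"euclidean"`.
#' @param include_self_matches Count the self pair i = j (default `TRUE`,
#'   keeps both components strictly positive).
#' @param prefactor_1_over_n Scale the component ratio by 1/n (default
#'   `TRUE`).
#' @param source Which image to score: `"equalized"` (default), `"image8"`,
#'   or `"raw"`.
#' @return An object of class `apen_config`.
#' @export
apen_config <- function(m1 = 20, m2 = 50, r = NULL,
                        norm = c("chebyshev", "euclidean"),
                        include_self_matches = TRUE,
                        prefactor_1_over_n = TRUE,
                        source = c("equalized", "image8", "raw")) {
  norm <- match.arg(norm)
  source <- match.arg(source)
  stopifnot(m1 >= 1, m2 > m1)
  if (!is.null(r)) stopifnot(r > 0)
  structure(list(m1 = m1, m2 = m2, r = r, norm = norm,
                 include_self_matches = include_self_matches,
                 prefactor_1_over_n = prefactor_1_over_n, source = source),
            class = "apen_config")
}

#' Reshape a square image into its row-major sequence
#'
#' Flattens left-to-right, top-to-bottom, so a 19 x 19 image becomes a
#' length-361 sequence in which consecutive main-diagonal elements sit 20
#' indices apart.
#'
#' @param img Square numeric matrix.
#' @return Numeric vector of length `nrow(img)^2`.
#' @export
reshape_image <- function(img) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop("image must be a square matrix")
  as.numeric(t(img))
}

#' Mean pattern-match fraction (approximate-entropy component)
#'
#' For each window start i, counts the windows j whose length-m pattern is
#' within `r` of pattern i under the chosen norm, and returns the mean of
#' `count / (n - m + 1)` over i. Self-matches are counted by default, so the
#' value lies in (0, 1].
#'
#' @param x Numeric sequence.
#' @param m Pattern length (must be below `length(x)`).
#' @param r Positive similarity threshold (absolute units).
#' @param cfg An [apen_config()] (used for norm and self-match flags).
#' @return Mean match fraction in (0, 1].
#' @export
apen_component <- function(x, m, r, cfg = apen_config()) {
  apen_component_cpp(as.numeric(x), as.integer(m), r,
                     self_matches = cfg$include_self_matches,
                     chebyshev = cfg$norm == "chebyshev")
}

#' Two-scale approximate-entropy score of a covariance image
#'
#' Reshapes the configured image into its 361-element sequence and computes
#' `(1/n) * ApEn(m1, r) / ApEn(m2, r)` where each ApEn component is the
#' mean pattern-match fraction of [apen_component()]. High scores indicate
#' low regularity (fewer repeated patterns across channel pairs); low
#' scores indicate a repetitive spatial covariance structure. Both
#' components, the resolved `r`, and the configuration are stored alongside
#' the value.
#'
#' @param image A [covariance_image()] (or a bare square matrix).
#' @param cfg An [apen_config()].
#' @return An object of class `apen_score` with fields `value`,
#'   `component_m1`, `component_m2`, `ratio`, `r`, `n`, `config`,
#'   `subject_id`, `condition`.
#' @export
apen_score <- function(image, cfg = apen_config()) {
  if (inherits(image, "covariance_image")) {
    img <- image[[cfg$source]]
    subject_id <- image$subject_id
    condition <- image$condition
  } else {
    img <- image
    subject_id <- NA_character_
    condition <- NA_character_
  }
  s <- reshape_image(img)
  n <- length(s)
  if (cfg$m2 >= n) stop("m2 (", cfg$m2, ") must be below sequence length (", n, ")")
  r <- cfg$r %||% (0.2 * stats::sd(s))
  if (!is.finite(r) || r <= 0) r <- .Machine$double.eps  # constant sequence
  c1 <- apen_component(s, cfg$m1, r, cfg)
  c2 <- apen_component(s, cfg$m2, r, cfg)
  if (c2 == 0)
    stop("degenerate: zero matches at m2 with self-matches excluded")
  ratio <- c1 / c2
  value <- if (cfg$prefactor_1_over_n) ratio / n else ratio
  structure(list(value = value, component_m1 = c1, component_m2 = c2,
                 ratio = ratio, r = r, n = n, config = cfg,
                 subject_id = subject_id, condition = condition),
            class = "apen_score")
}

#' @export
print.apen_score <- function(x, ...) {
  cat(sprintf(
    "<apen_score> value %.5f (ratio %.3f = %.4f / %.4f; m1=%d m2=%d r=%.3g n=%d)\n",
    x$value, x$ratio, x$component_m1, x$component_m2,
    x$config$m1, x$config$m2, x$r, x$n))
  if (!is.na(x$subject_id))
    cat("  subject:", x$subject_id, " condition:", x$condition, "\n")
  invisible(x)
}
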