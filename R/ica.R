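# Deflation (one-unit) FastICA with a tanh contrast.
#
# x: channels x samples data matrix. Components are extracted one at a
# time, each orthogonalized against the previous ones, most non-Gaussian
# directions first in practice. Near-Gaussian trailing components may stop
# at the iteration cap without settling; they are returned anyway (flagged
# in `converged`) since the artifact component of interest is strongly
# non-Gaussian and converges quickly. An error is raised only when no
# component converges at all. Initialization is deterministic (seeded), so
# the decomposition is a pure function of (x, seed).
fast_ica <- function(x, n_comp = nrow(x), seed = 1L, max_iter = 200L,
                     tol = 1e-6) {
  x <- x - rowMeans(x)
  n <- ncol(x)
  cv <- tcrossprod(x) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  whiten <- diag(1 / sqrt(pmax(eg$values[keep], 1e-12)), n_comp) %*%
    t(eg$vectors[, keep, drop = FALSE])
  z <- whiten %*% x
  W <- matrix(0, n_comp, n_comp)
  init <- with_seed(seed, matrix(stats::rnorm(n_comp^2), n_comp, n_comp))
  converged <- logical(n_comp)
  iterations <- integer(n_comp)
  for (p in seq_len(n_comp)) {
    w <- init[, p]
    if (p > 1) {
      prev <- W[seq_len(p - 1), , drop = FALSE]
      w <- w - as.vector(t(prev) %*% (prev %*% w))
    }
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wz <- as.vector(w %*% z)
      g <- tanh(wz)
      w_new <- as.vector(z %*% g) / n - mean(1 - g^2) * w
      if (p > 1) {
        prev <- W[seq_len(p - 1), , drop = FALSE]
        w_new <- w_new - as.vector(t(prev) %*% (prev %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) break
      w_new <- w_new / nrm
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      iterations[p] <- it
      if (delta < tol) { converged[p] <- TRUE; break }
    }
    W[p, ] <- w
  }
  if (!any(converged))
    stop("ICA failed to converge after ", max_iter,
         " iterations on every component")
  list(sources = W %*% z, unmixing = W %*% whiten,
       converged = converged, iterations = iterations)
}
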