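#' Mann-Whitney U test between two groups
#'
#' Two-sided test via [stats::wilcox.test()]: exact when both arms have at
#' most 20 untied values, normal approximation with tie correction
#' otherwise.
#'
#' @param a,b Numeric vectors (each with at least 2 values).
#' @param alpha Significance level carried into the result.
#' @return A list of class `stat_result` with `test`, `statistic` (U),
#'   `p_value`, `alpha`, `significant`.
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
  structure(list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
                 p_value = wt$p.value, alpha = alpha,
                 significant = wt$p.value < alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g%s\n",
              x$test, x$statistic %||% NA,
              x$p_value, if (isTRUE(x$significant)) " *" else ""))
  if (!is.null(x$posthoc)) { cat("post hoc:\n"); print(x$posthoc) }
  invisible(x)
}

#' Two-way ANOVA with Bonferroni post-hoc group contrasts
#'
#' Fits `value ~ group * condition` (both between-observation factors),
#' reports the two main effects and the interaction, and computes the
#' per-condition group contrasts using the pooled residual mean square,
#' with Bonferroni-adjusted p values and confidence intervals (the
#' Prism-style post test). Note the repeated-measures structure of a
#' within-subject condition factor is deliberately ignored, matching the
#' plain two-way layout; the output flags this.
#'
#' @param values Numeric response vector.
#' @param group,condition Factors (or coercible) of the same length.
#' @param alpha Significance level.
#' @return A `stat_result` with an `anova` table, a `posthoc` data frame
#'   (condition, mean difference, t, adjusted p, adjusted 95% CI), and
#'   `note`.
#' @export
two_way_anova_bonferroni <- function(values, group, condition, alpha = 0.05) {
  group <- factor(group); condition <- factor(condition)
  stopifnot(length(values) == length(group), length(values) == length(condition))
  if (nlevels(group) < 2 || nlevels(condition) < 2)
    stop("both factors need at least 2 levels")
  cells <- table(group, condition)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: group '", levels(group)[empty[1]], "' x condition '",
         levels(condition)[empty[2]], "'")
  }
  if (any(cells < 2)) stop("every cell needs at least 2 observations")
  fit <- stats::aov(values ~ group * condition)
  tab <- summary(fit)[[1]]
  # convention: an effect whose sum of squares is numerically zero has
  # F = 0, p = 1 (covers the 0/0 case of completely constant responses,
  # where floating-point residue would otherwise produce arbitrary F)
  eff <- seq_len(nrow(tab) - 1)  # all rows but Residuals
  ss_tol <- 1e-16 * (sum(values^2) + .Machine$double.xmin)
  zero_ss <- eff[tab[["Sum Sq"]][eff] < ss_tol]
  tab[["F value"]][zero_ss] <- 0
  tab[["Pr(>F)"]][zero_ss] <- 1
  mse <- tab["Residuals", "Mean Sq"]
  df_res <- tab["Residuals", "Df"]
  k <- nlevels(condition) * choose(nlevels(group), 2)
  post <- NULL
  gl <- levels(group)
  for (cond in levels(condition)) {
    for (i in seq_len(nlevels(group) - 1)) for (j in (i + 1):nlevels(group)) {
      vi <- values[group == gl[i] & condition == cond]
      vj <- values[group == gl[j] & condition == cond]
      diff <- mean(vi) - mean(vj)
      se <- sqrt(mse * (1 / length(vi) + 1 / length(vj)))
      tval <- diff / se
      p_adj <- min(1, k * 2 * stats::pt(-abs(tval), df_res))
      tcrit <- stats::qt(1 - alpha / (2 * k), df_res)
      post <- rbind(post, data.frame(
        condition = cond, comparison = paste(gl[i], "vs", gl[j]),
        mean_diff = diff, t = tval, p_adj = p_adj,
        ci_lower = diff - tcrit * se, ci_upper = diff + tcrit * se))
    }
  }
  rownames(tab) <- trimws(rownames(tab))
  structure(list(test = "two-way ANOVA + Bonferroni post hoc",
                 anova = tab,
                 statistic = tab["group:condition", "F value"],
                 p_value = tab["group:condition", "Pr(>F)"],
                 p_group = tab["group", "Pr(>F)"],
                 p_condition = tab["condition", "Pr(>F)"],
                 posthoc = post, alpha = alpha,
                 significant = tab["group:condition", "Pr(>F)"] < alpha,
                 note = "condition treated as between-observation; within-subject structure ignored"),
            class = "stat_result")
}

#' Channelwise unpaired t-tests on cordance
#'
#' Pooled-variance two-sided t test per channel between two groups' per
#' channel values (e.g. theta cordance), flagging channels below `alpha`.
#'
#' @param values_a,values_b Matrices (subjects x channels) with channel
#'   column names, one per group.
#' @param channels Channels to test (default: all shared columns).
#' @param alpha Significance level.
#' @return Data frame: channel, mean per group, t, df, p_value, significant.
#'   Channels with zero variance in both groups get `NA` with a flag.
#' @export
channelwise_ttests <- function(values_a, values_b,
                               channels = intersect(colnames(values_a),
                                                    colnames(values_b)),
                               alpha = 0.05) {
  if (length(channels) == 0) stop("no shared channels to test")
  out <- NULL
  for (ch in channels) {
    va <- values_a[, ch]; vb <- values_b[, ch]
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      out <- rbind(out, data.frame(channel = ch, mean_a = mean(va),
                                   mean_b = mean(vb), t = NA_real_,
                                   df = NA_real_, p_value = NA_real_,
                                   significant = NA, degenerate = TRUE))
      next
    }
    tt <- stats::t.test(va, vb, var.equal = TRUE)
    out <- rbind(out, data.frame(channel = ch, mean_a = mean(va),
                                 mean_b = mean(vb), t = unname(tt$statistic),
                                 df = unname(tt$parameter),
                                 p_value = tt$p.value,
                                 significant = tt$p.value < alpha,
                                 degenerate = FALSE))
  }
  out
}

#' Spearman rank correlation
#'
#' Two-tailed rank correlation via [stats::cor.test()] with tie handling.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param alpha Significance level.
#' @return A `stat_result` with `estimate` (rho), `p_value`.
#' @export
spearman <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  structure(list(test = "Spearman rank correlation",
                 estimate = unname(ct$estimate), statistic = unname(ct$statistic),
                 p_value = ct$p.value, alpha = alpha,
                 significant = ct$p.value < alpha),
            class = "stat_result")
}

#' Empirical ROC analysis
#'
#' Empirical ROC over all score thresholds for a binary classification
#' (higher score = more likely positive unless `direction = "<"`). AUC is
#' the Mann-Whitney statistic divided by `n_pos * n_neg` (rank form, ties
#' counted 1/2); the standard error uses the Hanley-McNeil formula and the
#' 95% CI is the normal interval clipped to `[0,1]`. The operating cut-off
#' maximizes Youden's J (sensitivity + specificity - 1), placed midway
#' between adjacent scores; exact binomial 95% CIs for sensitivity and
#' specificity at the cut-off are attached.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is positive).
#' @param direction `">"` when positives score higher.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_se`, `auc_ci95`, `cutoff`, `cutoff_sens`,
#'   `cutoff_spec`, `cutoff_sens_ci95`, `cutoff_spec_ci95`, `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels, direction = ">") {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  if (direction == "<") scores <- -scores
  n1 <- sum(labels); n0 <- sum(!labels)
  rk <- rank(scores)
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * auc_se, 0), 1)
  uniq <- sort(unique(scores))
  thr <- c(-Inf, (uniq[-1] + uniq[-length(uniq)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  cutoff <- thr[best]
  sens_ci <- stats::binom.test(round(sens[best] * n1), n1)$conf.int
  spec_ci <- stats::binom.test(round(spec[best] * n0), n0)$conf.int
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_se = auc_se, auc_ci95 = ci,
                 cutoff = if (direction == "<") -cutoff else cutoff,
                 cutoff_sens = sens[best], cutoff_spec = spec[best],
                 cutoff_sens_ci95 = as.numeric(sens_ci),
                 cutoff_spec_ci95 = as.numeric(spec_ci),
                 n_pos = n1, n_neg = n0, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f), n = %d+/%d-\n",
              x$auc, x$auc_se, x$auc_ci95[1], x$auc_ci95[2], x$n_pos, x$n_neg))
  cat(sprintf("  cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$cutoff_sens, 100 * x$cutoff_spec))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Combine an entropy score with a weighted omission rate
#'
#' `combined_i = apen_i + w * omission_i` on the raw scales (entropy score
#' around 0-1, omission rate in percent); `standardize = TRUE` z-scores
#' both inputs first, removing the unit dependence.
#'
#' @param apen_values,omission_rates Aligned numeric vectors.
#' @param w Weight in `[0, 1]`.
#' @param standardize Z-score inputs before combining.
#' @return Numeric vector of combined scores.
#' @export
combine_scores <- function(apen_values, omission_rates, w,
                           standardize = FALSE) {
  if (length(apen_values) != length(omission_rates))
    stop("apen_values and omission_rates must have the same length")
  stopifnot(w >= 0, w <= 1)
  if (standardize) {
    apen_values <- as.numeric(scale(apen_values))
    omission_rates <- as.numeric(scale(omission_rates))
  }
  apen_values + w * omission_rates
}

#' Weight sweep for the combined score
#'
#' Evaluates [roc()] of `apen + w * omission` for w in 0, 0.1, ..., 1 and
#' reports the full AUC grid plus the best-AUC weight.
#'
#' @inheritParams combine_scores
#' @param labels Binary group labels.
#' @param weights Weight grid (default 0 to 1 by 0.1).
#' @return List with `sweep` (data frame w, auc), `best_w`, `best_auc`,
#'   `best_roc`.
#' @export
combine_weight_sweep <- function(apen_values, omission_rates, labels,
                                 weights = seq(0, 1, by = 0.1),
                                 standardize = FALSE) {
  rocs <- lapply(weights, function(w)
    roc(combine_scores(apen_values, omission_rates, w, standardize), labels))
  aucs <- vapply(rocs, function(r) r$auc, numeric(1))
  best <- which.max(aucs)
  list(sweep = data.frame(w = weights, auc = aucs),
       best_w = weights[best], best_auc = aucs[best], best_roc = rocs[[best]])
}

# B bootstrap means (resample with replacement, size = length(values))
bootstrap_cell <- function(values, B) {
  n <- length(values)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  rowMeans(matrix(values[idx], nrow = B))
}

#' Bootstrap resampling of group x condition means
#'
#' For each cell (group x condition) draws `B` resamples with replacement of
#' the cell's own size and keeps the resampled means; then (1) fits a
#' Gaussian kernel density per cell (Silverman's bandwidth), (2) runs a
#' one-way ANOVA across all cells of the resampled means with Bonferroni
#' pairwise mean differences and adjusted 95% CIs over all pairs, and (3)
#' computes a ROC on the bootstrapped means per condition (patient vs
#' control). Reproducible under `seed`.
#'
#' @param cells Named list of numeric vectors; names `"group:condition"`
#'   (e.g. `"control:target"`). Each cell needs >= 2 values.
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param positive_group Group treated as positive in the per-condition ROC.
#' @return An object of class `bootstrap_result`: `means` (B x cells
#'   matrix), `densities`, `cell_summary` (per-cell mean and 95% percentile
#'   CI), `anova` (`stat_result`; `NULL` with a single cell), `pairwise`
#'   (all pairwise mean differences with Bonferroni CIs), `roc_by_condition`,
#'   `B`, `seed`.
#' @export
bootstrap_means <- function(cells, B = 1000, seed = 1L,
                            positive_group = "mdd") {
  if (B < 2) stop("B must be at least 2")
  if (is.null(names(cells)) || any(names(cells) == ""))
    stop("cells must be a fully named list ('group:condition')")
  for (nm in names(cells)) if (length(cells[[nm]]) < 2)
    stop("cell '", nm, "' needs at least 2 values")
  means <- with_seed(seed, {
    vapply(cells, bootstrap_cell, numeric(B), B = B)
  })
  densities <- apply(means, 2, stats::density, simplify = FALSE)
  nm <- colnames(means)
  cell_summary <- data.frame(
    cell = nm,
    mean = colMeans(means),
    ci_lower = apply(means, 2, stats::quantile, 0.025),
    ci_upper = apply(means, 2, stats::quantile, 0.975),
    row.names = NULL)
  pair <- NULL; anova_res <- NULL
  if (length(nm) >= 2) {
    cell_f <- factor(rep(nm, each = B), levels = nm)
    vals <- as.vector(means)
    fit <- stats::aov(vals ~ cell_f)
    tab <- summary(fit)[[1]]
    mse <- tab["Residuals", "Mean Sq"]; df_res <- tab["Residuals", "Df"]
    k <- choose(length(nm), 2)
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      diff <- mean(means[, i]) - mean(means[, j])
      se <- sqrt(mse * 2 / B)
      tval <- diff / se
      tcrit <- stats::qt(1 - 0.05 / (2 * k), df_res)
      pair <- rbind(pair, data.frame(
        comparison = paste(nm[i], "vs", nm[j]), mean_diff = diff,
        t = tval, p_adj = min(1, k * 2 * stats::pt(-abs(tval), df_res)),
        ci_lower = diff - tcrit * se, ci_upper = diff + tcrit * se))
    }
    anova_res <- structure(
      list(test = "one-way ANOVA across bootstrap cells",
           anova = tab, statistic = tab["cell_f", "F value"],
           p_value = tab["cell_f", "Pr(>F)"], alpha = 0.05,
           significant = tab["cell_f", "Pr(>F)"] < 0.05),
      class = "stat_result")
  }
  # per-condition ROC on bootstrapped means (patient vs control)
  split_nm <- strsplit(nm, ":", fixed = TRUE)
  groups <- vapply(split_nm, `[`, character(1), 1)
  conds <- vapply(split_nm, `[`, character(1), 2)
  roc_by_condition <- list()
  for (cond in unique(conds)) {
    pos <- which(conds == cond & groups == positive_group)
    neg <- which(conds == cond & groups != positive_group)
    if (length(pos) == 1 && length(neg) == 1) {
      sc <- c(means[, pos], means[, neg])
      lb <- rep(c(TRUE, FALSE), each = B)
      roc_by_condition[[cond]] <- roc(sc, lb)
    }
  }
  structure(list(means = means, densities = densities,
                 cell_summary = cell_summary, anova = anova_res,
                 pairwise = pair, roc_by_condition = roc_by_condition,
                 B = B, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d over %d cell(s)\n", x$B, ncol(x$means)))
  if (!is.null(x$anova))
    cat(sprintf("  one-way ANOVA: F = %.3g (p = %.3g); %d pairwise comparisons\n",
                x$anova$statistic, x$anova$p_value, nrow(x$pairwise)))
  for (cond in names(x$roc_by_condition))
    cat(sprintf("  %s: bootstrap AUC = %.3f (SE %.4f)\n", cond,
                x$roc_by_condition[[cond]]$auc, x$roc_by_condition[[cond]]$auc_se))
  invisible(x)
}

#' @export
plot.bootstrap_result <- function(x, ...) {
  rng_x <- range(vapply(x$densities, function(d) range(d$x), numeric(2)))
  rng_y <- c(0, max(vapply(x$densities, function(d) max(d$y), numeric(1))))
  graphics::plot(NULL, xlim = rng_x, ylim = rng_y,
                 xlab = "bootstrapped mean", ylab = "density", ...)
  for (i in seq_along(x$densities))
    graphics::lines(x$densities[[i]], col = i)
  graphics::legend("topright", legend = names(x$densities),
                   col = seq_along(x$densities), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
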