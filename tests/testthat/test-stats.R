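test_that("Mann-Whitney matches exact enumeration on separated groups", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)  # 2 / choose(6,3)
  same <- mann_whitney(rnorm(10), rnorm(10))
  expect_true(same$p_value > 0)
  ident <- mann_whitney(1:10 + 0.5, 1:10 + 0.5)
  expect_gte(ident$p_value, 0.99)
  expect_error(mann_whitney(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney rejection rate tracks a simulation oracle under shift", {
  set.seed(1)
  n_sim <- 400
  rej <- mean(vapply(seq_len(n_sim), function(k)
    mann_whitney(rnorm(18), rnorm(18) + 1)$p_value < 0.05, logical(1)))
  # power oracle for d = 1 at n = 18/18 is ~0.82 (normal-shift theory)
  expect_gt(rej, 0.70)
  expect_lt(rej, 0.93)
})

test_that("two-way ANOVA reproduces a hand-computed table on balanced data", {
  # balanced 2x3, 2 reps, known cell means, no noise: sums of squares are
  # closed-form; per-cell replicate jitter added for a finite-F variant
  cell_means <- matrix(c(1, 2, 3,
                         2, 4, 6), 2, byrow = TRUE)
  g <- rep(rep(c("a", "b"), each = 3), times = 2)
  cond <- rep(c("x", "y", "z"), times = 4)
  y0 <- rep(as.vector(t(cell_means)), times = 2)
  res0 <- two_way_anova_bonferroni(y0, g, cond)
  grand <- mean(cell_means)
  ss_group <- 6 * sum((rowMeans(cell_means) - grand)^2)
  ss_cond <- 4 * sum((colMeans(cell_means) - grand)^2)
  ss_int <- 2 * sum((cell_means - outer(rowMeans(cell_means) - grand,
                                        colMeans(cell_means) - grand, "+") -
                       grand)^2)
  expect_equal(res0$anova["group", "Sum Sq"], ss_group)
  expect_equal(res0$anova["condition", "Sum Sq"], ss_cond)
  expect_equal(res0$anova["group:condition", "Sum Sq"], ss_int)
  expect_equal(res0$anova["Residuals", "Sum Sq"], 0)
  # all-equal responses: F = 0 by convention
  flat <- two_way_anova_bonferroni(rep(3, 12), g, cond)
  expect_equal(unname(flat$anova[["F value"]][1:3]), c(0, 0, 0))
})

test_that("Bonferroni post hoc multiplies raw p by the contrast count", {
  set.seed(2)
  g <- rep(c("a", "b"), each = 9)
  cond <- rep(rep(c("x", "y", "z"), each = 3), times = 2)
  y <- rnorm(18) + (g == "b") * (cond == "x")
  res <- two_way_anova_bonferroni(y, g, cond)
  expect_equal(nrow(res$posthoc), 3)
  mse <- res$anova["Residuals", "Mean Sq"]
  df <- res$anova["Residuals", "Df"]
  vx <- y[cond == "x"]
  tval <- (mean(vx[1:3]) - mean(vx[4:6])) / sqrt(mse * (2 / 3))
  p_raw <- 2 * pt(-abs(tval), df)
  expect_equal(res$posthoc$p_adj[res$posthoc$condition == "x"],
               min(1, 3 * p_raw))
  expect_true(all(res$posthoc$ci_lower <= res$posthoc$ci_upper))
  expect_error(two_way_anova_bonferroni(y[cond != "x" | g != "a"],
                                        g[cond != "x" | g != "a"],
                                        cond[cond != "x" | g != "a"]),
               "empty cell")
})

test_that("channelwise t-tests equal the textbook pooled formula", {
  set.seed(3)
  a <- matrix(rnorm(18 * 7), 18, 7,
              dimnames = list(NULL, c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")))
  b <- matrix(rnorm(18 * 7, mean = 0.8), 18, 7, dimnames = dimnames(a))
  res <- channelwise_ttests(a, b)
  expect_equal(nrow(res), 7)
  ch <- "F7"
  sp <- sqrt(((18 - 1) * var(a[, ch]) + (18 - 1) * var(b[, ch])) / 34)
  t_manual <- (mean(a[, ch]) - mean(b[, ch])) / (sp * sqrt(2 / 18))
  expect_equal(res$t[res$channel == ch], t_manual)
  # identical groups: t = 0, p = 1
  res0 <- channelwise_ttests(a, a)
  expect_equal(res0$t, rep(0, 7))
  expect_equal(res0$p_value, rep(1, 7))
  # zero variance in both groups is flagged
  za <- matrix(1, 4, 1, dimnames = list(NULL, "Cz"))
  resz <- channelwise_ttests(za, za)
  expect_true(resz$degenerate)
  expect_true(is.na(resz$p_value))
})

test_that("Spearman handles monotone, reversed and constant inputs", {
  expect_equal(spearman(1:10, (1:10)^3)$estimate, 1)
  expect_equal(spearman(1:10, rev(1:10))$estimate, -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("empirical ROC matches hand enumeration and pROC", {
  r <- roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$cutoff_sens, 1)
  expect_equal(r$cutoff_spec, 1)
  # perfect separation in reverse direction
  r2 <- roc(c(4, 3, 2, 1), c(0, 0, 1, 1), direction = "<")
  expect_equal(r2$auc, 1)
  # label/sign symmetry
  set.seed(4)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(roc(sc, lb)$auc, 1 - roc(-sc, lb)$auc)
  # sensitivity/specificity arrays are monotone over thresholds
  rr <- roc(sc, lb)
  expect_true(all(diff(rr$sensitivity) <= 0))
  expect_true(all(diff(rr$specificity) >= 0))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(lb, sc, direction = "<", quiet = TRUE)
  expect_equal(rr$auc, as.numeric(pROC::auc(pr)))
  expect_error(roc(sc, rep(1, 40)), "both classes")
})

test_that("ROC of label-independent scores approaches 0.5", {
  set.seed(5)
  r <- roc(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("score combination and the weight sweep behave as designed", {
  set.seed(6)
  apen <- rnorm(36, 0.5, 0.2)            # uninformative
  grp <- rep(c(0, 1), each = 18)
  omission <- rnorm(36, 2, 1) + 6 * grp  # strongly separating
  expect_equal(combine_scores(apen, omission, 0), apen)
  expect_error(combine_scores(apen, omission[-1], 0.5), "length")
  sw <- combine_weight_sweep(apen, omission, grp)
  expect_equal(nrow(sw$sweep), 11)
  expect_equal(sw$sweep$w, seq(0, 1, by = 0.1))
  expect_gt(sw$best_w, 0)
  expect_gte(sw$best_auc, max(sw$sweep$auc[1]))
})

test_that("bootstrap means have the CLT scaling and exact bookkeeping", {
  set.seed(7)
  cells <- list("control:resting" = rnorm(18, 5, 2),
                "control:target" = rnorm(18, 4, 2),
                "control:nontarget" = rnorm(18, 4.5, 2),
                "mdd:resting" = rnorm(18, 4.8, 2),
                "mdd:target" = rnorm(18, 6, 2),
                "mdd:nontarget" = rnorm(18, 5.5, 2))
  bs <- bootstrap_means(cells, B = 1000, seed = 11)
  expect_equal(dim(bs$means), c(1000, 6))
  expect_equal(nrow(bs$pairwise), 15)  # choose(6,2)
  expect_length(bs$roc_by_condition, 3)
  for (nm in names(cells)) {
    expect_lt(abs(mean(bs$means[, nm]) - mean(cells[[nm]])),
              5 * sd(cells[[nm]]) / sqrt(18) / sqrt(1000))
    expect_lt(abs(sd(bs$means[, nm]) - sd(cells[[nm]]) / sqrt(18) * sqrt(17 / 18)),
              0.15 * sd(cells[[nm]]) / sqrt(18))
  }
  # bit-reproducible under the seed
  bs2 <- bootstrap_means(cells, B = 1000, seed = 11)
  expect_identical(bs$means, bs2$means)
  # degenerate cell: all resampled means equal the value, zero-width CI
  dg <- bootstrap_means(list("a:x" = rep(3, 5)), B = 200, seed = 1)
  expect_true(all(dg$means == 3))
  expect_equal(dg$cell_summary$ci_lower, dg$cell_summary$ci_upper)
  expect_error(bootstrap_means(cells, B = 1), "at least 2")
})

test_that("bootstrap ROC separates the arms it is given", {
  set.seed(8)
  cells <- list("control:target" = rnorm(18, 0.35, 0.3),
                "mdd:target" = rnorm(18, 0.7, 0.4))
  bs <- bootstrap_means(cells, B = 500, seed = 3)
  expect_gt(bs$roc_by_condition$target$auc, 0.9)
  expect_true(all(bs$roc_by_condition$target$auc_ci95 <= 1))
})
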