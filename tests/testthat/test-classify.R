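# PC-LDA and bootstrapped random-forest classification.

test_that("Tw matches the dense eigenproblem oracle on small instances", {
  set.seed(31)
  for (rep in 1:5) {
    g <- sample(2:4, 1)
    n <- 12 * g; p <- sample(4:10, 1)
    y <- rep(letters[1:g], each = 12)
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + 2 * as.integer(factor(y))
    res <- pc_lda(x, y, var_kept = 1)
    ora <- lda_eigen_oracle(x, y, res$pcs_retained)
    ndf <- length(res$tw)
    expect_equal(res$tw, ora[seq_len(ndf)], tolerance = 1e-8)
  }
})

test_that("Tw is near zero without class separation and large with it", {
  set.seed(11)
  x <- matrix(rnorm(50 * 10), 50, 10)
  y <- rep(c("a", "b"), 25)
  expect_lt(pc_lda(x, y)$tw[1], 0.5)

  x2 <- matrix(rnorm(50 * 10), 50, 10)
  x2[y == "b", 3] <- x2[y == "b", 3] + 10   # 10-sd shift on one feature
  res <- pc_lda(x2, y)
  expect_gt(res$tw[1], 5)
  # df scores bimodal: classes fully separated on DF1
  d1 <- res$df_scores[, 1]
  expect_true(max(d1[y == "a"]) < min(d1[y == "b"]) ||
              max(d1[y == "b"]) < min(d1[y == "a"]))
})

test_that("number of discriminant functions is classes minus one", {
  set.seed(2)
  x <- matrix(rnorm(30 * 8), 30, 8)
  y <- rep(c("a", "b", "c"), each = 10)
  res <- pc_lda(x, y, var_kept = 1)
  expect_equal(length(res$tw), 2L)
  expect_equal(ncol(res$df_scores), 2L)
  expect_true(all(diff(res$tw) <= 1e-9))   # non-increasing
  expect_true(all(res$tw >= 0))
})

test_that("pc_lda validates input and regularizes singular scatter", {
  x <- matrix(rnorm(20 * 5), 20, 5)
  expect_error(pc_lda(x, rep("a", 20)), "two classes")
  expect_error(pc_lda(x, c("b", rep("a", 19))), "at least 2 samples")
  # each class one unique row repeated: within-class scatter exactly zero
  xs <- x[rep(1:2, each = 10), ]
  ys <- rep(c("a", "b"), each = 10)
  expect_message(pc_lda(xs, ys, var_kept = 1), "ridge")
})

test_that("permuted labels give near-zero margin and no adequacy", {
  sim <- generate_lipidome(small_config(seed = 21))
  lg <- log2_transform(sim$matrix)
  md <- sim$metadata
  idx <- which(md$breed %in% c("A", "B"))
  set.seed(99)
  perm <- sample(md$breed[idx])
  rep0 <- rf_bootstrap_classify(subset_matrix(lg, samples = idx), perm,
                                fast_scheme(seed = 21, n_bootstraps = 20))
  expect_lt(abs(rep0$margin), 0.15)
  expect_false(rep0$adequate)
})

test_that("an overwhelming planted effect yields an adequate model", {
  sim <- generate_lipidome(small_config(seed = 22, effect_log2fc = 3,
                                        noise_sd = 0.3))
  lg <- log2_transform(sim$matrix)
  md <- sim$metadata
  # meta-class 2 separates A+C from B+D with many informative features
  lab <- ifelse(md$breed %in% c("A", "C"), "mc", "rest")
  rep1 <- rf_bootstrap_classify(lg, lab, fast_scheme(seed = 22, n_bootstraps = 20))
  expect_gt(rep1$margin, 0.5)
  expect_gt(rep1$auc, 0.95)
  expect_true(rep1$adequate)
})

test_that("reports are deterministic and scores stay in range", {
  sim <- generate_lipidome(small_config(seed = 23))
  lg <- log2_transform(sim$matrix)
  md <- sim$metadata
  idx <- which(md$breed %in% c("A", "C"))
  r1 <- rf_bootstrap_classify(subset_matrix(lg, samples = idx),
                              md$breed[idx], fast_scheme(seed = 7))
  r2 <- rf_bootstrap_classify(subset_matrix(lg, samples = idx),
                              md$breed[idx], fast_scheme(seed = 7))
  expect_identical(r1$per_bootstrap, r2$per_bootstrap)
  expect_true(all(r1$per_bootstrap$margin >= -1 & r1$per_bootstrap$margin <= 1))
  expect_true(all(r1$per_bootstrap$auc >= 0 & r1$per_bootstrap$auc <= 1))
  expect_true(all(r1$per_bootstrap$acc >= 0 & r1$per_bootstrap$acc <= 1))
})

test_that("duplicating a feature leaves scores nearly unchanged", {
  sim <- generate_lipidome(small_config(seed = 24))
  lg <- log2_transform(sim$matrix)
  md <- sim$metadata
  idx <- which(md$breed %in% c("A", "C"))
  x <- lg$intensities[idx, ]
  r1 <- rf_bootstrap_classify(x, md$breed[idx], fast_scheme(seed = 3, n_bootstraps = 20))
  x10 <- cbind(x, x[, rep(5, 10)])
  colnames(x10) <- make.unique(colnames(x10))
  r2 <- rf_bootstrap_classify(x10, md$breed[idx], fast_scheme(seed = 3, n_bootstraps = 20))
  mc_sd <- stats::sd(r1$per_bootstrap$margin) / sqrt(r1$n_bootstraps)
  expect_lt(abs(r1$margin - r2$margin), 0.05 + 4 * mc_sd)
})

test_that("tiny classes are rejected by name", {
  x <- matrix(rnorm(10 * 5), 10, 5)
  y <- c(rep("big", 8), rep("tiny", 2))
  expect_error(rf_bootstrap_classify(x, y, fast_scheme()), "tiny")
})

test_that("an independent forest engine agrees on a separable problem", {
  skip_if_not_installed("randomForest")
  sim <- generate_lipidome(small_config(seed = 25, effect_log2fc = 3))
  lg <- log2_transform(sim$matrix)
  md <- sim$metadata
  lab <- factor(ifelse(md$breed %in% c("A", "C"), "mc", "rest"))
  ours <- rf_bootstrap_classify(lg, lab, fast_scheme(seed = 9, n_bootstraps = 15))
  # cross-check with randomForest on the same data: out-of-bag votes
  set.seed(9)
  rf <- randomForest::randomForest(lg$intensities, lab, ntree = 500)
  oob_auc <- lipidbreed:::rank_auc(rf$votes[, levels(lab)[2]], lab)
  expect_gt(ours$auc, 0.9)
  expect_gt(oob_auc, 0.9)
  expect_lt(abs(ours$auc - oob_auc), 0.1)
})
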