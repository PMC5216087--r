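# Supervised workflow: PCA -> PC-LDA with Tw separation eigenvalues, and
# bootstrapped random-forest classification scored by margin, AUC and ACC.

#' Bootstrap resampling scheme
#'
#' Controls the randomized resampling used for classification and feature
#' ranking: repeated stratified 2/3 train / 1/3 test splits with a fresh
#' forest per split.
#'
#' @param n_bootstraps Number of resampling rounds (default 100).
#' @param train_fraction Fraction of each class used for training
#'   (default 2/3).
#' @param ntree Trees per forest (default 1000).
#' @param stratified Stratify splits by class (default TRUE).
#' @param mtry_frac Fraction of features tried at each split; `NULL`
#'   (default) uses the conventional sqrt(p) draw, widened to p/3
#'   whenever the training split falls below 30 samples - at such n the
#'   split search is otherwise dominated by noise features that separate
#'   the classes perfectly by chance.
#' @param seed Integer seed; fixes splits and forests.
#' @return A list of class `"bootstrap_scheme"`.
#' @export
bootstrap_scheme <- function(n_bootstraps = 100L, train_fraction = 2 / 3,
                             ntree = 1000L, stratified = TRUE,
                             mtry_frac = NULL, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_bootstraps >= 1,
            ntree >= 1,
            is.null(mtry_frac) || (mtry_frac > 0 && mtry_frac <= 1))
  structure(list(n_bootstraps = as.integer(n_bootstraps),
                 train_fraction = train_fraction, ntree = as.integer(ntree),
                 stratified = stratified, mtry_frac = mtry_frac,
                 seed = as.integer(seed)),
            class = "bootstrap_scheme")
}

# Stratified train/test split indices for one bootstrap round.
# Guarantees >= 2 training and >= 1 test sample per class.
stratified_split <- function(y, train_fraction, stratified = TRUE) {
  idx <- seq_along(y)
  if (!stratified) {
    ntr <- max(2L, min(length(y) - 1L, floor(length(y) * train_fraction)))
    train <- sample(idx, ntr)
    return(list(train = train, test = setdiff(idx, train)))
  }
  train <- unlist(lapply(split(idx, y), function(ii) {
    ntr <- max(2L, min(length(ii) - 1L, floor(length(ii) * train_fraction)))
    sample(ii, ntr)
  }), use.names = FALSE)
  list(train = sort(train), test = setdiff(idx, sort(train)))
}

# Rank-based AUC of scores for the second level of y (ties get mean ranks).
rank_auc <- function(scores, y) {
  lv <- levels(y)
  pos <- y == lv[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrapped random-forest classification
#'
#' For each bootstrap round: a stratified 2/3-1/3 split, a random forest of
#' `ntree` trees fit on the training part, and test-set scores: the
#' classification margin (per test sample, vote fraction for the true class
#' minus the largest vote fraction for any other class), the AUC of the
#' vote fractions, and the accuracy of the majority vote. Scores are
#' averaged over bootstraps and a model is flagged adequate when
#' margin > 0.2 and AUC and/or ACC > 0.8.
#'
#' @param x A `feature_matrix` or numeric samples x features matrix.
#' @param labels Binary class labels (factor or character), one per sample.
#' @param scheme A [bootstrap_scheme()].
#' @param comparison Optional label for the comparison being modelled.
#' @return A list of class `"class_model_report"` with `margin`, `auc`,
#'   `acc`, `adequate`, `per_bootstrap` (data frame) and the scheme used.
#' @export
rf_bootstrap_classify <- function(x, labels, scheme = bootstrap_scheme(),
                                  comparison = NULL) {
  x <- as_intensity_matrix(x)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("labels must define exactly two classes")
  small <- table(y) < 3L
  if (any(small)) {
    stop("class with fewer than 3 samples: ",
         paste(names(which(small)), collapse = ", "))
  }
  stopifnot(nrow(x) == length(y))
  if (is.null(comparison)) comparison <- paste(levels(y), collapse = " vs ")

  set.seed(scheme$seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, scheme$n_bootstraps)
  per <- matrix(NA_real_, scheme$n_bootstraps, 3,
                dimnames = list(NULL, c("margin", "auc", "acc")))
  for (b in seq_len(scheme$n_bootstraps)) {
    sp <- stratified_split(y, scheme$train_fraction, scheme$stratified)
    # resampling uncertainty is carried by the outer bootstrap loop; each
    # tree sees the full training split (no inner bootstrap, which at these
    # n leaves too few minority samples and floods the split search with
    # spuriously separating noise features), with feature subsampling as
    # the only source of tree diversity
    fit <- ranger::ranger(x = x[sp$train, , drop = FALSE], y = y[sp$train],
                          num.trees = scheme$ntree, probability = TRUE,
                          min.node.size = 1L, replace = FALSE,
                          sample.fraction = 1,
                          mtry = scheme_mtry(scheme, ncol(x),
                                             length(sp$train)),
                          num.threads = 1L, seed = boot_seeds[b])
    pr <- stats::predict(fit, data = x[sp$test, , drop = FALSE],
                         num.threads = 1L)$predictions
    pr <- pr[, levels(y), drop = FALSE]
    yte <- y[sp$test]
    p_true <- pr[cbind(seq_along(yte), as.integer(yte))]
    per[b, "margin"] <- mean(p_true - (1 - p_true))
    per[b, "auc"] <- rank_auc(pr[, 2], yte)
    pred <- levels(y)[1L + (pr[, 2] > 0.5)]
    per[b, "acc"] <- mean(pred == as.character(yte))
  }
  margin <- mean(per[, "margin"]); auc <- mean(per[, "auc"])
  acc <- mean(per[, "acc"])
  structure(list(comparison = comparison, margin = margin, auc = auc,
                 acc = acc, n_bootstraps = scheme$n_bootstraps,
                 per_bootstrap = as.data.frame(per),
                 adequate = margin > 0.2 && (auc > 0.8 || acc > 0.8),
                 scheme = scheme),
            class = "class_model_report")
}

#' @export
print.class_model_report <- function(x, ...) {
  cat(sprintf("%s: margin %.3f, AUC %.3f, ACC %.3f (%d bootstraps) -> %s\n",
              x$comparison, x$margin, x$auc, x$acc, x$n_bootstraps,
              if (x$adequate) "adequate" else "not adequate"))
  invisible(x)
}

as_intensity_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x$intensities else as.matrix(x)
}

scheme_mtry <- function(scheme, p, n_train = Inf) {
  if (!is.null(scheme$mtry_frac)) return(max(1L, floor(p * scheme$mtry_frac)))
  if (n_train < 30) max(1L, floor(p / 3)) else max(1L, floor(sqrt(p)))
}

#' PC-LDA: linear discriminant analysis on principal-component scores
#'
#' PCA on the mean-centred matrix retains the smallest number of components
#' reaching `var_kept` cumulative variance (capped at n - g so the
#' within-class scatter stays invertible). LDA then solves the generalized
#' eigenproblem `Sb v = lambda Sw v` on the retained scores, where Sw and
#' Sb are the within- and between-class scatter matrices (sums of squares,
#' not covariances). The eigenvalues Tw quantify goodness of class
#' separation; samples are projected onto the discriminant functions.
#'
#' @param x A `feature_matrix` or numeric samples x features matrix.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples).
#' @param var_kept Cumulative variance fraction to retain (default 0.95).
#' @return A list of class `"pc_lda"`: `df_scores` (samples x DFs), `tw`
#'   (eigenvalues, non-increasing), `pcs_retained`, `explained_variance`.
#' @export
pc_lda <- function(x, labels, var_kept = 0.95) {
  x <- as_intensity_matrix(x)
  y <- droplevels(as.factor(labels))
  g <- nlevels(y)
  if (g < 2L) stop("need at least two classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  stopifnot(var_kept > 0, var_kept <= 1, nrow(x) == length(y))
  n <- nrow(x)

  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  npc <- which(cum >= var_kept - 1e-12)[1]
  npc <- max(1L, min(npc, n - g))
  S <- pc$x[, seq_len(npc), drop = FALSE]

  mu <- colMeans(S)
  Sw <- matrix(0, npc, npc); Sb <- matrix(0, npc, npc)
  for (cl in levels(y)) {
    Sc <- S[y == cl, , drop = FALSE]
    mc <- colMeans(Sc)
    Xc <- sweep(Sc, 2, mc)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Sc) * tcrossprod(mc - mu)
  }
  ew <- eigen(Sw, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-10) {
    eps <- max(ew$values) * 1e-8 + 1e-8
    message(sprintf("pc_lda: singular within-class scatter, ridge epsilon %.3g",
                    eps))
    ew$values <- ew$values + eps
  }
  W_half_inv <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  A <- W_half_inv %*% Sb %*% W_half_inv
  A <- (A + t(A)) / 2
  ea <- eigen(A, symmetric = TRUE)
  ndf <- min(g - 1L, npc)
  tw <- pmax(ea$values[seq_len(ndf)], 0)
  V <- W_half_inv %*% ea$vectors[, seq_len(ndf), drop = FALSE]
  df_scores <- sweep(S, 2, mu) %*% V
  colnames(df_scores) <- sprintf("DF%d", seq_len(ndf))
  rownames(df_scores) <- rownames(x)
  structure(list(df_scores = df_scores, tw = tw, pcs_retained = npc,
                 explained_variance = cum[npc], labels = y),
            class = "pc_lda")
}

#' @export
print.pc_lda <- function(x, ...) {
  cat(sprintf("pc_lda: %d PCs (%.1f%% variance), Tw = %s\n",
              x$pcs_retained, 100 * x$explained_variance,
              paste(sprintf("%.3f", x$tw), collapse = ", ")))
  invisible(x)
}
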