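# Per-feature explanatory-signal ranking: permutation importance (RFIS),
# orientation-folded univariate AUC, Welch t-test with Benjamini-Hochberg
# FDR, and |r| > 0.8 correlation clustering of selected features.

# Vectorized Welch (unequal-variance) t-test over matrix columns.
# Returns p-values and the class-1 minus class-2 mean difference.
welch_t_columns <- function(x, y) {
  lv <- levels(y)
  x1 <- x[y == lv[1], , drop = FALSE]
  x2 <- x[y == lv[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- se2 <= 0 | !is.finite(p)
  p[zero_var] <- 1
  list(p = p, diff = m1 - m2, zero_var = zero_var)
}

#' Rank features for a binary comparison
#'
#' Combines three criteria over the same stratified bootstrap splits used
#' for classification: the random-forest importance score (RFIS; the mean
#' decrease in classification accuracy when a feature's values are
#' permuted, measured out-of-split on each bootstrap's held-out third and
#' averaged over bootstraps), the orientation-folded univariate AUC, and a
#' Welch t-test with Benjamini-Hochberg FDR correction. Features are sorted by
#' RFIS (descending), ties broken by p-value then name. Zero-variance
#' features get p = 1, RFIS 0 and are flagged.
#'
#' Rank-based scores are invariant to monotone transforms, but the t-test
#' and direction calls assume roughly log-scale intensities; pass a
#' [log2_transform()]ed matrix.
#'
#' @param x A `feature_matrix` or numeric samples x features matrix.
#' @param labels Binary class labels.
#' @param scheme A [bootstrap_scheme()] controlling splits and forests.
#' @param mtry_frac Fraction of features tried per split in the ranking
#'   forests (default 1/3). Importance-based selection needs informative
#'   features to be drawn often enough to register; the conventional
#'   sqrt(p) draw leaves permutation importances sparse and noisy in
#'   p >> n profiles, so ranking uses the larger draw favoured in the
#'   random-forest variable-selection literature. Classification forests
#'   keep their own (scheme) setting.
#' @return Data frame of class `"ranked_features"`: `name`, `rfis`,
#'   `uni_auc`, `p_value`, `q_value`, `direction` (elevated/decreased in
#'   class 1 relative to class 2, classes in factor-level order),
#'   `zero_variance`. The class levels are stored in
#'   `attr(, "class_levels")`.
#' @export
rank_features <- function(x, labels, scheme = bootstrap_scheme(),
                          mtry_frac = 1 / 3) {
  xm <- as_intensity_matrix(x)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("labels must define exactly two classes")
  stopifnot(nrow(xm) == length(y))
  if (is.null(colnames(xm))) colnames(xm) <- sprintf("F%d", seq_len(ncol(xm)))

  set.seed(scheme$seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, scheme$n_bootstraps)
  imp <- numeric(ncol(xm))
  for (b in seq_len(scheme$n_bootstraps)) {
    sp <- stratified_split(y, scheme$train_fraction, scheme$stratified)
    # holdout mode: trees are grown on the training split only (weight 0
    # excludes the test third) and permutation importance is scored on the
    # held-out samples - the out-of-split estimator of the accuracy
    # decrease when a feature is omitted. Trees subsample 3/4 of the
    # training split so that credit for a redundant signal block is
    # spread over its members rather than concentrated on one
    # representative.
    w <- as.numeric(seq_along(y) %in% sp$train)
    fit <- ranger::ranger(x = xm, y = y,
                          num.trees = scheme$ntree,
                          importance = "permutation",
                          case.weights = w, holdout = TRUE,
                          min.node.size = 1L, replace = FALSE,
                          sample.fraction = 0.75,
                          mtry = max(1L, floor(ncol(xm) * mtry_frac)),
                          num.threads = 1L, seed = boot_seeds[b])
    imp <- imp + fit$variable.importance
  }
  rfis <- imp / scheme$n_bootstraps

  lv <- levels(y)
  auc <- apply(xm, 2, function(col) rank_auc(col, y))
  uni_auc <- pmax(auc, 1 - auc)
  wt <- welch_t_columns(xm, y)
  q <- stats::p.adjust(wt$p, method = "BH")
  rfis[wt$zero_var] <- 0

  out <- data.frame(
    name = colnames(xm),
    rfis = as.numeric(rfis),
    uni_auc = as.numeric(uni_auc),
    p_value = as.numeric(wt$p),
    q_value = as.numeric(q),
    direction = ifelse(wt$diff > 0, "elevated", "decreased"),
    zero_variance = wt$zero_var,
    stringsAsFactors = FALSE)
  out <- out[order(-out$rfis, out$p_value, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_levels") <- lv
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Single-linkage correlation clusters
#'
#' Computes Pearson correlations between the candidate features over all
#' samples and returns the connected components of the |r| > threshold
#' graph (single linkage), the grouping used to recognise adducts,
#' isotopologues and breakdown products of one metabolite. Constant
#' features have undefined correlation and are excluded with a warning.
#'
#' @param x A `feature_matrix` or numeric samples x features matrix.
#' @param candidates Feature names (or indices) to cluster, in priority
#'   order (e.g. RFIS-ranked); default all features.
#' @param threshold Absolute correlation threshold (default 0.8).
#' @return Data frame `feature`, `cluster_id` (`"C1"`, `"C2"`, ... in
#'   order of first appearance; singletons included), `seed_feature`
#'   (highest-priority member of the feature's cluster).
#' @export
correlation_clusters <- function(x, candidates = NULL, threshold = 0.8) {
  xm <- as_intensity_matrix(x)
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(candidates)) candidates <- colnames(xm)
  if (is.numeric(candidates)) candidates <- colnames(xm)[candidates]
  stopifnot(all(candidates %in% colnames(xm)))
  sub <- xm[, candidates, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("excluding constant features from correlation graph: ",
            paste(candidates[const], collapse = ", "))
  }
  keep <- candidates[!const]
  if (length(keep) == 0L) {
    return(data.frame(feature = character(0), cluster_id = character(0),
                      seed_feature = character(0)))
  }
  r <- stats::cor(sub[, keep, drop = FALSE])
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  # order clusters by the first (highest-priority) member
  first_pos <- tapply(seq_along(keep), comp, min)
  relabel <- stats::setNames(rank(first_pos), names(first_pos))
  cid <- sprintf("C%d", relabel[as.character(comp)])
  seeds <- tapply(seq_along(keep), comp, function(ii) keep[min(ii)])
  out <- data.frame(feature = keep,
                    cluster_id = cid,
                    seed_feature = unname(seeds[as.character(comp)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
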