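# Iterative diet-confounder filtering: lower the RFIS inclusion cutoff on a
# confounded meta-class comparison, expand the removal set by correlated
# features, and stop when the meta-class model collapses.

#' Default descending cutoff schedule
#'
#' Log-uniform descent from 0.01 to 1e-4, covering the working range of
#' RFIS thresholds for diet-signal filtering (the documented heuristic
#' preset is 3e-4).
#'
#' @param from Upper cutoff (default 0.01).
#' @param to Lower cutoff (default 1e-4).
#' @param length.out Number of cutoffs (default 9).
#' @return Strictly decreasing numeric vector.
#' @export
cutoff_schedule <- function(from = 0.01, to = 1e-4, length.out = 9L) {
  stopifnot(from > to, to > 0)
  10^seq(log10(from), log10(to), length.out = length.out)
}

#' Filter confounded signals until the meta-class model collapses
#'
#' For each cutoff `c` in the (strictly decreasing) schedule, the removal
#' set is the features whose RFIS for the confounded meta-class comparison
#' exceeds `c`, expanded once by every feature correlated at
#' |r| > `corr_threshold` with a directly-removed feature (isotopes and
#' adducts of the same metabolite). The meta-class random-forest model is
#' refit on the reduced matrix; filtering stops at the first cutoff where
#' the model is no longer adequate (margin <= 0.2, the collapse criterion),
#' returning the matrix filtered at that cutoff and the full trajectory.
#' The PC-LDA Tw of the reduced matrix is logged at each step but is not
#' the stopping statistic.
#'
#' @param fm A `feature_matrix` (log2 scale recommended).
#' @param metaclass_labels Binary labels, one per sample; `NA` samples
#'   (e.g. a breed excluded from the meta-class design) are ignored when
#'   refitting but retained in the filtered matrix.
#' @param ranked A `ranked_features` table computed on the same meta-class
#'   comparison (see [rank_features()]).
#' @param schedule Strictly decreasing positive cutoffs
#'   (default [cutoff_schedule()]).
#' @param corr_threshold Correlation-expansion threshold (default 0.8).
#' @param scheme [bootstrap_scheme()] for the refits.
#' @return A list with `matrix` (the filtered `feature_matrix`) and
#'   `report` (class `"filter_report"`): `cutoff_trajectory` data frame
#'   (`cutoff`, `n_removed_direct`, `n_removed_correlated`, `margin`,
#'   `tw1`), `final_cutoff`, `removed_features`, `n_before`, `n_after`,
#'   `collapsed`.
#' @export
filter_confounder <- function(fm, metaclass_labels, ranked,
                              schedule = cutoff_schedule(),
                              corr_threshold = 0.8,
                              scheme = bootstrap_scheme()) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(ranked, "ranked_features"))
  if (length(schedule) > 0 && any(diff(schedule) >= 0)) {
    stop("schedule must be strictly decreasing")
  }
  stopifnot(all(schedule > 0))
  y_all <- as.factor(metaclass_labels)
  use <- !is.na(y_all)
  n_before <- ncol(fm$intensities)
  xm <- fm$intensities

  traj <- data.frame(cutoff = numeric(0), n_removed_direct = integer(0),
                     n_removed_correlated = integer(0), margin = numeric(0),
                     tw1 = numeric(0))
  removed <- character(0)
  final_cutoff <- NA_real_
  collapsed <- FALSE

  for (cu in schedule) {
    direct <- ranked$name[ranked$rfis > cu]
    direct <- intersect(direct, colnames(xm))
    correlated <- character(0)
    if (length(direct) > 0 && length(direct) < ncol(xm)) {
      others <- setdiff(colnames(xm), direct)
      rr <- suppressWarnings(
        stats::cor(xm[, others, drop = FALSE], xm[, direct, drop = FALSE]))
      rr[!is.finite(rr)] <- 0
      correlated <- others[apply(abs(rr) > corr_threshold, 1, any)]
    }
    removal <- union(direct, correlated)
    keep <- setdiff(colnames(xm), removal)
    if (length(keep) < 2L) {
      warning("cutoff ", signif(cu, 3), " would remove almost all features; stopping")
      break
    }
    reduced <- subset_matrix(fm, features = keep)
    rep_c <- rf_bootstrap_classify(
      subset_matrix(reduced, samples = which(use)), y_all[use], scheme,
      comparison = sprintf("metaclass @ cutoff %.2g", cu))
    tw1 <- pc_lda(subset_matrix(reduced, samples = which(use)),
                  y_all[use])$tw[1]
    traj <- rbind(traj, data.frame(
      cutoff = cu, n_removed_direct = length(direct),
      n_removed_correlated = length(correlated), margin = rep_c$margin,
      tw1 = tw1))
    removed <- removal
    final_cutoff <- cu
    if (rep_c$margin <= 0.2) { collapsed <- TRUE; break }
  }

  out_fm <- if (length(removed) > 0) {
    subset_matrix(fm, features = setdiff(colnames(xm), removed))
  } else fm
  if (length(schedule) > 0 && !collapsed) {
    warning("schedule exhausted without model collapse")
  }
  report <- structure(list(
    cutoff_trajectory = traj, final_cutoff = final_cutoff,
    removed_features = removed, n_before = n_before,
    n_after = ncol(out_fm$intensities), collapsed = collapsed),
    class = "filter_report")
  list(matrix = out_fm, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d -> %d features (%.1f%% removed), final cutoff %s, %s\n",
    x$n_before, x$n_after,
    100 * (x$n_before - x$n_after) / x$n_before,
    format(signif(x$final_cutoff, 3)),
    if (x$collapsed) "model collapsed" else "no collapse"))
  invisible(x)
}
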