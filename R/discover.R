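# All-pairs breed modelling and breed-unique signal discovery.

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Pairwise breed classification grid
#'
#' Scores every unordered breed pair with [rf_bootstrap_classify()] and
#' tallies, per breed, the number of comparisons meeting the adequacy
#' thresholds (margin > 0.2 and AUC and/or ACC > 0.8). Per-pair seeds are
#' derived deterministically from the scheme seed.
#'
#' @param fm A `feature_matrix`.
#' @param breeds Breed label per sample.
#' @param scheme A [bootstrap_scheme()].
#' @return A list of class `"pairwise_grid"`: `reports` (named by
#'   `"A|B"`), `adequate_count` (named integer per breed), `breeds`.
#' @export
pairwise_grid <- function(fm, breeds, scheme = bootstrap_scheme()) {
  y <- droplevels(as.factor(breeds))
  lv <- levels(y)
  if (length(lv) < 2L) stop("need at least two breeds")
  small <- table(y) < 3L
  if (any(small)) {
    stop("breed with fewer than 3 samples: ",
         paste(names(which(small)), collapse = ", "))
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  set.seed(scheme$seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, length(pairs))
  reports <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    idx <- which(y %in% pr)
    sc <- scheme; sc$seed <- pair_seeds[i]
    reports[[pair_key(pr[1], pr[2])]] <- rf_bootstrap_classify(
      subset_matrix(fm, samples = idx), y[idx], sc,
      comparison = paste(pr, collapse = " vs "))
  }
  adequate_count <- vapply(lv, function(b) {
    sum(vapply(reports, function(r) {
      r$adequate && b %in% strsplit(r$comparison, " vs ")[[1]]
    }, logical(1)))
  }, integer(1))
  structure(list(reports = reports, adequate_count = adequate_count,
                 breeds = lv, scheme = scheme),
            class = "pairwise_grid")
}

#' @export
print.pairwise_grid <- function(x, ...) {
  cat(sprintf("pairwise_grid: %d breeds, %d comparisons, %d adequate\n",
              length(x$breeds), length(x$reports),
              sum(vapply(x$reports, `[[`, logical(1), "adequate"))))
  invisible(x)
}

#' Grid as a table
#'
#' @param grid A `pairwise_grid`.
#' @return Data frame with one row per comparison: `breed_1`, `breed_2`,
#'   `margin`, `auc`, `acc`, `adequate`.
#' @export
grid_table <- function(grid) {
  stopifnot(inherits(grid, "pairwise_grid"))
  rows <- lapply(names(grid$reports), function(k) {
    r <- grid$reports[[k]]
    pr <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(breed_1 = pr[1], breed_2 = pr[2], margin = r$margin,
               auc = r$auc, acc = r$acc, adequate = r$adequate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank features for a set of breed pairs
#'
#' Helper computing (and caching) per-pair [rank_features()] tables, with
#' per-pair seeds derived from the scheme seed. Used by [unique_signals()];
#' exposed so a precomputed cache can be reused across threshold settings.
#'
#' @param fm A `feature_matrix` (log2 scale recommended).
#' @param breeds Breed label per sample.
#' @param pairs List of length-2 character vectors of breed names.
#' @param scheme A [bootstrap_scheme()].
#' @return Named list (by `"A|B"` key) of `ranked_features` tables; class
#'   levels are the sorted pair, so `direction` refers to the
#'   alphabetically first breed.
#' @export
pair_rankings <- function(fm, breeds, pairs, scheme = bootstrap_scheme()) {
  y <- droplevels(as.factor(breeds))
  keys <- vapply(pairs, function(p) pair_key(p[1], p[2]), character(1))
  set.seed(scheme$seed + 1L)
  seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, length(keys)), sort(keys))
  out <- list()
  for (i in seq_along(pairs)) {
    pr <- sort(pairs[[i]])
    idx <- which(y %in% pr)
    sc <- scheme; sc$seed <- seeds[[keys[i]]]
    out[[keys[i]]] <- rank_features(
      subset_matrix(fm, samples = idx),
      factor(as.character(y[idx]), levels = pr), sc)
  }
  out
}

#' Breed-unique signal discovery
#'
#' Breeds with fewer than `min_adequate` adequate pairwise comparisons are
#' dropped. For each remaining breed, candidate features are the
#' intersection, over all its adequate comparisons (or all comparisons
#' with `strict_all = TRUE`), of the top-ranked sets (RFIS > `rfis_min`
#' and p < `p_max`) with a consistent direction relative to the focal
#' breed. A candidate shared by two breeds is not unique and is discarded
#' for both.
#'
#' @param grid A [pairwise_grid()].
#' @param fm The `feature_matrix` the grid was computed on (log2 scale
#'   recommended).
#' @param breeds Breed label per sample.
#' @param scheme [bootstrap_scheme()] for per-pair rankings.
#' @param min_adequate Minimum adequate comparisons for a breed to be
#'   pursued (default 6).
#' @param rfis_min RFIS inclusion threshold (default 0.002).
#' @param p_max p-value inclusion threshold (default 0.05).
#' @param strict_all Require candidates in every comparison, not only the
#'   adequate ones (default FALSE).
#' @param rankings Optional precomputed [pair_rankings()] cache.
#' @return Data frame of class `"unique_signals"`: `breed`, `feature`,
#'   `direction` (in the focal breed), `support` (comparisons
#'   intersected), `rfis_min` (worst RFIS across them), `p_max` (worst
#'   p-value).
#' @export
unique_signals <- function(grid, fm, breeds, scheme = bootstrap_scheme(),
                           min_adequate = 6L, rfis_min = 0.002,
                           p_max = 0.05, strict_all = FALSE,
                           rankings = NULL) {
  stopifnot(inherits(grid, "pairwise_grid"))
  y <- droplevels(as.factor(breeds))
  eligible <- names(which(grid$adequate_count >= min_adequate))
  empty <- data.frame(breed = character(0), feature = character(0),
                      direction = character(0), support = integer(0),
                      rfis_min = numeric(0), p_max = numeric(0))
  if (length(eligible) == 0L) return(structure(empty, class = c("unique_signals", "data.frame")))

  comps_of <- function(b) {
    ks <- Filter(function(k) b %in% strsplit(k, "|", fixed = TRUE)[[1]],
                 names(grid$reports))
    if (strict_all) ks else
      Filter(function(k) grid$reports[[k]]$adequate, ks)
  }
  needed <- unique(unlist(lapply(eligible, comps_of)))
  if (is.null(rankings)) {
    prs <- lapply(needed, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
    rankings <- pair_rankings(fm, y, prs, scheme)
  }

  per_breed <- list()
  for (b in eligible) {
    ks <- comps_of(b)
    if (length(ks) == 0L) next
    cand <- NULL
    for (k in ks) {
      rk <- rankings[[k]]
      lv <- attr(rk, "class_levels")
      sel <- rk[rk$rfis > rfis_min & rk$p_value < p_max, , drop = FALSE]
      if (nrow(sel) == 0L) { cand <- NULL; break }
      # orient direction to the focal breed
      dir_b <- if (lv[1] == b) sel$direction else
        ifelse(sel$direction == "elevated", "decreased", "elevated")
      tab <- data.frame(feature = sel$name, direction = dir_b,
                        rfis = sel$rfis, p = sel$p_value,
                        stringsAsFactors = FALSE)
      if (is.null(cand)) {
        cand <- tab
        cand$rfis_min <- cand$rfis; cand$p_max <- cand$p
      } else {
        m <- match(cand$feature, tab$feature)
        ok <- !is.na(m) & tab$direction[m] == cand$direction
        cand <- cand[ok, , drop = FALSE]
        m <- m[ok]
        cand$rfis_min <- pmin(cand$rfis_min, tab$rfis[m])
        cand$p_max <- pmax(cand$p_max, tab$p[m])
      }
      if (nrow(cand) == 0L) { cand <- NULL; break }
    }
    if (!is.null(cand) && nrow(cand) > 0L) {
      cand$support <- length(ks)
      per_breed[[b]] <- cand
    }
  }
  if (length(per_breed) == 0L) return(structure(empty, class = c("unique_signals", "data.frame")))

  # uniqueness: a feature that is a candidate for more than one breed is
  # part of a shared discriminating series, not breed-unique
  all_feats <- unlist(lapply(per_breed, `[[`, "feature"), use.names = FALSE)
  shared <- unique(all_feats[duplicated(all_feats)])
  rows <- lapply(names(per_breed), function(b) {
    cand <- per_breed[[b]]
    cand <- cand[!cand$feature %in% shared, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    data.frame(breed = b, feature = cand$feature, direction = cand$direction,
               support = cand$support, rfis_min = cand$rfis_min,
               p_max = cand$p_max, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  structure(out, class = c("unique_signals", "data.frame"))
}
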