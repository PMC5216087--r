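# Feature-matrix container, TSV/CSV round trip, 0.01-amu binning and the
# M<mz>T<rt> feature naming convention.

#' Canonical feature name
#'
#' Features are named `M<nearest-integer m/z>T<nearest-integer RT>`, e.g.
#' m/z 705.5889 at RT 366 s becomes `"M706T366"`. Rounding uses R's
#' round-half-to-even convention.
#'
#' @param mz Accurate m/z (positive).
#' @param rt Retention time in seconds (non-negative).
#' @return Character vector of feature names.
#' @examples
#' feature_name(705.5889, 366)
#' @export
feature_name <- function(mz, rt) {
  stopifnot(all(mz > 0), all(rt >= 0))
  sprintf("M%dT%d", as.integer(round(mz)), as.integer(round(rt)))
}

#' Construct a feature matrix
#'
#' A `feature_matrix` holds a samples x features intensity table together
#' with per-feature accurate m/z and retention time. Feature names follow
#' [feature_name()] when not supplied; duplicates get a numeric suffix so
#' column names stay unique.
#'
#' @param intensities Numeric matrix, samples in rows (rownames = sample
#'   ids), features in columns. Must be finite and non-negative.
#' @param mz Numeric vector of feature m/z values (one per column).
#' @param rt Numeric vector of retention times in seconds.
#' @param name Optional character vector of feature names.
#' @return An object of class `"feature_matrix"` with elements
#'   `intensities` (matrix) and `features` (data frame `name`, `mz`, `rt`).
#' @export
feature_matrix <- function(intensities, mz, rt, name = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(is.numeric(intensities),
            length(mz) == ncol(intensities),
            length(rt) == ncol(intensities))
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("S%03d", seq_len(nrow(intensities)))
  }
  if (anyDuplicated(rownames(intensities))) stop("duplicate sample ids")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  stopifnot(all(mz > 0), all(rt >= 0))
  if (is.null(name)) name <- feature_name(mz, rt)
  name <- make.unique(name, sep = "_")
  colnames(intensities) <- name
  structure(list(intensities = intensities,
                 features = data.frame(name = name, mz = as.numeric(mz),
                                       rt = as.numeric(rt),
                                       stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  m/z range %.4f-%.4f, RT range %.0f-%.0f s\n",
              min(x$features$mz), max(x$features$mz),
              min(x$features$rt), max(x$features$rt)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Subset a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param samples Sample index/names to keep (default all).
#' @param features Feature index/names to keep (default all).
#' @return A `feature_matrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(fm, samples = NULL, features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  ints <- fm$intensities
  if (!is.null(samples)) ints <- ints[samples, , drop = FALSE]
  feat <- fm$features
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, feat$name)
    ints <- ints[, features, drop = FALSE]
    feat <- feat[features, , drop = FALSE]
  }
  out <- fm
  out$intensities <- ints
  out$features <- feat
  rownames(out$features) <- NULL
  out
}

#' Log2-transform intensities
#'
#' Applies `log2(x + offset)`; untargeted LC-MS intensities are modelled on
#' the log scale throughout.
#'
#' @param fm A `feature_matrix`.
#' @param offset Pseudocount added before the log (default 1).
#' @return A `feature_matrix` on the log2 scale.
#' @export
log2_transform <- function(fm, offset = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$intensities <- log2(fm$intensities + offset)
  fm
}

#' Write a feature matrix to TSV/CSV
#'
#' Rows are features with columns `name`, `mz`, `rt` followed by one
#' intensity column per sample. The separator is chosen from the file
#' extension (`.csv` -> comma, otherwise tab).
#'
#' @param fm A `feature_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- cbind(fm$features, as.data.frame(t(fm$intensities)))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV/CSV
#'
#' Expects the layout written by [write_matrix()]: feature rows with `mz`,
#' `rt`, an optional `name` column, and at least one sample column.
#' Missing intensity cells are treated as 0 (with a message giving the
#' count); malformed numeric cells and duplicate sample columns are errors
#' reported with their location.
#'
#' @param path Input file path.
#' @return A `feature_matrix`.
#' @export
read_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate sample columns: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("mz", "rt") %in% names(df))) {
    stop("matrix file must have 'mz' and 'rt' columns: ", path)
  }
  meta_cols <- intersect(c("name", "mz", "rt"), names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  if (length(sample_cols) == 0L) stop("no sample columns in ", path)
  ints <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_cols),
                 dimnames = list(NULL, sample_cols))
  for (j in seq_along(sample_cols)) {
    col <- df[[sample_cols[j]]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                   sample_cols[j], bad[1], col[bad[1]]))
    }
    ints[, j] <- val
  }
  n_missing <- sum(is.na(ints))
  if (n_missing > 0L) {
    message(n_missing, " missing intensity cells treated as 0")
    ints[is.na(ints)] <- 0
  }
  feature_matrix(t(ints), mz = as.numeric(df$mz), rt = as.numeric(df$rt),
                 name = if ("name" %in% names(df)) as.character(df$name) else NULL)
}

#' Read a sample-metadata table
#'
#' @param path TSV/CSV with at least `sample_id` and `breed` columns;
#'   `diet`, `age_months`, `weight_kg`, `sex` are optional.
#' @return Data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "breed") %in% names(df))) {
    stop("metadata must have 'sample_id' and 'breed' columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' Check matrix/metadata consistency
#'
#' Every matrix sample id must have exactly one metadata row.
#'
#' @param fm A `feature_matrix`.
#' @param metadata Data frame from [read_metadata()].
#' @return The metadata reordered to the matrix sample order.
#' @export
align_metadata <- function(fm, metadata) {
  ids <- rownames(fm$intensities)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss) > 0L) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  }
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}

#' Bin accurate-mass features
#'
#' Pools features into half-open m/z intervals `[k*width, (k+1)*width)`
#' anchored at zero, summing intensities per sample within each bin. The
#' bin label m/z is the interval lower edge; the intensity-weighted mean of
#' the member m/z values (and RT) is kept alongside (`mz_center`,
#' `rt_center`) so accurate masses remain retrievable from the binned view.
#' Total intensity per sample is conserved. Binning a binned matrix is a
#' no-op (all features already sit on bin lower edges).
#'
#' @param fm A `feature_matrix`.
#' @param width Bin width in amu (default 0.01).
#' @return A `feature_matrix` of bins, ordered by m/z.
#' @export
bin_mz <- function(fm, width = 0.01) {
  stopifnot(inherits(fm, "feature_matrix"), width > 0)
  # tiny epsilon keeps values sitting exactly on a lower edge (e.g. an
  # already-binned matrix) in their own bin despite FP division error
  k <- floor(fm$features$mz / width + 1e-7)
  groups <- split(seq_along(k), k)
  n_bins <- length(groups)
  ints <- matrix(0, nrow = nrow(fm$intensities), ncol = n_bins,
                 dimnames = list(rownames(fm$intensities), NULL))
  mz_edge <- numeric(n_bins); mz_center <- numeric(n_bins)
  rt_center <- numeric(n_bins)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    ints[, g] <- rowSums(fm$intensities[, idx, drop = FALSE])
    w <- colSums(fm$intensities[, idx, drop = FALSE])
    if (sum(w) <= 0) w <- rep(1, length(idx))
    mz_edge[g] <- as.numeric(names(groups)[g]) * width
    mz_center[g] <- sum(fm$features$mz[idx] * w) / sum(w)
    rt_center[g] <- sum(fm$features$rt[idx] * w) / sum(w)
  }
  ord <- order(mz_edge)
  out <- feature_matrix(ints[, ord, drop = FALSE], mz = mz_edge[ord],
                        rt = rt_center[ord],
                        name = feature_name(mz_center[ord], rt_center[ord]))
  out$features$mz_center <- mz_center[ord]
  out$features$rt_center <- rt_center[ord]
  out
}
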