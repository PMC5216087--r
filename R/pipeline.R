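# End-to-end workflow: simulate (or load) -> bin -> meta-class model ->
# confounder filter -> pairwise grid -> unique signals -> annotation,
# with a machine-readable manifest linking every output to the thresholds
# used.

#' Assemble a run configuration
#'
#' Collects every tunable constant of the workflow with its default:
#' 0.01 amu bins; 100 bootstraps with 2/3-1/3 splits and 1000 trees;
#' adequacy at margin > 0.2 with AUC and/or ACC > 0.8; RFIS presets 0.003
#' (meta-class explanatory signals), 0.002 (pairwise discovery) and a
#' filter schedule descending through 3e-4; |r| > 0.8 correlation
#' clustering; 5 ppm annotation window. The configuration round-trips
#' through JSON unchanged.
#'
#' @param seed Master seed; per-stage seeds are derived as
#'   `(seed * 101 + stage_index) mod (2^31 - 1)`.
#' @param synthetic List of overrides passed to [synthetic_config()]
#'   (ignored when `matrix_path` is given).
#' @param matrix_path,metadata_path Optional paths to an existing feature
#'   matrix and metadata instead of simulating.
#' @param bin_width m/z bin width in amu.
#' @param log_offset Pseudocount for the log2 transform.
#' @param n_bootstraps,ntree,train_fraction Bootstrap scheme settings.
#' @param rfis_explanatory RFIS threshold for meta-class explanatory
#'   signals.
#' @param rfis_discover RFIS threshold for pairwise discovery.
#' @param q_max FDR threshold for explanatory signals.
#' @param p_max p-value threshold for discovery.
#' @param filter_schedule Descending RFIS cutoffs for the confounder
#'   filter; `NULL` disables filtering.
#' @param corr_threshold Correlation threshold for clusters and filter
#'   expansion.
#' @param min_adequate Adequate-comparison floor for pursuing a breed.
#' @param ppm_window Annotation window (ppm).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       synthetic = list(),
                       matrix_path = NULL, metadata_path = NULL,
                       bin_width = 0.01, log_offset = 1,
                       n_bootstraps = 100L, ntree = 1000L,
                       train_fraction = 2 / 3,
                       rfis_explanatory = 0.003, rfis_discover = 0.002,
                       q_max = 0.05, p_max = 0.05,
                       filter_schedule = cutoff_schedule(),
                       corr_threshold = 0.8, min_adequate = 6L,
                       ppm_window = 5) {
  filter_schedule <- as.numeric(unlist(filter_schedule))
  cfg <- list(seed = as.integer(seed), synthetic = synthetic,
              matrix_path = matrix_path, metadata_path = metadata_path,
              bin_width = bin_width, log_offset = log_offset,
              n_bootstraps = as.integer(n_bootstraps),
              ntree = as.integer(ntree), train_fraction = train_fraction,
              rfis_explanatory = rfis_explanatory,
              rfis_discover = rfis_discover, q_max = q_max, p_max = p_max,
              filter_schedule = filter_schedule,
              corr_threshold = corr_threshold,
              min_adequate = as.integer(min_adequate),
              ppm_window = ppm_window)
  thr <- unlist(cfg[c("bin_width", "rfis_explanatory", "rfis_discover",
                      "q_max", "p_max", "corr_threshold", "ppm_window")])
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 101 + k) %% (.Machine$integer.max - 1))
}

#' Run the full breed-lipidomics workflow
#'
#' Executes simulate (or load) -> bin -> meta-class model -> confounder
#' filter -> pairwise grid -> unique-signal discovery -> annotation,
#' writing every stage output plus a manifest (`manifest.json`) that
#' records, per stage, the files produced, their MD5 checksums and the
#' thresholds in force. Any stage failure aborts with the stage name.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @param formula_table Candidate compositions for annotation; default the
#'   bundled lipid table.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir,
                         formula_table = lipid_formula_table()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), stages = list())
  scheme_of <- function(k) bootstrap_scheme(
    n_bootstraps = cfg$n_bootstraps, train_fraction = cfg$train_fraction,
    ntree = cfg$ntree, seed = stage_seed(cfg$seed, k))
  note <- function(stage, files, params = list()) {
    paths <- file.path(out_dir, files)
    manifest$stages[[stage]] <<- list(
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(paths)), files)),
      params = params)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## 1. simulate or load
  ## (stage expressions are promises evaluated in this function's frame,
  ## so plain assignments persist across stages)
  truth <- NULL
  run_stage("input", {
    if (!is.null(cfg$matrix_path)) {
      fm <- read_matrix(cfg$matrix_path)
      metadata <- read_metadata(cfg$metadata_path)
      write_matrix(fm, file.path(out_dir, "matrix.tsv"))
      utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      syn <- do.call(synthetic_config,
                     c(cfg$synthetic, list(seed = stage_seed(cfg$seed, 1))))
      sim <- generate_lipidome(syn)
      write_simulation(sim, out_dir)
      fm <- sim$matrix; metadata <- sim$metadata; truth <- sim$truth
    }
    metadata <- align_metadata(fm, metadata)
  })
  note("input", c("matrix.tsv", "metadata.tsv"),
       list(seed = stage_seed(cfg$seed, 1)))

  ## 2. bin + log transform
  run_stage("bin", {
    binned <- bin_mz(fm, cfg$bin_width)
    lg <- log2_transform(binned, cfg$log_offset)
    write_matrix(binned, file.path(out_dir, "binned.tsv"))
  })
  note("bin", "binned.tsv", list(bin_width = cfg$bin_width))

  ## 3. meta-class model (group 1 vs group 2, mixed breed omitted)
  run_stage("metaclass", {
    g1 <- if (!is.null(truth)) truth$group1_breeds else
      utils::head(sort(unique(metadata$breed)), 3)
    mixed <- if (!is.null(truth)) truth$mixed_breed else character(0)
    mlab <- ifelse(metadata$breed %in% g1, "group1", "group2")
    mlab[metadata$breed %in% mixed] <- NA
    keep <- !is.na(mlab)
    mrep <- rf_bootstrap_classify(
      subset_matrix(lg, samples = which(keep)), mlab[keep], scheme_of(3),
      comparison = "metaclass-1")
    mlda <- pc_lda(subset_matrix(lg, samples = which(keep)), mlab[keep])
    jsonlite::write_json(
      list(comparison = mrep$comparison, margin = mrep$margin,
           auc = mrep$auc, acc = mrep$acc, adequate = mrep$adequate,
           tw = mlda$tw, pcs_retained = mlda$pcs_retained),
      file.path(out_dir, "metaclass_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    
  })
  note("metaclass", "metaclass_report.json")

  ## 4. meta-class feature ranking
  run_stage("rank", {
    keep <- !is.na(mlab)
    ranked <- rank_features(subset_matrix(lg, samples = which(keep)),
                             mlab[keep], scheme_of(4))
    utils::write.table(ranked, file.path(out_dir, "ranked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("rank", "ranked.tsv",
       list(rfis_explanatory = cfg$rfis_explanatory, q_max = cfg$q_max))

  ## 5. confounder filter
  run_stage("filter", {
    if (length(cfg$filter_schedule) == 0L) {
      filtered <- lg
      flt_report <- list(skipped = TRUE)
    } else {
      flt <- filter_confounder(lg, mlab, ranked,
                               schedule = cfg$filter_schedule,
                               corr_threshold = cfg$corr_threshold,
                               scheme = scheme_of(5))
      filtered <- flt$matrix
      flt_report <- flt$report
      flt_report$removed_features <- as.list(flt_report$removed_features)
    }
    jsonlite::write_json(unclass(flt_report),
                         file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    write_matrix(filtered, file.path(out_dir, "filtered.tsv"))
  })
  note("filter", c("filtered.tsv", "filter_report.json"),
       list(corr_threshold = cfg$corr_threshold,
            schedule = cfg$filter_schedule))

  ## 6. pairwise grid
  run_stage("grid", {
    grid <- pairwise_grid(filtered, metadata$breed, scheme_of(6))
    utils::write.table(grid_table(grid), file.path(out_dir, "grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("grid", "grid.tsv")

  ## 7. unique-signal discovery
  run_stage("discover", {
    uniq <- unique_signals(grid, filtered, metadata$breed, scheme_of(7),
                            min_adequate = cfg$min_adequate,
                            rfis_min = cfg$rfis_discover,
                            p_max = cfg$p_max)
    utils::write.table(uniq, file.path(out_dir, "unique_signals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("discover", "unique_signals.tsv",
       list(min_adequate = cfg$min_adequate,
            rfis_min = cfg$rfis_discover, p_max = cfg$p_max))

  ## 8. annotation of discovered signals (accurate m/z from the un-binned
  ## view of each bin)
  run_stage("annotate", {
    feats <- filtered$features
    mzcol <- if ("mz_center" %in% names(feats)) "mz_center" else "mz"
    hits <- feats[feats$name %in% uniq$feature, c("name", mzcol)]
    names(hits) <- c("name", "mz")
    ann <- annotate_features(hits, formula_table, cfg$ppm_window)
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("annotate", "annotations.tsv", list(ppm_window = cfg$ppm_window))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Bundled lipid composition table
#'
#' Small offline table of lipid elemental compositions and adduct rules
#' (phosphatidylcholines, sphingomyelins, sterol lipids, long-chain
#' hydrocarbons and related species) used as the default annotation
#' candidate list.
#'
#' @return Data frame with columns `name`, `formula`, `rule`.
#' @export
lipid_formula_table <- function() {
  path <- system.file("extdata", "lipid_formulas.tsv", package = "lipidbreed",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
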