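# Synthetic untargeted-lipidomics generator with a ground-truth ledger.
#
# Emulates the statistical structure the downstream analysis assumes: a
# panel of breeds with 7-12 animals each, ~2500 accurate-mass features,
# correlated adduct/isotope satellite clusters driven by shared per-sample
# latent multipliers, a diet axis (chicken vs red meat) partially collinear
# with a breed meta-class, a second breed meta-class axis, and a handful of
# single-breed-unique features.

# Default canine panel: breed sizes and typical adult weights (kg).
.canine_panel <- data.frame(
  breed = c("Be", "Ch", "CS", "Da", "GR", "Gh", "GS", "LR", "Ma"),
  n = c(12L, 7L, 12L, 8L, 12L, 12L, 12L, 12L, 9L),
  weight = c(10, 2.5, 13, 9, 32, 30, 35, 32, 4),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic lipidome generator
#'
#' Defaults emulate a nine-breed fasted-plasma study: breed panel
#' Be(12), Ch(7), CS(12), Da(8), GR(12), Gh(12), GS(12), LR(12), Ma(9);
#' 2500 features per ionisation mode; a chicken/red-meat diet axis aligned
#' with the first breed meta-class (Ch, Da, Gh vs Be, CS, GR, GS, Ma) with
#' the LR breed mixed across both diets; a second meta-class axis (Ch, Da,
#' Ma, GR reduced vs the rest); and breed-unique features for Ch (5
#' decreased), GR (7 elevated) and Gh (1 decreased).
#'
#' @param breeds Named integer vector of samples per breed. `NULL` uses the
#'   default canine panel when `n_breeds = 9`, otherwise generic breeds
#'   `B1..Bk` with sizes drawn uniformly from `samples_per_breed`.
#' @param n_breeds Number of breed classes (used when `breeds` is `NULL`).
#' @param samples_per_breed Integer range (lo, hi) for per-breed sample
#'   counts when sizes are drawn; must lie within 7-12 to match the
#'   emulated recruitment design.
#' @param n_features Total number of features (default 2500).
#' @param n_cluster_bases Number of base metabolites that spawn correlated
#'   satellite features (adducts/isotopes).
#' @param max_satellites Maximum satellites per clustered base (1 to this).
#' @param diet_classes Two diet labels (default chicken, red_meat).
#' @param diet_chicken_prob Named per-breed probability of the first diet
#'   class; `NULL` derives 0.9 for group-1 breeds, 0.1 for the others and
#'   0.5 for the mixed breed.
#' @param group1_breeds Breeds forming the first meta-class (diet-aligned).
#' @param metaclass2_breeds Breeds carrying the second-axis effect.
#' @param mixed_breed The breed with mixed diet assignment (LR analogue).
#' @param n_diet_bases Base metabolites carrying the diet effect.
#' @param n_metaclass2_bases Base metabolites carrying the second-axis effect.
#' @param n_diet_pathways Number of covarying "pathway" families the diet
#'   bases are grouped into; members of a family (and their satellites)
#'   share a per-sample latent term, emulating biochemically related
#'   diet-derived lipids (triglyceride/phosphatidylcholine series) that
#'   cluster at |r| > 0.8 in real profiles.
#' @param n_metaclass2_pathways Pathway families for the second-axis
#'   features (sphingolipid/hydrocarbon series analogue).
#' @param pathway_latent_sd SD of the shared per-sample latent within a
#'   pathway family. Family members are distinct compounds, so their
#'   covariance beyond the shared dietary/meta-class driver is weaker than
#'   that of adduct/isotope satellites of one ion; the default equals
#'   `noise_sd`, letting the planted effect itself supply most of the
#'   within-family correlation.
#' @param unique_spec Named numeric vector: breed -> signed count of unique
#'   features (positive = elevated in that breed, negative = decreased).
#' @param effect_log2fc Planted effect size, log2 fold change (default 1).
#' @param noise_sd Residual SD on the log2 scale (default 0.5).
#' @param cluster_latent_sd SD of the shared per-sample latent term within a
#'   satellite cluster; the default 2.5 x `noise_sd` puts the expected
#'   within-cluster Pearson r at ~0.86.
#' @param baseline_log2_range Range of per-feature baseline log2 means
#'   (default 10-20, i.e. ~3 orders of magnitude of dynamic range).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(breeds = NULL,
                             n_breeds = 9L,
                             samples_per_breed = c(7L, 12L),
                             n_features = 2500L,
                             n_cluster_bases = 300L,
                             max_satellites = 3L,
                             diet_classes = c("chicken", "red_meat"),
                             diet_chicken_prob = NULL,
                             group1_breeds = NULL,
                             metaclass2_breeds = NULL,
                             mixed_breed = NULL,
                             n_diet_bases = 60L,
                             n_metaclass2_bases = 18L,
                             n_diet_pathways = 10L,
                             n_metaclass2_pathways = 5L,
                             pathway_latent_sd = noise_sd,
                             unique_spec = NULL,
                             effect_log2fc = 1,
                             noise_sd = 0.5,
                             cluster_latent_sd = 2.5 * noise_sd,
                             baseline_log2_range = c(10, 20),
                             seed = 1L) {
  stopifnot(length(diet_classes) == 2L, noise_sd >= 0, effect_log2fc >= 0,
            cluster_latent_sd >= 0, n_features >= 1)
  use_panel <- is.null(breeds) && n_breeds == 9L
  if (is.null(breeds)) {
    if (samples_per_breed[1] < 7L || samples_per_breed[2] > 12L ||
        samples_per_breed[1] > samples_per_breed[2]) {
      stop("samples_per_breed range must lie within 7-12")
    }
    if (use_panel) {
      breeds <- stats::setNames(.canine_panel$n, .canine_panel$breed)
    }  # else drawn in generate() under the config seed
  } else {
    if (is.null(names(breeds)) || any(breeds < 3L)) {
      stop("explicit breeds must be named and have >= 3 samples each")
    }
  }
  breed_names <- if (!is.null(breeds)) names(breeds) else
    sprintf("B%d", seq_len(n_breeds))
  if (is.null(group1_breeds)) {
    group1_breeds <- if (use_panel) c("Ch", "Da", "Gh") else
      utils::head(breed_names, min(3L, length(breed_names) - 1L))
  }
  if (is.null(mixed_breed)) {
    mixed_breed <- if (use_panel) "LR" else utils::tail(breed_names, 1L)
  }
  if (is.null(metaclass2_breeds)) {
    metaclass2_breeds <- if (use_panel) c("Ch", "Da", "Ma", "GR") else {
      others <- setdiff(breed_names, c(group1_breeds, mixed_breed))
      c(utils::head(group1_breeds, 2L), utils::head(others, 2L))
    }
  }
  if (is.null(unique_spec)) {
    unique_spec <- if (use_panel) c(Ch = -5, GR = 7, Gh = -1) else numeric(0)
  }
  stopifnot(all(group1_breeds %in% breed_names),
            all(metaclass2_breeds %in% breed_names),
            mixed_breed %in% breed_names,
            all(names(unique_spec) %in% breed_names))
  if (is.null(diet_chicken_prob)) {
    diet_chicken_prob <- stats::setNames(
      ifelse(breed_names %in% group1_breeds, 0.9, 0.1), breed_names)
    diet_chicken_prob[mixed_breed] <- 0.5
  }
  if (any(diet_chicken_prob < 0 | diet_chicken_prob > 1)) {
    stop("diet probabilities must be in [0, 1]")
  }
  # feasibility: clustered bases + their maximal satellites + planted
  # singleton uniques must fit into n_features
  n_unique <- sum(abs(unique_spec))
  if (n_cluster_bases * (1L + max_satellites) + n_unique > n_features) {
    stop("infeasible config: more planted/clustered features than n_features")
  }
  if (n_diet_bases + n_metaclass2_bases + n_unique > n_features) {
    stop("infeasible config: more planted features than n_features")
  }
  structure(list(
    breeds = breeds, n_breeds = length(breed_names),
    breed_names = breed_names,
    samples_per_breed = samples_per_breed, n_features = as.integer(n_features),
    n_cluster_bases = as.integer(n_cluster_bases),
    max_satellites = as.integer(max_satellites),
    diet_classes = diet_classes, diet_chicken_prob = diet_chicken_prob,
    group1_breeds = group1_breeds, metaclass2_breeds = metaclass2_breeds,
    mixed_breed = mixed_breed,
    n_diet_bases = as.integer(n_diet_bases),
    n_metaclass2_bases = as.integer(n_metaclass2_bases),
    n_diet_pathways = as.integer(n_diet_pathways),
    n_metaclass2_pathways = as.integer(n_metaclass2_pathways),
    pathway_latent_sd = pathway_latent_sd,
    unique_spec = unique_spec,
    effect_log2fc = effect_log2fc, noise_sd = noise_sd,
    cluster_latent_sd = cluster_latent_sd,
    baseline_log2_range = baseline_log2_range, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic lipidome study
#'
#' Builds a feature matrix (raw intensity scale), sample metadata and a
#' ground-truth ledger under the model
#' `log2 I = baseline(feature) + breed effect + diet effect + cluster latent + noise`.
#' Satellites of one base metabolite share a per-sample latent term so
#' within-cluster Pearson correlations exceed 0.8 in expectation; isotope
#' satellites sit +1.0033548 m/z above their parent with lower mean
#' intensity. One designated breed has mixed diet assignment; all others
#' are near-pure. Output is fully determined by `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"lipidome_sim"` with elements `matrix`
#'   (a [feature_matrix()], raw scale), `metadata` (data frame), `truth`
#'   (ground-truth ledger) and `config`.
#' @export
generate_lipidome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- samples ----
  if (is.null(cfg$breeds)) {
    sizes <- sample(seq(cfg$samples_per_breed[1], cfg$samples_per_breed[2]),
                    cfg$n_breeds, replace = TRUE)
    cfg$breeds <- stats::setNames(sizes, cfg$breed_names)
  }
  breed <- rep(names(cfg$breeds), times = cfg$breeds)
  n <- length(breed)
  sample_id <- unlist(lapply(names(cfg$breeds), function(b)
    sprintf("%s%02d", b, seq_len(cfg$breeds[[b]]))))
  p_chick <- cfg$diet_chicken_prob[breed]
  diet <- ifelse(stats::runif(n) < p_chick, cfg$diet_classes[1],
                 cfg$diet_classes[2])
  # guarantee the mixed breed really carries both diet classes
  mix_idx <- which(breed == cfg$mixed_breed)
  if (length(unique(diet[mix_idx])) == 1L) {
    diet[mix_idx[length(mix_idx)]] <-
      setdiff(cfg$diet_classes, diet[mix_idx[1]])[1]
  }

  ## ---- feature scaffold ----
  sat_counts <- sample(seq_len(cfg$max_satellites), cfg$n_cluster_bases,
                       replace = TRUE)
  n_satellites <- sum(sat_counts)
  n_bases <- cfg$n_features - n_satellites
  if (n_bases < cfg$n_cluster_bases) stop("infeasible config: too many satellites")

  base_mz <- round(stats::runif(n_bases, 200, 1000), 4)
  base_rt <- round(stats::runif(n_bases, 60, 600), 1)
  baseline <- stats::runif(n_bases, cfg$baseline_log2_range[1],
                           cfg$baseline_log2_range[2])

  # feature table: bases first, then satellites appended per clustered base
  mz <- base_mz; rt <- base_rt; base_of <- seq_len(n_bases)
  feat_baseline <- baseline
  sat_kind <- rep(NA_character_, n_bases)
  for (b in seq_len(cfg$n_cluster_bases)) {
    for (s in seq_len(sat_counts[b])) {
      kind <- sample(c("isotope", "adduct"), 1L)
      off <- if (kind == "isotope") 1.00335483507 else
        sample(c(17.0265491, 21.9819425), 1L)
      drop <- if (kind == "isotope") 1.5 else stats::runif(1, 0.5, 2)
      mz <- c(mz, base_mz[b] + off)
      rt <- c(rt, base_rt[b])
      base_of <- c(base_of, b)
      feat_baseline <- c(feat_baseline, baseline[b] - drop)
      sat_kind <- c(sat_kind, kind)
    }
  }
  p <- length(mz)
  stopifnot(p == cfg$n_features)
  fname <- make.unique(feature_name(mz, rt), sep = "_")

  ## ---- planted effect assignment (on base metabolites) ----
  cluster_base_ids <- seq_len(cfg$n_cluster_bases)
  singleton_ids <- setdiff(seq_len(n_bases), cluster_base_ids)
  n_unique <- sum(abs(cfg$unique_spec))
  pool_clustered <- sample(cluster_base_ids)
  pool_singleton <- sample(singleton_ids)
  take <- function(pool, k) list(got = utils::head(pool, k),
                                 rest = utils::tail(pool, length(pool) - k))
  # diet and meta-class-2 effects: ~2/3 on clustered bases to exercise
  # correlated-feature expansion, rest on singletons
  k_diet_cl <- min(round(cfg$n_diet_bases * 2 / 3), length(pool_clustered))
  tk <- take(pool_clustered, k_diet_cl); diet_bases <- tk$got
  pool_clustered <- tk$rest
  tk <- take(pool_singleton, cfg$n_diet_bases - k_diet_cl)
  diet_bases <- c(diet_bases, tk$got); pool_singleton <- tk$rest
  k_m2_cl <- min(round(cfg$n_metaclass2_bases * 2 / 3), length(pool_clustered))
  tk <- take(pool_clustered, k_m2_cl); m2_bases <- tk$got
  pool_clustered <- tk$rest
  tk <- take(pool_singleton, cfg$n_metaclass2_bases - k_m2_cl)
  m2_bases <- c(m2_bases, tk$got); pool_singleton <- tk$rest
  if (length(diet_bases) < cfg$n_diet_bases ||
      length(m2_bases) < cfg$n_metaclass2_bases ||
      length(pool_singleton) < n_unique) {
    stop("infeasible config: not enough features for the planted effects")
  }
  unique_bases <- list()
  for (b in names(cfg$unique_spec)) {
    k <- abs(cfg$unique_spec[[b]])
    tk <- take(pool_singleton, k)
    unique_bases[[b]] <- tk$got; pool_singleton <- tk$rest
  }

  ## ---- intensity model ----
  eff <- matrix(0, n, n_bases)  # per-sample effect on each base metabolite
  is_red <- diet == cfg$diet_classes[2]
  eff[, diet_bases] <- eff[, diet_bases] +
    outer(as.numeric(is_red), rep(cfg$effect_log2fc, length(diet_bases)))
  in_m2 <- breed %in% cfg$metaclass2_breeds
  eff[, m2_bases] <- eff[, m2_bases] -
    outer(as.numeric(in_m2), rep(cfg$effect_log2fc, length(m2_bases)))
  for (b in names(unique_bases)) {
    sgn <- sign(cfg$unique_spec[[b]])
    eff[, unique_bases[[b]]] <- eff[, unique_bases[[b]]] +
      outer(as.numeric(breed == b), rep(sgn * cfg$effect_log2fc,
                                        length(unique_bases[[b]])))
  }
  # latent grouping: by default each clustered base has its own shared
  # latent (adduct/isotope cluster); diet and second-axis bases are instead
  # grouped into pathway families whose members (and satellites) covary
  latent_group <- rep(NA_character_, n_bases)
  latent_group[cluster_base_ids] <- sprintf("cl%d", cluster_base_ids)
  latent_group[diet_bases] <- sprintf(
    "diet%d", rep(seq_len(max(1L, cfg$n_diet_pathways)),
                  length.out = length(diet_bases)))
  latent_group[m2_bases] <- sprintf(
    "m2%d", rep(seq_len(max(1L, cfg$n_metaclass2_pathways)),
                length.out = length(m2_bases)))
  groups <- unique(latent_group[!is.na(latent_group)])
  group_sd <- ifelse(grepl("^cl", groups), cfg$cluster_latent_sd,
                     cfg$pathway_latent_sd)
  z <- matrix(stats::rnorm(n * length(groups)), n, length(groups),
              dimnames = list(NULL, groups))
  z <- sweep(z, 2, group_sd, `*`)
  latent <- matrix(0, n, n_bases)
  has_lat <- !is.na(latent_group)
  latent[, has_lat] <- z[, latent_group[has_lat], drop = FALSE]

  shared <- eff[, base_of, drop = FALSE] + latent[, base_of, drop = FALSE]
  log2I <- matrix(rep(feat_baseline, each = n), n, p) + shared +
    matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  ints <- 2^log2I
  rownames(ints) <- sample_id
  fm <- feature_matrix(ints, mz = mz, rt = rt, name = fname)

  ## ---- metadata ----
  panel_w <- stats::setNames(.canine_panel$weight, .canine_panel$breed)
  w_mean <- ifelse(breed %in% names(panel_w), panel_w[breed], 20)
  metadata <- data.frame(
    sample_id = sample_id, breed = breed, diet = diet,
    age_months = sample(12:120, n, replace = TRUE),
    weight_kg = round(pmax(1, w_mean + stats::rnorm(n, 0, w_mean * 0.1)), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  ## ---- ground truth ----
  feat_of_base <- function(ids) fname[base_of %in% ids]   # base + satellites
  sat_idx <- which(seq_len(p) > n_bases)
  cluster_members <- lapply(cluster_base_ids, function(b) {
    sats <- sat_idx[base_of[sat_idx] == b]
    list(base = fname[b], satellites = fname[sats], r_sign = 1)
  })
  names(cluster_members) <- fname[cluster_base_ids]
  uniq <- lapply(names(unique_bases), function(b) {
    data.frame(feature = fname[unique_bases[[b]]],
               direction = if (cfg$unique_spec[[b]] > 0) "elevated" else "decreased",
               stringsAsFactors = FALSE)
  })
  names(uniq) <- names(unique_bases)
  truth <- list(
    diet_features = feat_of_base(diet_bases),
    metaclass1_features = feat_of_base(diet_bases),
    metaclass2_features = feat_of_base(m2_bases),
    unique_features = uniq,
    cluster_members = cluster_members,
    diet_pathways = split(fname[base_of %in% diet_bases],
                          latent_group[base_of[base_of %in% diet_bases]]),
    group1_breeds = cfg$group1_breeds,
    metaclass2_breeds = cfg$metaclass2_breeds,
    mixed_breed = cfg$mixed_breed)

  structure(list(matrix = fm, metadata = metadata, truth = truth,
                 config = cfg),
            class = "lipidome_sim")
}

#' @export
print.lipidome_sim <- function(x, ...) {
  cat(sprintf("lipidome_sim: %d samples, %d breeds, %d features (seed %d)\n",
              nrow(x$matrix$intensities), length(unique(x$metadata$breed)),
              ncol(x$matrix$intensities), x$config$seed))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes `matrix.tsv` (features x samples), `metadata.tsv` and
#' `truth.json` into `dir`.
#'
#' @param sim A `lipidome_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lipidome_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$matrix, file.path(dir, "matrix.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
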