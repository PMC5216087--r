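test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 9)
  a <- generate_lipidome(cfg)
  b <- generate_lipidome(cfg)
  expect_identical(a$matrix$intensities, b$matrix$intensities)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("default configuration matches the emulated study design", {
  cfg <- synthetic_config()
  expect_equal(length(cfg$breeds), 9L)
  expect_true(all(cfg$breeds >= 7 & cfg$breeds <= 12))
  expect_equal(cfg$n_features, 2500L)
  expect_equal(sort(cfg$group1_breeds), c("Ch", "Da", "Gh"))
  expect_equal(cfg$mixed_breed, "LR")
  sim <- generate_lipidome(synthetic_config(seed = 7))
  expect_equal(dim(sim$matrix), c(sum(cfg$breeds), 2500L))
  expect_equal(nrow(sim$metadata), sum(cfg$breeds))
})

test_that("diet assignment is mixed for the designated breed, near-pure otherwise", {
  sim <- generate_lipidome(synthetic_config(seed = 7))
  md <- sim$metadata
  mixed <- table(md$diet[md$breed == sim$truth$mixed_breed])
  expect_equal(length(mixed), 2L)   # both diet classes present
  # pure breeds: the configured majority class dominates
  for (b in setdiff(unique(md$breed), sim$truth$mixed_breed)) {
    expected <- if (b %in% sim$truth$group1_breeds) "chicken" else "red_meat"
    expect_gt(mean(md$diet[md$breed == b] == expected), 0.5)
  }
})

test_that("within-cluster correlations exceed the adduct/isotope threshold", {
  sim <- generate_lipidome(synthetic_config(seed = 7))
  lg <- log2_transform(sim$matrix)
  meds <- vapply(sim$truth$cluster_members, function(cl) {
    mem <- c(cl$base, cl$satellites)
    r <- stats::cor(lg$intensities[, mem, drop = FALSE])
    stats::median(abs(r[upper.tri(r)]))
  }, numeric(1))
  expect_gt(stats::median(meds), 0.8)
})

test_that("satellites sit at isotope/adduct offsets with lower intensity", {
  sim <- generate_lipidome(small_config(seed = 2))
  feats <- sim$matrix$features
  offsets <- c(1.00335483507, 17.0265491, 21.9819425)
  for (cl in sim$truth$cluster_members) {
    base_mz <- feats$mz[feats$name == cl$base]
    for (s in cl$satellites) {
      d <- feats$mz[feats$name == s] - base_mz
      expect_true(any(abs(d - offsets) < 1e-6))
      expect_lt(mean(log2(sim$matrix$intensities[, s])),
                mean(log2(sim$matrix$intensities[, cl$base])))
    }
  }
})

test_that("planted unique features shift in the declared direction", {
  sim <- generate_lipidome(small_config(seed = 3))
  lg <- log2_transform(sim$matrix)
  md <- sim$metadata
  for (b in names(sim$truth$unique_features)) {
    uf <- sim$truth$unique_features[[b]]
    for (i in seq_len(nrow(uf))) {
      din <- mean(lg$intensities[md$breed == b, uf$feature[i]])
      dout <- mean(lg$intensities[md$breed != b, uf$feature[i]])
      if (uf$direction[i] == "elevated") expect_gt(din, dout)
      else expect_lt(din, dout)
    }
  }
})

test_that("a zero-effect configuration carries no class signal downstream", {
  # single small datasets have a null-margin spread of ~0.13, so average
  # the pairwise score over several generated datasets
  scores <- vapply(1:4, function(gs) {
    sim <- generate_lipidome(small_config(seed = gs, effect_log2fc = 0))
    lg <- log2_transform(sim$matrix)
    md <- sim$metadata
    idx <- which(md$breed %in% c("A", "B"))
    r <- rf_bootstrap_classify(subset_matrix(lg, samples = idx),
                               md$breed[idx],
                               fast_scheme(seed = gs, n_bootstraps = 25))
    c(r$margin, r$auc)
  }, numeric(2))
  expect_lt(abs(mean(scores[1, ])), 0.15)
  expect_gt(mean(scores[2, ]), 0.3)
  expect_lt(mean(scores[2, ]), 0.7)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_features = 50, n_cluster_bases = 40),
               "infeasible")
  expect_error(synthetic_config(n_features = 100, n_cluster_bases = 5,
                                n_diet_bases = 90, n_metaclass2_bases = 30),
               "infeasible")
  expect_error(synthetic_config(samples_per_breed = c(3, 5)), "7-12")
  expect_error(synthetic_config(breeds = c(A = 2, B = 8)), ">= 3")
})

test_that("ground truth is internally consistent", {
  sim <- generate_lipidome(small_config(seed = 6))
  tr <- sim$truth
  # unique feature sets pairwise disjoint across breeds
  all_u <- unlist(lapply(tr$unique_features, `[[`, "feature"))
  expect_equal(anyDuplicated(all_u), 0L)
  # every satellite belongs to exactly one base metabolite
  sats <- unlist(lapply(tr$cluster_members, `[[`, "satellites"))
  expect_equal(anyDuplicated(sats), 0L)
  # all truth features exist in the matrix
  expect_true(all(c(all_u, sats, tr$diet_features, tr$metaclass2_features)
                  %in% sim$matrix$features$name))
})

test_that("simulations round-trip to disk", {
  dir <- withr::local_tempdir()
  sim <- generate_lipidome(small_config(seed = 8, n_features = 40,
                                        n_diet_bases = 5,
                                        n_metaclass2_bases = 4))
  write_simulation(sim, dir)
  back <- read_matrix(file.path(dir, "matrix.tsv"))
  expect_equal(back$intensities, sim$matrix$intensities, tolerance = 1e-6)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$breed, sim$metadata$breed)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$diet_features, sim$truth$diet_features)
})
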