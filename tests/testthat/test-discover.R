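# All-pairs breed modelling and breed-unique signal discovery.

# hand-built discovery fixture: four breeds, each with its own block of
# strongly elevated features, one signal shared by breeds A and B, and no
# other structure - every pair is separable and ground truth is explicit
discover_fixture <- function(seed = 71, n_per = 8, block = 20) {
  set.seed(seed)
  breeds <- rep(c("A", "B", "C", "D"), each = n_per)
  n <- length(breeds)
  p_noise <- 120
  x <- matrix(rnorm(n * p_noise, 14, 0.5), n, p_noise)
  blocks <- list()
  for (b in c("A", "B", "C", "D")) {
    blk <- matrix(rnorm(n * block, 14, 0.5), n, block)
    blk[breeds == b, ] <- blk[breeds == b, ] + 3
    colnames(blk) <- sprintf("%s_unique_%02d", b, seq_len(block))
    blocks[[b]] <- blk
  }
  shared <- matrix(rnorm(n, 14, 0.5), n, 1)
  shared[breeds %in% c("A", "B"), ] <- shared[breeds %in% c("A", "B"), ] + 3
  colnames(shared) <- "AB_shared"
  colnames(x) <- sprintf("noise_%03d", seq_len(p_noise))
  xa <- cbind(x, do.call(cbind, blocks), shared)
  fm <- feature_matrix(2^xa, mz = seq(200.12, by = 1.01,
                                      length.out = ncol(xa)),
                       rt = rep(300, ncol(xa)), name = colnames(xa))
  list(fm = log2_transform(fm, offset = 0), breeds = breeds)
}

test_that("the pairwise grid enumerates all unordered pairs", {
  fx <- discover_fixture()
  grid <- pairwise_grid(fx$fm, fx$breeds, fast_scheme(seed = 1))
  expect_equal(length(grid$reports), 6L)
  expect_true(all(vapply(grid$reports, `[[`, logical(1), "adequate")))
  expect_equal(unname(grid$adequate_count), rep(3L, 4))
  gt <- grid_table(grid)
  expect_equal(nrow(gt), 6L)
  expect_true(all(gt$margin > 0.2))
})

test_that("permuted breed labels give no adequate comparisons", {
  fx <- discover_fixture(seed = 72)
  set.seed(5)
  perm <- sample(fx$breeds)
  grid <- pairwise_grid(fx$fm, perm, fast_scheme(seed = 2))
  expect_equal(sum(vapply(grid$reports, `[[`, logical(1), "adequate")), 0L)
  expect_equal(unname(grid$adequate_count), rep(0L, 4))
})

test_that("unique signals are recovered per breed with direction", {
  fx <- discover_fixture(seed = 73)
  sch <- fast_scheme(seed = 3)
  grid <- pairwise_grid(fx$fm, fx$breeds, sch)
  us <- unique_signals(grid, fx$fm, fx$breeds, sch, min_adequate = 3L)
  # every planted block feature is recovered for its breed, elevated
  for (b in c("A", "B", "C", "D")) {
    got <- us$feature[us$breed == b]
    expect_setequal(got, sprintf("%s_unique_%02d", b, 1:20))
    expect_true(all(us$direction[us$breed == b] == "elevated"))
    expect_true(all(us$support[us$breed == b] == 3L))
  }
  # the shared A/B signal is part of a multi-breed series, never unique
  expect_false("AB_shared" %in% us$feature)
  # no feature is reported for two breeds
  expect_equal(anyDuplicated(us$feature), 0L)
  expect_true(all(us$rfis_min > 0.002 & us$p_max < 0.05))
})

test_that("breeds below the adequacy floor are not pursued", {
  fx <- discover_fixture(seed = 74)
  sch <- fast_scheme(seed = 4)
  grid <- pairwise_grid(fx$fm, fx$breeds, sch)
  us <- unique_signals(grid, fx$fm, fx$breeds, sch, min_adequate = 4L)
  expect_equal(nrow(us), 0L)
})

test_that("tightening thresholds never adds signals", {
  fx <- discover_fixture(seed = 75)
  sch <- fast_scheme(seed = 5)
  grid <- pairwise_grid(fx$fm, fx$breeds, sch)
  pairs <- lapply(names(grid$reports),
                  function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  cache <- pair_rankings(fx$fm, fx$breeds, pairs, sch)
  base <- unique_signals(grid, fx$fm, fx$breeds, sch, min_adequate = 3L,
                         rankings = cache)
  tighter_rfis <- unique_signals(grid, fx$fm, fx$breeds, sch,
                                 min_adequate = 3L, rfis_min = 0.02,
                                 rankings = cache)
  tighter_p <- unique_signals(grid, fx$fm, fx$breeds, sch,
                              min_adequate = 3L, p_max = 1e-6,
                              rankings = cache)
  key <- function(u) paste(u$breed, u$feature)
  expect_true(all(key(tighter_rfis) %in% key(base)))
  expect_true(all(key(tighter_p) %in% key(base)))
})

test_that("grids are deterministic under a fixed scheme seed", {
  fx <- discover_fixture(seed = 76)
  g1 <- pairwise_grid(fx$fm, fx$breeds, fast_scheme(seed = 6))
  g2 <- pairwise_grid(fx$fm, fx$breeds, fast_scheme(seed = 6))
  expect_identical(grid_table(g1), grid_table(g2))
})
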