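# Independent mass oracle: per-atom summation over a separately sourced
# constants table (NIST/CODATA values typed independently of the package's
# IUPAC table), used to cross-check the package's adduct algebra.
oracle_masses <- c(
  C = 12.000000000, H = 1.007825032, N = 14.003074005, O = 15.994914620,
  P = 30.973761998, S = 31.972071174, Na = 22.989769282
)
oracle_electron <- 0.000548579909
oracle_c13_minus_c12 <- 13.003354835 - 12

oracle_adduct_mz <- function(counts, delta = c(H = 1), charge = 1, n_c13 = 0) {
  for (el in names(delta)) {
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + delta[[el]]
  }
  m <- 0
  for (el in names(counts)) m <- m + counts[[el]] * oracle_masses[[el]]
  (m + n_c13 * oracle_c13_minus_c12 - charge * oracle_electron) / abs(charge)
}

# random elemental composition in the lipid-relevant range
random_formula_counts <- function() {
  c(C = sample(0:60, 1), H = sample(0:120, 1), N = sample(0:3, 1),
    O = sample(0:10, 1), P = sample(0:2, 1), S = sample(0:2, 1))
}

counts_to_string <- function(counts) {
  counts <- counts[counts > 0]
  paste0(mapply(function(el, n) paste0(el, n), names(counts), counts),
         collapse = "")
}

# dense generalized-eigenproblem oracle: eigenvalues of Sw^-1 Sb computed
# directly (scatter sums), independent of the whitening route used in
# pc_lda
lda_eigen_oracle <- function(x, y, npc) {
  pc <- prcomp(x, center = TRUE)
  S <- pc$x[, seq_len(npc), drop = FALSE]
  y <- as.factor(y)
  mu <- colMeans(S)
  Sw <- matrix(0, npc, npc); Sb <- matrix(0, npc, npc)
  for (cl in levels(y)) {
    Sc <- S[y == cl, , drop = FALSE]
    mc <- colMeans(Sc)
    Sw <- Sw + crossprod(sweep(Sc, 2, mc))
    Sb <- Sb + nrow(Sc) * tcrossprod(mc - mu)
  }
  ev <- eigen(solve(Sw) %*% Sb, only.values = TRUE)$values
  sort(Re(ev), decreasing = TRUE)
}

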