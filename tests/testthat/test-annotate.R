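test_that("formula parsing handles implicit counts, subscripts and errors", {
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C39H78NO8P")),
               c(C = 39L, H = 78L, N = 1L, O = 8L, P = 1L))
  # typeset table notation with underscore subscripts
  expect_equal(unclass(parse_formula("C_39_H_78_NO_8_P")),
               unclass(parse_formula("C39H78NO8P")))
  expect_error(parse_formula("C39X2"), "X")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("39C"), "malformed")
})

test_that("monoisotopic masses match hand-summed constants", {
  expect_equal(monoisotopic_mass("H"), 1.00782503, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("H2O"), 18.0105646, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C39H78NO8P"), 719.5465051, tolerance = 1e-6)
})

# Theoretical m/z values printed for the protonated phosphatidylcholines
# and the ammoniated hydrocarbon/fatty-acid series, with the first 13C
# isotopologue of PC(33:0).
golden_ions <- data.frame(
  formula = c("C39H78NO8P", "C41H82NO8P", "C41H82NO8P", "C43H86NO8P",
              "C18H34", "C18H36", "C17H34O2", "C15H30O"),
  rule = c("[M+H]1+", "[M+H]1+", "[M+H]1+ 13C", "[M+H]1+",
           "[M+NH4]1+", "[M+NH4]1+", "[M+NH4]1+", "[M+NH4]1+"),
  mz = c(720.553784, 748.585084, 749.588438, 776.616384,
         268.299877, 270.315527, 288.289706, 244.263491),
  stringsAsFactors = FALSE
)

test_that("published theoretical m/z values are reproduced within 1e-4", {
  rules <- adduct_rules()
  for (i in seq_len(nrow(golden_ions))) {
    got <- adduct_mz(golden_ions$formula[i], rules[[golden_ions$rule[i]]])
    expect_equal(got, golden_ions$mz[i], tolerance = 1e-4 / golden_ions$mz[i],
                 label = sprintf("%s %s", golden_ions$formula[i],
                                 golden_ions$rule[i]))
    expect_lt(abs(got - golden_ions$mz[i]), 1e-4)
  }
})

test_that("adduct algebra agrees with an independent per-atom oracle", {
  rules <- adduct_rules()
  set.seed(42)
  n_checked <- 0
  for (i in 1:200) {
    counts <- random_formula_counts()
    if (sum(counts) == 0) next
    f <- counts_to_string(counts)
    expect_equal(adduct_mz(f, rules[["[M+H]1+"]]),
                 oracle_adduct_mz(counts[counts > 0]),
                 tolerance = 1e-6)
    expect_equal(adduct_mz(f, rules[["[M+NH4]1+"]]),
                 oracle_adduct_mz(counts[counts > 0], c(N = 1, H = 4)),
                 tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("isotopologue spacing and adduct differences are exact", {
  rules <- adduct_rules()
  set.seed(7)
  for (i in 1:50) {
    counts <- random_formula_counts()
    counts["C"] <- max(counts[["C"]], 1L)  # need a carbon for 13C
    f <- counts_to_string(counts)
    d13 <- adduct_mz(f, rules[["[M+H]1+ 13C"]]) - adduct_mz(f, rules[["[M+H]1+"]])
    expect_equal(d13, 1.0033548, tolerance = 1e-6)
    dnh4 <- adduct_mz(f, rules[["[M+NH4]1+"]]) - adduct_mz(f, rules[["[M+H]1+"]])
    expect_lt(abs(dnh4 - 17.026549), 1e-5)
  }
})

test_that("adduct rules validate composition and charge", {
  expect_error(adduct_rule("bad", c(H = 1), charge = 0))
  expect_error(adduct_mz("C2", adduct_rule("[M-H2O+H]1+", c(H = -1, O = -1), 1L)),
               "negative")
  expect_error(adduct_mz("H2O", adduct_rules()[["[M+H]1+ 13C"]]), "carbons")
})

test_that("ppm matching selects candidates inside the window", {
  cands <- data.frame(formula = c("C39H78NO8P", "C41H82NO8P"),
                      rule = c("[M+H]1+", "[M+H]1+"),
                      name = c("PC(31:0)", "PC(33:0)"))
  hits <- ppm_match(720.5525, cands, window_ppm = 5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$formula, "C39H78NO8P")
  expect_equal(hits$ppm_error, -1.78, tolerance = 0.01)
  expect_equal(hits$msi_level, 3L)

  exact <- ppm_match(adduct_mz("C39H78NO8P", adduct_rules()[["[M+H]1+"]]),
                     cands)
  expect_equal(exact$ppm_error[1], 0)

  far <- ppm_match(1.01 * 720.553784, cands)
  expect_equal(nrow(far), 0L)
})

test_that("head-group fragments classify PC/SM, PE and PS", {
  # phosphocholine fragment plus trimethylamine loss
  expect_equal(classify_headgroup(720.5538, c(184.0733, 661.48)), "PC/SM")
  # single phosphoethanolamine neutral loss
  expect_equal(classify_headgroup(720.5538, 579.53), "PE")
  # phosphoserine head loss
  expect_equal(classify_headgroup(720.5538, 720.5538 - 185.0089), "PS")
  # 184 alone is not PC/SM evidence without the -59 loss
  expect_equal(classify_headgroup(720.5538, 184.0733), character(0))
  expect_equal(classify_headgroup(500.3, 123.4), character(0))
})

test_that("feature-table annotation joins matches per feature", {
  feats <- data.frame(name = c("M721T300", "M999T1"),
                      mz = c(720.5525, 999.999))
  ann <- annotate_features(feats, lipid_formula_table(), window_ppm = 5)
  expect_true(all(ann$feature == "M721T300"))
  expect_true("PC(31:0)" %in% ann$putative_name)
})
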