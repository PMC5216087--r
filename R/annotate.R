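# Accurate-mass annotation: elemental-formula algebra, adduct/isotope rules,
# ppm matching and head-group fragment diagnostics.

# Monoisotopic atomic masses (Da), IUPAC/CIAAW 2021 evaluation.
# Only the elements needed for lipid annotation are carried.
.monoisotopic_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)

# Electron rest mass (Da, CODATA) and the 13C - 12C mass difference.
.electron_mass <- 0.000548579909
.c13_shift <- 1.00335483507

#' Parse an elemental formula
#'
#' Parses Hill-style elemental composition strings such as `"C39H78NO8P"`
#' into an element count vector. Underscores and whitespace (as used for
#' subscripts in typeset tables) are stripped before parsing, and an element
#' without an explicit count has count 1.
#'
#' @param text Formula string, e.g. `"H2O"`, `"C39H78NO8P"`.
#' @return A named integer vector of element counts with class `"formula_comp"`.
#' @examples
#' parse_formula("C39H78NO8P")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[_ ]", "", text)
  if (!nzchar(s)) stop("empty formula")
  counts <- integer(0)
  pos <- 1L
  while (pos <= nchar(s)) {
    m <- regmatches(substr(s, pos, nchar(s)),
                    regexec("^([A-Z][a-z]?)([0-9]*)", substr(s, pos, nchar(s))))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop(sprintf("malformed formula '%s' at position %d", text, pos))
    }
    elem <- m[2]
    if (!elem %in% names(.monoisotopic_masses)) {
      stop(sprintf("unknown element symbol '%s' at position %d in '%s'",
                   elem, pos, text))
    }
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
    pos <- pos + nchar(m[1])
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("formula has no atoms: ", text)
  structure(counts, class = "formula_comp")
}

#' Monoisotopic mass of a composition
#'
#' Sum of element counts times monoisotopic atomic masses.
#'
#' @param formula A `formula_comp` (from [parse_formula()]) or a formula
#'   string, or a named numeric vector of element counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(formula) {
  comp <- as_composition(formula)
  sum(.monoisotopic_masses[names(comp)] * as.numeric(comp))
}

as_composition <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  comp <- unclass(formula)
  if (is.null(names(comp)) || any(!names(comp) %in% names(.monoisotopic_masses))) {
    stop("composition must be named with known element symbols")
  }
  comp
}

#' Define an adduct / isotopologue rule
#'
#' An adduct rule maps a neutral composition M to an observed ion m/z by
#' adding (or removing) atoms, setting a charge, and optionally shifting
#' carbons to 13C. Charge is signed; the electron-mass correction is applied
#' per unit charge.
#'
#' @param name Rule label, e.g. `"[M+H]1+"`.
#' @param delta Named integer vector of element-count changes (may be
#'   negative, e.g. a neutral loss).
#' @param charge Signed integer charge of the product ion; must be nonzero.
#' @param n_c13 Number of 12C -> 13C substitutions (default 0).
#' @return An object of class `"adduct_rule"`.
#' @examples
#' adduct_rule("[M+H]1+", c(H = 1), charge = 1)
#' @export
adduct_rule <- function(name, delta, charge, n_c13 = 0L) {
  stopifnot(is.numeric(charge), length(charge) == 1L, charge != 0)
  if (length(delta) > 0 &&
      (is.null(names(delta)) || any(!names(delta) %in% names(.monoisotopic_masses)))) {
    stop("delta must be a named element-count vector over known elements")
  }
  structure(list(name = name, delta = delta, charge = as.integer(charge),
                 n_c13 = as.integer(n_c13)),
            class = "adduct_rule")
}

#' Built-in adduct rule registry
#'
#' Positive-mode electrospray rules used throughout: protonated and
#' ammoniated molecules, their first 13C isotopologues, and the sodiated
#' molecule.
#'
#' @return Named list of [adduct_rule()] objects.
#' @export
adduct_rules <- function() {
  list(
    "[M+H]1+"        = adduct_rule("[M+H]1+", c(H = 1), 1L),
    "[M+H]1+ 13C"    = adduct_rule("[M+H]1+ 13C", c(H = 1), 1L, n_c13 = 1L),
    "[M+NH4]1+"      = adduct_rule("[M+NH4]1+", c(N = 1, H = 4), 1L),
    "[M+NH4]1+ 13C"  = adduct_rule("[M+NH4]1+ 13C", c(N = 1, H = 4), 1L, n_c13 = 1L),
    "[M+Na]1+"       = adduct_rule("[M+Na]1+", c(Na = 1), 1L)
  )
}

#' Theoretical m/z of an ion under an adduct rule
#'
#' Applies the rule's composition delta to the neutral formula, adds any 13C
#' isotope shifts, subtracts `charge` electron masses, and divides by the
#' absolute charge.
#'
#' @param formula Neutral composition (string or `formula_comp`).
#' @param rule An [adduct_rule()].
#' @return Theoretical m/z (Th).
#' @examples
#' adduct_mz("C39H78NO8P", adduct_rules()[["[M+H]1+"]])
#' @export
adduct_mz <- function(formula, rule) {
  stopifnot(inherits(rule, "adduct_rule"))
  comp <- as_composition(formula)
  for (el in names(rule$delta)) {
    comp[el] <- (if (el %in% names(comp)) comp[[el]] else 0) + rule$delta[[el]]
  }
  if (any(comp < 0)) {
    stop(sprintf("rule '%s' yields negative element counts", rule$name))
  }
  if (rule$n_c13 > 0 && (!"C" %in% names(comp) || comp[["C"]] < rule$n_c13)) {
    stop("not enough carbons for requested 13C substitution")
  }
  comp <- comp[comp > 0]
  mass <- sum(.monoisotopic_masses[names(comp)] * as.numeric(comp)) +
    rule$n_c13 * .c13_shift
  (mass - rule$charge * .electron_mass) / abs(rule$charge)
}

#' Match an observed m/z against candidate compositions
#'
#' Computes theoretical m/z for every (formula, rule) candidate and keeps
#' those within the ppm window, ordered by absolute ppm error. Annotations
#' are putative (MSI level 3; level 2 when independent fragment evidence is
#' supplied by the caller).
#'
#' @param observed_mz Observed m/z value.
#' @param candidates Data frame with columns `formula`, `rule` (rule names
#'   resolved in `rules`) and optionally `name`; or a list of
#'   `list(formula=, rule=, name=)` entries where `rule` may be an
#'   [adduct_rule()].
#' @param window_ppm Match window in ppm (default 5, the upper end of the
#'   1-5 ppm first-pass identification window).
#' @param rules Rule registry used to resolve rule names.
#' @param fragment_evidence Logical; if `TRUE` matched annotations are
#'   reported at MSI level 2 instead of 3.
#' @return Data frame with columns `formula`, `rule`, `putative_name`,
#'   `theoretical_mz`, `ppm_error`, `msi_level`, sorted by `abs(ppm_error)`.
#' @export
ppm_match <- function(observed_mz, candidates, window_ppm = 5,
                      rules = adduct_rules(), fragment_evidence = FALSE) {
  stopifnot(window_ppm > 0, is.finite(observed_mz), observed_mz > 0)
  if (is.data.frame(candidates)) {
    candidates <- lapply(seq_len(nrow(candidates)), function(i) {
      list(formula = candidates$formula[i], rule = candidates$rule[i],
           name = if ("name" %in% names(candidates)) candidates$name[i] else NA_character_)
    })
  }
  rows <- lapply(candidates, function(cand) {
    rule <- cand$rule
    if (is.character(rule)) {
      if (!rule %in% names(rules)) stop("unknown adduct rule: ", rule)
      rule <- rules[[rule]]
    }
    theo <- adduct_mz(cand$formula, rule)
    ppm <- 1e6 * (observed_mz - theo) / theo
    data.frame(formula = as.character(cand$formula), rule = rule$name,
               putative_name = if (is.null(cand$name)) NA_character_ else cand$name,
               theoretical_mz = theo, ppm_error = ppm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[abs(out$ppm_error) <= window_ppm, , drop = FALSE]
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  out$msi_level <- rep(if (fragment_evidence) 2L else 3L, nrow(out))
  rownames(out) <- NULL
  out
}

# Head-group diagnostics computed from compositions, not nominal masses:
# phosphocholine cation C5H15NO4P+ (m/z 184.0733); neutral losses
# trimethylamine C3H9N (59.0735), phosphoethanolamine C2H8NO4P (141.0191),
# phosphoserine head C3H8NO6P (185.0089).
headgroup_rules <- function() {
  pchol <- (monoisotopic_mass("C5H14NO4P") + .monoisotopic_masses[["H"]] -
              .electron_mass)
  list(
    phosphocholine_fragment = unname(pchol),
    loss_trimethylamine = monoisotopic_mass("C3H9N"),
    loss_phosphoethanolamine = monoisotopic_mass("C2H8NO4P"),
    loss_phosphoserine = monoisotopic_mass("C3H8NO6P")
  )
}

#' Classify lipid head group from fragment evidence
#'
#' Applies the diagnostic fragmentation rules for choline-containing
#' phospholipids and for PE/PS head-group neutral losses: PC and SM ions
#' show the phosphocholine fragment at m/z 184.0733 together with a
#' trimethylamine neutral loss (precursor - 59.0735); PE shows a single
#' precursor - 141.0191 loss; PS a precursor - 185.0089 loss. All supported
#' labels are returned; ambiguity is preserved.
#'
#' @param precursor_mz Precursor ion m/z.
#' @param fragment_mzs Numeric vector of observed fragment m/z values.
#' @param tol_mz Absolute matching tolerance in Th (default 0.01).
#' @return Character vector of supported head-group labels (subset of
#'   `"PC/SM"`, `"PE"`, `"PS"`), possibly empty.
#' @export
classify_headgroup <- function(precursor_mz, fragment_mzs, tol_mz = 0.01) {
  stopifnot(length(fragment_mzs) >= 1, tol_mz > 0)
  hg <- headgroup_rules()
  near <- function(target) any(abs(fragment_mzs - target) <= tol_mz)
  labels <- character(0)
  if (near(hg$phosphocholine_fragment) &&
      near(precursor_mz - hg$loss_trimethylamine)) {
    labels <- c(labels, "PC/SM")
  }
  if (near(precursor_mz - hg$loss_phosphoethanolamine)) labels <- c(labels, "PE")
  if (near(precursor_mz - hg$loss_phosphoserine)) labels <- c(labels, "PS")
  labels
}

#' Annotate a set of features against a formula table
#'
#' Convenience wrapper over [ppm_match()] for a whole feature table and a
#' candidate lipid composition table (such as the one bundled under
#' `inst/extdata/lipid_formulas.tsv`).
#'
#' @param features Data frame with columns `name` and `mz`.
#' @param formula_table Data frame with columns `formula`, `rule` and
#'   optionally `name`.
#' @param window_ppm Match window in ppm.
#' @param rules Adduct rule registry.
#' @return Data frame of annotations, one row per (feature, match).
#' @export
annotate_features <- function(features, formula_table, window_ppm = 5,
                              rules = adduct_rules()) {
  stopifnot(all(c("name", "mz") %in% names(features)))
  out <- lapply(seq_len(nrow(features)), function(i) {
    hits <- ppm_match(features$mz[i], formula_table, window_ppm, rules)
    if (nrow(hits) == 0L) return(NULL)
    cbind(data.frame(feature = features$name[i], mz = features$mz[i],
                     stringsAsFactors = FALSE), hits)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L) {
    return(data.frame(feature = character(0), mz = numeric(0),
                      formula = character(0), rule = character(0),
                      putative_name = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), msi_level = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
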