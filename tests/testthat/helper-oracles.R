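# Independent oracles used to cross-check the implementation.
#
# The mass oracle derives residue masses from elemental compositions and
# monoisotopic atomic masses, so it shares no table with the package code.

ORACLE_ATOM <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)

ORACLE_RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_formula_mass <- function(formula) {
  sum(ORACLE_ATOM[names(formula)] * formula)
}

oracle_residue_mass <- function(letter, carbamidomethyl = TRUE) {
  m <- oracle_formula_mass(ORACLE_RESIDUE_FORMULA[[letter]])
  if (carbamidomethyl && letter == "C")
    m <- m + oracle_formula_mass(c(C = 2, H = 3, N = 1, O = 1))
  m
}

ORACLE_WATER <- oracle_formula_mass(c(H = 2, O = 1))
ORACLE_NH3 <- oracle_formula_mass(c(N = 1, H = 3))
ORACLE_PROTON <- 1.00727646688

oracle_peptide_mass <- function(sequence) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(vapply(letters, oracle_residue_mass, numeric(1))) + ORACLE_WATER
}

# m/z of one fragment by direct residue summation
oracle_fragment_mz <- function(sequence, series, index, charge, loss = "noloss") {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  frag <- if (series == "b") letters[seq_len(index)] else rev(rev(letters)[seq_len(index)])
  neutral <- sum(vapply(frag, oracle_residue_mass, numeric(1)))
  if (series == "y") neutral <- neutral + ORACLE_WATER
  neutral <- neutral - switch(loss, noloss = 0, NH3 = ORACLE_NH3, H2O = ORACLE_WATER)
  (neutral + charge * ORACLE_PROTON) / charge
}

# Brute-force digestion: every substring whose boundaries are termini or
# cleavage sites and whose internal cleavage-site count is <= max_missed.
oracle_digest <- function(sequence, enzyme, max_missed) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(letters)
  is_site <- function(i) {
    if (i < 1 || i >= L) return(FALSE)
    if (!letters[i] %in% c("K", "R")) return(FALSE)
    if (enzyme == "Trypsin" && letters[i + 1] == "P") return(FALSE)
    TRUE
  }
  out <- character()
  for (from in seq_len(L)) {
    if (from != 1 && !is_site(from - 1)) next
    for (to in from:L) {
      if (to != L && !is_site(to)) next
      internal <- if (to > from)
        sum(vapply(from:(to - 1), is_site, logical(1))) else 0
      if (internal <= max_missed)
        out <- c(out, paste0(substr(sequence, from, to), "@", from))
    }
  }
  sort(out)
}

# Seeded random peptides over the canonical alphabet
random_peptides <- function(n, min_len = 7, max_len = 30, seed = 1) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  vapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1)
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
}
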