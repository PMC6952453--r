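#' @importFrom stats median quantile sd cor lm coef predict runif rnorm rbinom rexp setNames
#' @importFrom utils head tail
NULL

# Monoisotopic residue masses (Da), canonical 20 amino acids.
# Carbamidomethylation of cysteine is applied as a fixed modification
# everywhere (+57.021464 Da), matching the library convention used throughout.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

RESIDUE_MASS <- c(
  A =  71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G =  57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P =  97.052764, Q = 128.058578, R = 156.101111, S =  87.032028,
  T = 101.047679, V =  99.068414, W = 186.079313, Y = 163.063329
)

MASS_PROTON  <- 1.007276
MASS_WATER   <- 18.010565
MASS_NH3     <- 17.026549
MASS_CAM     <- 57.021464  # carbamidomethyl, fixed on every C

# Canonical fragment-matrix layout: 12 ion-type rows x 49 cleavage-site
# columns. Column j is the site after residue j (holds b_j and y_{L-j}).
ION_TYPES <- data.frame(
  series = rep(c("b", "y"), each = 6L),
  charge = rep(rep(c(1L, 2L), each = 3L), 2L),
  loss   = rep(c("noloss", "NH3", "H2O"), 4L),
  stringsAsFactors = FALSE
)
ION_ROW_NAMES <- paste0(ION_TYPES$series, ION_TYPES$charge,
                        ifelse(ION_TYPES$loss == "noloss", "",
                               paste0("-", ION_TYPES$loss)))
N_ION_TYPES <- 12L
MAX_PEPTIDE_LENGTH <- 50L
N_FRAGMENT_SITES <- MAX_PEPTIDE_LENGTH - 1L

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("peptide sequence must be a single non-empty string")
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(letters, AA_LETTERS)
  if (length(bad))
    stop("unknown amino-acid letter(s) in '", sequence, "': ",
         paste(unique(bad), collapse = ", "))
  letters
}

#' Monoisotopic mass of a peptide
#'
#' Sums residue monoisotopic masses, adds one water for the termini and
#' +57.021464 Da per cysteine (fixed carbamidomethylation).
#'
#' @param sequence Peptide sequence (string over the 20 canonical one-letter
#'   amino-acid codes). Vectorized.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("AVLGTSNFK")
#' @export
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    letters <- .check_sequence(s)
    sum(RESIDUE_MASS[letters]) + MASS_WATER +
      MASS_CAM * sum(letters == "C")
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Precursor m/z of a peptide at a given charge
#'
#' @param sequence Peptide sequence(s).
#' @param charge Positive integer precursor charge.
#' @return m/z in Th.
#' @export
precursor_mz <- function(sequence, charge) {
  if (any(charge < 1L)) stop("charge must be >= 1")
  (peptide_mass(sequence) + charge * MASS_PROTON) / charge
}

#' Enumerate theoretical b/y fragment ions
#'
#' For a peptide of length L, returns all 12 ion types (b/y, charge 1+/2+,
#' no loss / -NH3 / -H2O) at each of the L-1 cleavage sites. Cysteines carry
#' the fixed carbamidomethyl mass. Neutral losses are generated for every
#' fragment irrespective of residue composition; in training targets the
#' unobserved ones simply stay at zero intensity.
#'
#' @param sequence Peptide sequence, 2 to 50 residues.
#' @return A data.frame with columns `series` ("b"/"y"), `index` (number of
#'   residues in the fragment), `charge`, `loss` ("noloss"/"NH3"/"H2O"),
#'   `site` (cleavage-site column, 1..L-1 from the N-terminus), `row`
#'   (canonical fragment-matrix row, 1..12) and `mz` (Th).
#' @export
enumerate_fragments <- function(sequence) {
  letters <- .check_sequence(sequence)
  L <- length(letters)
  if (L < 2L) stop("peptide must have at least 2 residues")
  if (L > MAX_PEPTIDE_LENGTH) stop("peptide longer than 50 residues")
  res <- RESIDUE_MASS[letters] + MASS_CAM * (letters == "C")
  prefix <- cumsum(res)            # b_i neutral (residue sum)
  suffix <- rev(cumsum(rev(res)))  # residue sum of last L-i+1 residues
  sites <- seq_len(L - 1L)
  out <- do.call(rbind, lapply(seq_len(N_ION_TYPES), function(r) {
    ser <- ION_TYPES$series[r]; z <- ION_TYPES$charge[r]; lo <- ION_TYPES$loss[r]
    if (ser == "b") {
      idx <- sites
      neutral <- prefix[sites]
    } else {
      idx <- L - sites
      neutral <- suffix[sites + 1L] + MASS_WATER
    }
    loss_mass <- switch(lo, noloss = 0, NH3 = MASS_NH3, H2O = MASS_WATER)
    data.frame(series = ser, index = idx, charge = z, loss = lo,
               site = sites, row = r,
               mz = (neutral - loss_mass + z * MASS_PROTON) / z,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Theoretical fragment m/z values arranged as a 12 x 49 matrix
#'
#' Same layout as [FragmentMatrix] intensity targets: rows in the canonical
#' ion-type order, column j = cleavage site after residue j. Cells beyond
#' L-1 sites are NA.
#'
#' @param sequence Peptide sequence.
#' @return 12 x 49 numeric matrix of m/z values (NA where undefined).
#' @export
fragment_mz_matrix <- function(sequence) {
  fr <- enumerate_fragments(sequence)
  m <- matrix(NA_real_, N_ION_TYPES, N_FRAGMENT_SITES,
              dimnames = list(ION_ROW_NAMES, NULL))
  m[cbind(fr$row, fr$site)] <- fr$mz
  m
}

#' Construct an empty fragment intensity matrix
#' @return 12 x 49 zero matrix with canonical row names.
#' @export
empty_fragment_matrix <- function() {
  matrix(0, N_ION_TYPES, N_FRAGMENT_SITES,
         dimnames = list(ION_ROW_NAMES, NULL))
}
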