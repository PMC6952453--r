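# One-hot sequence encodings feeding the neural models.
#
# Plain peptides: 20 rows (amino acids, alphabetical A..Y) x 50 positions,
# left-aligned, zero-padded on the right.
#
# Flanked peptides (detectability input): 22 rows (20 amino acids + blank +
# '.') x 66 positions with a fixed template: columns 1-7 N-flank (outer-side
# blank padding), 8 = '.', 9-58 peptide (left-aligned, trailing positions
# hold the blank symbol), 59 = '.', 60-66 C-flank.

FLANK_WIDTH <- 7L
BLANK_SYMBOL <- "_"
DOT_SYMBOL <- "."
FLANKED_ALPHABET <- c(AA_LETTERS, BLANK_SYMBOL, DOT_SYMBOL)
FLANKED_WIDTH <- 2L * FLANK_WIDTH + 2L + MAX_PEPTIDE_LENGTH  # 66

#' One-hot encode a peptide sequence
#'
#' @param sequence Peptide of 1 to 50 canonical residues.
#' @return A 20 x 50 binary matrix; row order is alphabetical over the
#'   one-letter codes, columns beyond the peptide length are all zero.
#' @export
encode_peptide <- function(sequence) {
  letters <- .check_sequence(sequence)
  L <- length(letters)
  if (L > MAX_PEPTIDE_LENGTH) stop("peptide longer than 50 residues")
  m <- matrix(0L, length(AA_LETTERS), MAX_PEPTIDE_LENGTH,
              dimnames = list(AA_LETTERS, NULL))
  m[cbind(match(letters, AA_LETTERS), seq_len(L))] <- 1L
  m
}

#' Decode a one-hot peptide matrix back to its sequence
#' @param matrix A 20 x 50 one-hot matrix as produced by [encode_peptide()].
#' @return The peptide string.
#' @export
decode_peptide <- function(matrix) {
  occupied <- colSums(matrix) > 0
  if (!any(occupied)) return("")
  cols <- which(occupied)
  paste(AA_LETTERS[apply(matrix[, cols, drop = FALSE], 2L, which.max)],
        collapse = "")
}

.check_flank <- function(flank, side) {
  if (is.na(flank)) flank <- ""
  letters <- if (nzchar(flank)) strsplit(flank, "", fixed = TRUE)[[1L]] else character()
  letters <- letters[letters != BLANK_SYMBOL]
  bad <- setdiff(letters, AA_LETTERS)
  if (length(bad))
    stop(side, "-flank contains invalid letter(s): ", paste(bad, collapse = ", "))
  if (length(letters) > FLANK_WIDTH)
    stop(side, "-flank longer than ", FLANK_WIDTH, " residues")
  letters
}

#' One-hot encode a peptide with its protein flanking context
#'
#' Encodes the string `<n_flank>.<peptide>.<c_flank>` over a 22-symbol
#' alphabet (20 amino acids, a blank for missing flank positions, and the
#' '.' separator), e.g. the protein context "___MASK.LLRAVILGPPGSGK.GTVCQRI"
#' for a tryptic peptide near a protein N-terminus. Layout is fixed:
#' columns 1-7 N-flank (blank-padded on the outer side), column 8 the dot,
#' columns 9-58 the peptide left-aligned (blanks after), column 59 the dot,
#' columns 60-66 the C-flank (blank-padded on the outer side).
#'
#' @param n_flank Up to 7 residues preceding the N-terminal cleavage site;
#'   may contain '_' placeholders or be shorter than 7.
#' @param sequence The peptide sequence (7-50 residues for model use).
#' @param c_flank Up to 7 residues following the C-terminal cleavage site.
#' @return A 22 x 66 binary matrix (rows: A..Y, '_', '.').
#' @export
encode_flanked_peptide <- function(n_flank, sequence, c_flank) {
  pep <- .check_sequence(sequence)
  if (length(pep) > MAX_PEPTIDE_LENGTH) stop("peptide longer than 50 residues")
  nf <- .check_flank(n_flank, "N")
  cf <- .check_flank(c_flank, "C")
  symbols <- rep(BLANK_SYMBOL, FLANKED_WIDTH)
  # N-flank right-aligned against the dot
  if (length(nf)) symbols[(FLANK_WIDTH - length(nf) + 1L):FLANK_WIDTH] <- nf
  symbols[FLANK_WIDTH + 1L] <- DOT_SYMBOL
  symbols[FLANK_WIDTH + 1L + seq_along(pep)] <- pep
  symbols[FLANK_WIDTH + 2L + MAX_PEPTIDE_LENGTH] <- DOT_SYMBOL
  if (length(cf))
    symbols[FLANK_WIDTH + 2L + MAX_PEPTIDE_LENGTH + seq_along(cf)] <- cf
  m <- matrix(0L, length(FLANKED_ALPHABET), FLANKED_WIDTH,
              dimnames = list(FLANKED_ALPHABET, NULL))
  m[cbind(match(symbols, FLANKED_ALPHABET), seq_len(FLANKED_WIDTH))] <- 1L
  m
}

#' Decode a flanked-peptide one-hot matrix
#' @param matrix A 22 x 66 matrix from [encode_flanked_peptide()].
#' @return List with `n_flank`, `sequence`, `c_flank` (blanks stripped).
#' @export
decode_flanked_peptide <- function(matrix) {
  symbols <- FLANKED_ALPHABET[apply(matrix, 2L, which.max)]
  dots <- which(symbols == DOT_SYMBOL)
  if (length(dots) != 2L) stop("malformed flanked encoding: expected 2 dots")
  strip <- function(x) paste(x[x != BLANK_SYMBOL], collapse = "")
  list(n_flank = strip(symbols[seq_len(dots[1L] - 1L)]),
       sequence = strip(symbols[(dots[1L] + 1L):(dots[2L] - 1L)]),
       c_flank = strip(symbols[(dots[2L] + 1L):length(symbols)]))
}

# Stack encodings into the 3D array (n, positions, channels) consumed by the
# network engine.
.encode_batch <- function(sequences) {
  n <- length(sequences)
  arr <- array(0, dim = c(n, MAX_PEPTIDE_LENGTH, length(AA_LETTERS)))
  for (i in seq_len(n)) arr[i, , ] <- t(encode_peptide(sequences[[i]]))
  arr
}

.encode_flanked_batch <- function(n_flanks, sequences, c_flanks) {
  n <- length(sequences)
  arr <- array(0, dim = c(n, FLANKED_WIDTH, length(FLANKED_ALPHABET)))
  for (i in seq_len(n))
    arr[i, , ] <- t(encode_flanked_peptide(n_flanks[[i]], sequences[[i]],
                                           c_flanks[[i]]))
  arr
}
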