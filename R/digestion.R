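# In silico proteolysis. Cleavage model: trypsin cuts after K or R;
# plain Trypsin suppresses cleavage when the next residue is proline,
# Trypsin/P does not. Peptides spanning up to `max_missed` internal sites
# are emitted with their true protein flanking context (up to 7 residues on
# each side) so they can feed the detectability model directly.

#' Read a protein FASTA database
#'
#' Accessions are parsed from UniProt-style headers
#' (`sp|P01234|NAME_HUMAN` -> `P01234`) or taken as the first
#' whitespace-delimited token for plain headers. Lowercase sequences are
#' uppercased with a warning; on duplicated accessions the first entry wins.
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @param entrapment Logical flag stored on every entry (default FALSE);
#'   used when assembling entrapment libraries.
#' @return A data.frame with columns `accession`, `description`, `sequence`,
#'   `entrapment`.
#' @export
read_fasta <- function(path, entrapment = FALSE) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  seqs <- as.character(aa)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues found; uppercasing")
    seqs <- toupper(seqs)
  }
  first_tok <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^[a-z]{2}\\|", first_tok),
                vapply(strsplit(first_tok, "|", fixed = TRUE), `[`, "", 2L),
                first_tok)
  desc <- sub("^\\S+\\s*", "", headers)
  dup <- duplicated(acc)
  if (any(dup)) {
    warning("duplicate accession(s) dropped: ",
            paste(unique(acc[dup]), collapse = ", "))
  }
  out <- data.frame(accession = acc, description = desc, sequence = seqs,
                    entrapment = entrapment, stringsAsFactors = FALSE)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write protein entries to FASTA
#' @param proteins Data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nzchar(proteins$description),
                      paste(proteins$accession, proteins$description),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

.cleavage_sites <- function(sequence, enzyme) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(letters)
  if (L < 1L) return(integer())
  sites <- which(letters %in% c("K", "R"))
  sites <- sites[sites < L]
  if (enzyme == "Trypsin") {
    sites <- sites[letters[sites + 1L] != "P"]
  } else if (enzyme != "Trypsin/P") {
    stop("unknown enzyme: ", enzyme, " (use 'Trypsin' or 'Trypsin/P')")
  }
  sites
}

#' Digest one protein in silico
#'
#' @param sequence Protein sequence (string) or a one-row protein entry.
#' @param enzyme `"Trypsin"` (no cleavage before proline) or `"Trypsin/P"`.
#' @param max_missed Maximum number of missed cleavage sites (>= 0).
#' @param accession Parent accession recorded on each peptide.
#' @param entrapment Entrapment flag propagated to peptides.
#' @return Data.frame with `sequence`, `n_flank`, `c_flank` (up to 7 true
#'   protein residues on each side; empty at the protein termini),
#'   `missed_cleavages`, `start`, `end`, `accession`, `entrapment`.
#' @export
digest <- function(sequence, enzyme = "Trypsin/P", max_missed = 2L,
                   accession = NA_character_, entrapment = FALSE) {
  if (is.data.frame(sequence)) {
    accession <- sequence$accession
    entrapment <- sequence$entrapment
    sequence <- sequence$sequence
  }
  if (max_missed < 0L) stop("max_missed must be >= 0")
  L <- nchar(sequence)
  sites <- .cleavage_sites(sequence, enzyme)
  bounds <- c(0L, sites, L)  # peptide k spans bounds[k]+1 .. bounds[k+1]
  n_seg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_seg)) {
    for (j in i:min(n_seg, i + max_missed)) {
      from <- bounds[i] + 1L
      to <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- c(from, to, j - i)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(), n_flank = character(),
                      c_flank = character(), missed_cleavages = integer(),
                      start = integer(), end = integer(),
                      accession = character(), entrapment = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  from <- m[, 1L]; to <- m[, 2L]
  data.frame(
    sequence = substring(sequence, from, to),
    n_flank = substring(sequence, pmax(1L, from - FLANK_WIDTH), from - 1L),
    c_flank = substring(sequence, to + 1L, pmin(L, to + FLANK_WIDTH)),
    missed_cleavages = m[, 3L],
    start = from, end = to,
    accession = accession, entrapment = entrapment,
    stringsAsFactors = FALSE
  )
}

#' Digest a whole protein table
#'
#' @inheritParams digest
#' @param proteins Protein data.frame from [read_fasta()].
#' @return Row-bound digest of all proteins.
#' @export
digest_proteins <- function(proteins, enzyme = "Trypsin/P", max_missed = 2L) {
  out <- lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins$sequence[i], enzyme, max_missed,
           accession = proteins$accession[i],
           entrapment = proteins$entrapment[i]))
  do.call(rbind, out)
}

#' Filter digested peptides on length and mass
#'
#' Keeps peptides of 7-50 residues with monoisotopic mass (including fixed
#' carbamidomethylation) at most `max_mass` Da.
#'
#' @param peptides Digest data.frame.
#' @param min_length,max_length Length bounds in residues (default 7 and 50).
#' @param max_mass Mass cutoff in Da (default 6000).
#' @return The filtered data.frame.
#' @export
filter_peptides <- function(peptides, min_length = 7L, max_length = 50L,
                            max_mass = 6000) {
  if (!nrow(peptides)) return(peptides)
  len <- nchar(peptides$sequence)
  keep <- len >= min_length & len <= max_length
  keep[keep] <- peptide_mass(peptides$sequence[keep]) <= max_mass
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Zero-missed-cleavage union of Trypsin and Trypsin/P digests
#'
#' Digests with both enzymes at zero missed cleavages and merges the results,
#' deduplicated on (sequence, start, accession) with flanks preserved. On a
#' sequence without K-P/R-P motifs the two digests coincide; proline-adjacent
#' sites make the union strictly larger than plain trypsin alone.
#'
#' @inheritParams digest
#' @return Combined digest data.frame.
#' @export
combine_no_missed_union <- function(sequence, accession = NA_character_,
                                    entrapment = FALSE) {
  a <- digest(sequence, "Trypsin", 0L, accession, entrapment)
  b <- digest(sequence, "Trypsin/P", 0L, accession, entrapment)
  both <- rbind(a, b)
  key <- paste(both$accession, both$start, both$sequence)
  out <- both[!duplicated(key), , drop = FALSE]
  out <- out[order(out$start, nchar(out$sequence)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a merged target + entrapment protein set
#'
#' Samples entrapment proteins (from a foreign-organism pool) to match the
#' target protein count, flags them, and returns the merged table. The
#' entrapment strategy spikes a library with foreign proteins so that the
#' fraction of foreign hits surviving downstream filtering proxies the
#' false-positive rate.
#'
#' @param target_proteins Protein data.frame (target organism).
#' @param entrapment_pool Protein data.frame of foreign-organism proteins.
#' @param n Number of entrapment entries to draw (default: number of target
#'   proteins). If the pool is smaller, all of it is used with a warning.
#' @param seed Integer seed making the draw reproducible.
#' @return Merged data.frame with `entrapment` set appropriately.
#' @export
build_entrapment_set <- function(target_proteins, entrapment_pool,
                                 n = nrow(target_proteins), seed = 1L) {
  shared <- intersect(target_proteins$accession, entrapment_pool$accession)
  if (length(shared))
    stop("target and entrapment pools share accessions: ",
         paste(head(shared, 3L), collapse = ", "))
  if (n > nrow(entrapment_pool)) {
    warning("entrapment pool smaller than requested; taking all ",
            nrow(entrapment_pool), " entries")
    n <- nrow(entrapment_pool)
  }
  set.seed(seed)
  idx <- sort(sample.int(nrow(entrapment_pool), n))
  trap <- entrapment_pool[idx, , drop = FALSE]
  trap$entrapment <- TRUE
  target_proteins$entrapment <- FALSE
  out <- rbind(target_proteins, trap)
  rownames(out) <- NULL
  out
}

#' Deduplicate a peptide digest to unique sequences
#'
#' Collapses rows with the same peptide sequence, merging parent accessions
#' (`;`-separated). A peptide found in both target and entrapment proteins
#' is conservatively counted as target (`entrapment = FALSE`).
#'
#' @param peptides Digest data.frame.
#' @return One row per unique sequence with merged `accession`.
#' @export
dedupe_peptides <- function(peptides) {
  if (!nrow(peptides)) return(peptides)
  sp <- split(seq_len(nrow(peptides)), peptides$sequence)
  idx <- vapply(sp, `[`, integer(1L), 1L)
  out <- peptides[idx, , drop = FALSE]
  out$accession <- vapply(sp, function(i)
    paste(sort(unique(peptides$accession[i])), collapse = ";"), "")
  out$entrapment <- vapply(sp, function(i) all(peptides$entrapment[i]), NA)
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
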