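# Assembly of predicted spectral libraries and their CSV serialization.
# Libraries are long-format tables, one row per fragment ion, using
# Spectronaut-style assay-CSV column names.

LIBRARY_COLUMNS <- c("ModifiedPeptide", "StrippedPeptide", "PrecursorCharge",
                     "PrecursorMz", "iRT", "ProteinId", "FragmentType",
                     "FragmentNumber", "FragmentCharge", "FragmentLossType",
                     "FragmentMz", "RelativeIntensity")

#' Render the modified-peptide string
#'
#' Fixed carbamidomethylation on cysteine is written in Spectronaut's
#' notation, e.g. `_VC[Carbamidomethyl (C)]K_`.
#'
#' @param sequence Stripped peptide sequence.
#' @return Modified peptide string.
#' @export
modified_peptide_string <- function(sequence) {
  paste0("_", gsub("C", "C[Carbamidomethyl (C)]", sequence, fixed = TRUE), "_")
}

#' Assemble an in silico spectral library
#'
#' Predicts fragment intensities (per-charge MS/MS models) and iRT for each
#' peptide, computes precursor and fragment m/z, and applies the fragment
#' export rule: fragments with predicted relative intensity >=
#' `min_intensity`, ranked by intensity and capped at `max_fragments`;
#' precursors retaining fewer than `min_fragments` fragments are dropped
#' (reported via message). Peptides that fail the encoder constraints are
#' skipped with a warning.
#'
#' @param peptides Data.frame with `sequence` and optionally `accession`
#'   and `entrapment`.
#' @param msms_models Named list of trained MS/MS models, e.g.
#'   `list("2" = model2, "3" = model3)`.
#' @param rt_model Trained iRT model.
#' @param charges Precursor charges to export (default 2 and 3).
#' @param min_intensity,max_fragments,min_fragments Fragment export rule.
#' @return Long-format library data.frame (one row per fragment) plus an
#'   `entrapment` column.
#' @export
assemble_library <- function(peptides, msms_models, rt_model,
                             charges = c(2L, 3L), min_intensity = 0.05,
                             max_fragments = 20L, min_fragments = 6L) {
  peptides <- peptides[!duplicated(peptides$sequence), , drop = FALSE]
  if (!"accession" %in% names(peptides)) peptides$accession <- ""
  if (!"entrapment" %in% names(peptides)) peptides$entrapment <- FALSE
  len <- nchar(peptides$sequence)
  ok <- len >= 2L & len <= MAX_PEPTIDE_LENGTH &
    !grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"),
           peptides$sequence)
  if (any(!ok)) {
    warning(sum(!ok), " peptide(s) failed encoder constraints and were skipped")
    peptides <- peptides[ok, , drop = FALSE]
  }
  if (!nrow(peptides)) return(.empty_library())
  irt <- predict_rt(rt_model, peptides$sequence)
  blocks <- list()
  dropped <- 0L
  for (z in charges) {
    model <- msms_models[[as.character(z)]]
    if (is.null(model)) stop("no MS/MS model provided for charge ", z)
    mats <- predict_msms(model, peptides$sequence)
    pmz <- precursor_mz(peptides$sequence, z)
    for (i in seq_len(nrow(peptides))) {
      rows <- .select_fragments(peptides$sequence[i], mats[[i]],
                                min_intensity, max_fragments)
      if (nrow(rows) < min_fragments) { dropped <- dropped + 1L; next }
      blocks[[length(blocks) + 1L]] <- data.frame(
        ModifiedPeptide = modified_peptide_string(peptides$sequence[i]),
        StrippedPeptide = peptides$sequence[i],
        PrecursorCharge = as.integer(z),
        PrecursorMz = pmz[i],
        iRT = irt[i],
        ProteinId = peptides$accession[i],
        rows,
        entrapment = peptides$entrapment[i],
        stringsAsFactors = FALSE)
    }
  }
  if (dropped)
    message(dropped, " precursor(s) dropped: fewer than ", min_fragments,
            " fragments above intensity ", min_intensity)
  if (!length(blocks)) return(.empty_library())
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

.select_fragments <- function(sequence, mat, min_intensity, max_fragments) {
  fr <- enumerate_fragments(sequence)
  fr$intensity <- mat[cbind(fr$row, fr$site)]
  fr <- fr[fr$intensity >= min_intensity & fr$intensity > 0, , drop = FALSE]
  fr <- fr[order(-fr$intensity, fr$row, fr$site), , drop = FALSE]
  fr <- head(fr, max_fragments)
  data.frame(FragmentType = fr$series,
             FragmentNumber = as.integer(fr$index),
             FragmentCharge = as.integer(fr$charge),
             FragmentLossType = fr$loss,
             FragmentMz = fr$mz,
             RelativeIntensity = fr$intensity,
             stringsAsFactors = FALSE)
}

.empty_library <- function() {
  out <- data.frame(ModifiedPeptide = character(), StrippedPeptide = character(),
                    PrecursorCharge = integer(), PrecursorMz = numeric(),
                    iRT = numeric(), ProteinId = character(),
                    FragmentType = character(), FragmentNumber = integer(),
                    FragmentCharge = integer(), FragmentLossType = character(),
                    FragmentMz = numeric(), RelativeIntensity = numeric(),
                    entrapment = logical(), stringsAsFactors = FALSE)
  out
}

#' Write / read a spectral library CSV
#'
#' Long-format CSV with the canonical Spectronaut-style header
#' (ModifiedPeptide, StrippedPeptide, PrecursorCharge, PrecursorMz, iRT,
#' ProteinId, FragmentType, FragmentNumber, FragmentCharge,
#' FragmentLossType, FragmentMz, RelativeIntensity). The `entrapment`
#' bookkeeping column is included unless `dialect = "spectronaut"` strips
#' it for import into external tools.
#'
#' @param library Library data.frame from [assemble_library()].
#' @param path CSV path.
#' @param dialect `"full"` (default, round-trippable) or `"spectronaut"`.
#' @return `read_library_csv` returns the library data.frame.
#' @export
write_library_csv <- function(library, path, dialect = c("full", "spectronaut")) {
  dialect <- match.arg(dialect)
  out <- library
  if (dialect == "spectronaut") out$entrapment <- NULL
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("malformed library CSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- !dt$FragmentType %in% c("b", "y") |
    !dt$FragmentLossType %in% c("noloss", "NH3", "H2O") |
    !is.finite(dt$FragmentMz) | !is.finite(dt$RelativeIntensity)
  if (any(bad))
    stop("malformed library row(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  if (!"entrapment" %in% names(dt)) dt$entrapment <- FALSE
  dt
}

#' Group proteins by identical retained peptide sets
#'
#' The protein-inference simplification used for second-pass libraries:
#' proteins whose retained peptide sets are identical are merged into one
#' group (no parsimony cover).
#'
#' @param peptides Digest data.frame with `sequence` and `accession`
#'   (possibly `;`-merged).
#' @return Data.frame mapping `accession` to `group_id`.
#' @export
group_proteins <- function(peptides) {
  acc <- strsplit(peptides$accession, ";", fixed = TRUE)
  long <- data.frame(accession = unlist(acc),
                     sequence = rep(peptides$sequence, lengths(acc)),
                     stringsAsFactors = FALSE)
  pepsets <- vapply(split(long$sequence, long$accession),
                    function(s) paste(sort(unique(s)), collapse = "|"), "")
  groups <- split(names(pepsets), pepsets)
  out <- do.call(rbind, lapply(groups, function(accs)
    data.frame(accession = accs,
               group_id = paste(sort(accs), collapse = ";"),
               stringsAsFactors = FALSE)))
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a second-pass (refined) spectral library
#'
#' Two-step DIA strategy: proteins detected in a first search are
#' re-digested in silico (Trypsin/P, <= 2 missed cleavages by default),
#' peptides are filtered by predicted detectability, protein grouping is
#' re-performed on the retained peptides, and a fresh library is assembled
#' restricted to those peptides.
#'
#' @param first_pass_ids Accessions of proteins detected in the first
#'   search.
#' @param proteins Full protein data.frame (FASTA) to map the ids into;
#'   unmapped ids are reported.
#' @param detect_model Trained detectability model.
#' @param msms_models,rt_model Prediction models for library assembly.
#' @param threshold Detectability threshold (inclusive).
#' @param max_missed Missed cleavages for the restricted digest.
#' @param ... Passed to [assemble_library()].
#' @return List with `library`, `peptides` (retained digest) and `groups`
#'   (protein grouping).
#' @export
build_second_pass_library <- function(first_pass_ids, proteins, detect_model,
                                      msms_models, rt_model, threshold = 0.5,
                                      max_missed = 2L, ...) {
  unmapped <- setdiff(first_pass_ids, proteins$accession)
  if (length(unmapped))
    warning(length(unmapped), " first-pass protein id(s) not in FASTA: ",
            paste(head(unmapped, 3L), collapse = ", "))
  sel <- proteins[proteins$accession %in% first_pass_ids, , drop = FALSE]
  dig <- dedupe_peptides(filter_peptides(
    digest_proteins(sel, "Trypsin/P", max_missed)))
  scores <- score_detectability(detect_model, dig)
  kept <- filter_by_detectability(dig, scores, threshold)
  groups <- group_proteins(kept)
  lib <- assemble_library(kept, msms_models, rt_model, ...)
  list(library = lib, peptides = kept, groups = groups)
}

#' End-to-end library generation from a protein database
#'
#' The full pipeline: (optional) entrapment merging, in silico digestion,
#' library filters (7-50 aa, <= 6000 Da), optional detectability filtering,
#' prediction and assembly. Digestion follows the two standard recipes:
#' with detectability filtering, Trypsin/P with <= `max_missed` cleavages;
#' without, the zero-missed union of Trypsin and Trypsin/P digests.
#'
#' @param proteins Target protein data.frame from [read_fasta()].
#' @param msms_models,rt_model Trained prediction models.
#' @param detect_model Optional detectability model; `NULL` disables
#'   detectability filtering.
#' @param threshold Detectability threshold.
#' @param entrapment_pool Optional foreign-organism protein data.frame;
#'   sampled to match the target count and flagged.
#' @param max_missed Missed cleavages when detectability filtering is on.
#' @param entrapment_seed Seed for entrapment sampling.
#' @param ... Passed to [assemble_library()].
#' @return List with `library`, `peptides`, `proteins`.
#' @export
build_library_from_fasta <- function(proteins, msms_models, rt_model,
                                     detect_model = NULL, threshold = 0.5,
                                     entrapment_pool = NULL, max_missed = 2L,
                                     entrapment_seed = 1L, ...) {
  if (!is.null(entrapment_pool))
    proteins <- build_entrapment_set(proteins, entrapment_pool,
                                     seed = entrapment_seed)
  if (is.null(detect_model)) {
    dig <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
      combine_no_missed_union(proteins$sequence[i],
                              accession = proteins$accession[i],
                              entrapment = proteins$entrapment[i])))
  } else {
    dig <- digest_proteins(proteins, "Trypsin/P", max_missed)
  }
  dig <- dedupe_peptides(filter_peptides(dig))
  if (!is.null(detect_model)) {
    scores <- score_detectability(detect_model, dig)
    dig <- filter_by_detectability(dig, scores, threshold)
  }
  lib <- assemble_library(dig, msms_models, rt_model, ...)
  list(library = lib, peptides = dig, proteins = proteins)
}
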