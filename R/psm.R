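# DDA search-result ingestion: PSM tables, peak lists, spectrum annotation
# into fragment-matrix training targets, and iRT calibration.

PSM_REQUIRED <- c("sequence", "charge", "q_value", "rt", "spectrum_ref")

#' Read a PSM report table
#'
#' Reads a delimited PSM export (CSV/TSV autodetected) and renames columns
#' through a declarative column map, e.g.
#' `c(sequence = "PEP.StrippedSequence", charge = "PP.Charge", ...)`.
#' Required logical columns: `sequence`, `charge`, `q_value`, `rt`,
#' `spectrum_ref`; optional: `irt`, `run_id`. Rows failing numeric coercion
#' are dropped with a warning. Duplicate precursors are preserved at this
#' stage; deduplication is [select_best_psms()].
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector mapping logical names to file
#'   column names; `NULL` if the file already uses the logical names.
#' @return Data.frame of PSM records.
#' @export
read_psm_report <- function(path, column_map = NULL) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(dt))
    if (length(missing_src))
      stop("column(s) not found in ", path, ": ",
           paste(missing_src, collapse = ", "))
    idx <- match(unname(column_map), names(dt))
    names(dt)[idx] <- names(column_map)
  }
  missing_req <- setdiff(PSM_REQUIRED, names(dt))
  if (length(missing_req))
    stop("missing mandatory PSM column(s): ",
         paste(missing_req, collapse = ", "))
  for (col in c("charge", "q_value", "rt", "irt")) {
    if (col %in% names(dt)) dt[[col]] <- suppressWarnings(as.numeric(dt[[col]]))
  }
  bad <- is.na(dt$charge) | is.na(dt$q_value) | is.na(dt$rt) |
    !nzchar(dt$sequence)
  if (any(bad)) {
    warning(sum(bad), " PSM row(s) failed type coercion and were dropped")
    dt <- dt[!bad, , drop = FALSE]
  }
  if (any(dt$q_value < 0 | dt$q_value > 1))
    stop("q_value outside [0, 1]")
  if (!"run_id" %in% names(dt)) dt$run_id <- "run1"
  rownames(dt) <- NULL
  dt
}

#' Keep one best PSM per precursor
#'
#' For each (sequence, charge) precursor, keeps the single PSM with the
#' minimum Q-value. Ties are broken deterministically by higher summed
#' matched intensity when a `matched_intensity` column is present, then by
#' lexicographic `spectrum_ref`. Precursors with charge outside
#' `keep_charges` are dropped (singly charged peptides and charges above 3+
#' are excluded from MS/MS model training).
#'
#' @param psms PSM data.frame from [read_psm_report()].
#' @param keep_charges Charges retained (default `c(2, 3)`); `NULL` keeps
#'   all.
#' @return One row per retained precursor.
#' @export
select_best_psms <- function(psms, keep_charges = c(2L, 3L)) {
  if (!is.null(keep_charges)) psms <- psms[psms$charge %in% keep_charges, ,
                                           drop = FALSE]
  if (!nrow(psms)) return(psms)
  mi <- if ("matched_intensity" %in% names(psms)) psms$matched_intensity
        else rep(0, nrow(psms))
  ord <- order(psms$sequence, psms$charge, psms$q_value, -xtfrm(mi),
               psms$spectrum_ref)
  psms <- psms[ord, , drop = FALSE]
  key <- paste(psms$sequence, psms$charge)
  out <- psms[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- peak lists -------------------------------------------------------------

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS/END IONS blocks; the TITLE line is used as the
#' spectrum reference.
#'
#' @param path Path to an MGF file.
#' @return Named list of spectra; each a data.frame with `mz`, `intensity`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  spectra <- vector("list", length(starts))
  titles <- character(length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    title_line <- grep("^TITLE=", block, value = TRUE)
    titles[k] <- if (length(title_line)) sub("^TITLE=", "", title_line[1L])
                 else paste0("index=", k)
    peaks <- block[grepl("^[0-9]", block)]
    if (length(peaks)) {
      m <- do.call(rbind, strsplit(trimws(peaks), "[ \t]+"))
      spectra[[k]] <- data.frame(mz = as.numeric(m[, 1L]),
                                 intensity = as.numeric(m[, 2L]))
    } else {
      spectra[[k]] <- data.frame(mz = numeric(), intensity = numeric())
    }
  }
  names(spectra) <- titles
  spectra
}

#' Write spectra to an MGF file
#' @param spectra Named list of peak data.frames (`mz`, `intensity`);
#'   names become TITLEs.
#' @param path Output path.
#' @param precursors Optional data.frame with `pepmass` and `charge` per
#'   spectrum.
#' @export
write_mgf <- function(spectra, path, precursors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", names(spectra)[k]), con)
    if (!is.null(precursors)) {
      writeLines(paste0("PEPMASS=", format(precursors$pepmass[k], digits = 10)), con)
      writeLines(paste0("CHARGE=", precursors$charge[k], "+"), con)
    }
    sp <- spectra[[k]]
    if (nrow(sp))
      writeLines(sprintf("%.6f %.6g", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read peak lists from an mzML file
#'
#' Thin wrapper over \pkg{mzR} (must be installed); spectrum references are
#' the native spectrum ids.
#'
#' @param path Path to an mzML file.
#' @return Named list of peak data.frames (`mz`, `intensity`).
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(pk, function(m)
    data.frame(mz = m[, 1L], intensity = m[, 2L]))
  names(spectra) <- hdr$spectrumId
  spectra
}

# --- spectrum annotation ----------------------------------------------------

#' Annotate an experimental spectrum into a fragment-intensity matrix
#'
#' For each theoretical fragment of the peptide (all 12 ion types at every
#' cleavage site), the most intense peak within the mass tolerance is
#' assigned; unmatched cells stay 0. The matrix is max-normalized so the
#' result is scale-invariant in the peak intensities.
#'
#' @param peaks Data.frame with `mz` and `intensity`.
#' @param sequence Peptide sequence (<= 50 residues).
#' @param tolerance Match tolerance; ppm by default.
#' @param unit `"ppm"` or `"Th"`.
#' @return A 12 x 49 matrix in [0, 1]; attribute `empty` is TRUE when no
#'   peak matched.
#' @export
annotate_spectrum <- function(peaks, sequence, tolerance = 20, unit = c("ppm", "Th")) {
  unit <- match.arg(unit)
  fr <- enumerate_fragments(sequence)
  mat <- empty_fragment_matrix()
  if (nrow(peaks)) {
    tol <- if (unit == "ppm") fr$mz * tolerance * 1e-6 else rep(tolerance, nrow(fr))
    for (k in seq_len(nrow(fr))) {
      hit <- which(abs(peaks$mz - fr$mz[k]) <= tol[k])
      if (length(hit)) {
        mat[fr$row[k], fr$site[k]] <- max(peaks$intensity[hit])
      }
    }
  }
  mx <- max(mat)
  if (mx > 0) mat <- mat / mx
  attr(mat, "empty") <- mx == 0
  mat
}

# --- iRT calibration --------------------------------------------------------

#' Calibrate retention times to the iRT scale
#'
#' Fits a least-squares line mapping the observed RT of reference peptides
#' found in each run to their reference iRT values, and applies it to all
#' PSMs of that run. PSMs that already carry engine-computed iRT (an `irt`
#' column with values) are left untouched.
#'
#' @param psms PSM data.frame (columns `sequence`, `rt`, `run_id`).
#' @param reference Data.frame with `sequence` and `irt` of the reference
#'   (spike-in) peptides.
#' @return List with `psms` (iRT filled) and `calibration` (per-run slope/
#'   intercept and number of anchors).
#' @export
calibrate_irt <- function(psms, reference) {
  if (!"irt" %in% names(psms)) psms$irt <- NA_real_
  cal <- list()
  for (run in unique(psms$run_id)) {
    in_run <- psms$run_id == run
    anchors <- merge(psms[in_run, c("sequence", "rt")], reference,
                     by = "sequence")
    anchors <- stats::aggregate(cbind(rt, irt) ~ sequence, anchors, median)
    if (nrow(anchors) < 2L)
      stop("run '", run, "': need >= 2 reference peptides, found ",
           nrow(anchors))
    fit <- lm(irt ~ rt, data = anchors)
    slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
    if (slope == 0) stop("degenerate iRT calibration (zero slope)")
    fill <- in_run & is.na(psms$irt)
    psms$irt[fill] <- intercept + slope * psms$rt[fill]
    cal[[run]] <- data.frame(run_id = run, slope = slope,
                             intercept = intercept, n_anchors = nrow(anchors))
  }
  list(psms = psms, calibration = do.call(rbind, cal))
}

# --- training-set assembly --------------------------------------------------

#' Split annotated PSMs into training and test subsets
#'
#' Seed-reproducible random 2/3 - 1/3 partition at the precursor level for
#' one precursor charge; no peptide sequence appears in both partitions.
#'
#' @param psms Annotated PSM data.frame (one row per precursor, e.g. with a
#'   `target` list-column).
#' @param charge Precursor charge to subset (NULL = all).
#' @param split_seed Seed for the partition.
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param min_precursors Minimum precursor count required.
#' @return List with `train` and `test` data.frames.
#' @export
build_training_set <- function(psms, charge = NULL, split_seed = 1L,
                               train_fraction = 2 / 3, min_precursors = 10L) {
  if (!is.null(charge)) psms <- psms[psms$charge == charge, , drop = FALSE]
  n <- nrow(psms)
  if (n < min_precursors)
    stop("too few precursors (", n, " < ", min_precursors, ")")
  # split on unique sequences so no peptide leaks across partitions
  seqs <- unique(psms$sequence)
  set.seed(split_seed)
  n_train <- round(train_fraction * length(seqs))
  train_seqs <- sample(seqs, n_train)
  train <- psms[psms$sequence %in% train_seqs, , drop = FALSE]
  test <- psms[!psms$sequence %in% train_seqs, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}
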