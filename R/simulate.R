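# Seeded synthetic-data generators with known ground-truth rules. They
# emulate the statistical shape of HCD DDA data (fragment-intensity
# patterns driven by local residues and position, additive retention,
# logistic detectability) well enough to validate every pipeline stage
# offline; they do not model mobile-proton physics.

# Residue frequencies loosely following natural protein composition, with
# K/R frequency such that typical tryptic peptides fall in the 7-50 aa
# window.
PROTEOME_AA_FREQ <- c(
  A = 0.080, C = 0.015, D = 0.052, E = 0.062, F = 0.040, G = 0.070,
  H = 0.025, I = 0.055, K = 0.058, L = 0.092, M = 0.024, N = 0.042,
  P = 0.047, Q = 0.040, R = 0.053, S = 0.068, T = 0.057, V = 0.066,
  W = 0.012, Y = 0.033
)

#' Generate a random proteome
#'
#' Seeded, reproducible protein entries with near-natural residue
#' composition; typical tryptic peptides fall within the 7-50 residue
#' library window.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Protein length range, default 200-400 aa.
#' @param seed Integer seed.
#' @param prefix Accession prefix.
#' @return Protein data.frame compatible with [digest_proteins()].
#' @export
generate_random_proteome <- function(n_proteins, length_range = c(200L, 400L),
                                     seed = 1L, prefix = "SYN") {
  stopifnot(n_proteins >= 1L)
  set.seed(seed)
  freq <- PROTEOME_AA_FREQ / sum(PROTEOME_AA_FREQ)
  lens <- sample(length_range[1L]:length_range[2L], n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(names(freq), L, replace = TRUE, prob = freq), collapse = ""),
    "")
  data.frame(accession = sprintf("%s%04d", prefix, seq_len(n_proteins)),
             description = "synthetic protein",
             sequence = seqs, entrapment = FALSE, stringsAsFactors = FALSE)
}

#' Ground-truth fragmentation rule
#'
#' Deterministic intensity rule standing in for real HCD fragmentation:
#' the singly charged y intensity at cleavage site j of a length-L peptide
#' is `exp(-decay * (L - j) / L)` times the basicity weights of the two
#' residues flanking the site; b ions are scaled by `b_ratio` with decay
#' from the N-terminus; doubly charged ions grow with fragment length; and
#' ammonia/water losses are strong only for fragments containing R/K/Q/N
#' or S/T/E/D respectively. Per-residue basicity weights are drawn
#' lognormally from the seed, so the rule is a pure function of
#' (parameters, seed).
#'
#' @param decay Positional decay rate (default 1.2).
#' @param b_ratio b-series intensity relative to y (default 0.45).
#' @param charge2_scale Overall scale of 2+ fragment rows (default 0.35).
#' @param loss_strong,loss_weak Neutral-loss fractions with/without the
#'   mobilizing residues.
#' @param noise_sigma Multiplicative log-normal noise applied to realized
#'   peak lists (not to the target matrices).
#' @param noise_peak_rate Density of spurious peaks added to realized peak
#'   lists, as a fraction of true peaks (default 0.05).
#' @param seed Seed for the basicity weights.
#' @return An object of class `fragmentation_rule`.
#' @export
fragmentation_rule <- function(decay = 1.2, b_ratio = 0.45,
                               charge2_scale = 0.35, loss_strong = 0.3,
                               loss_weak = 0.02, noise_sigma = 0,
                               noise_peak_rate = 0.05, seed = 1L) {
  set.seed(seed)
  basicity_n <- setNames(exp(rnorm(20L, 0, 0.6)), AA_LETTERS)
  basicity_c <- setNames(exp(rnorm(20L, 0, 0.6)), AA_LETTERS)
  structure(list(decay = decay, b_ratio = b_ratio,
                 charge2_scale = charge2_scale, loss_strong = loss_strong,
                 loss_weak = loss_weak, noise_sigma = noise_sigma,
                 noise_peak_rate = noise_peak_rate, seed = seed,
                 basicity_n = basicity_n, basicity_c = basicity_c),
            class = "fragmentation_rule")
}

NH3_LOSS_RESIDUES <- c("R", "K", "Q", "N")
H2O_LOSS_RESIDUES <- c("S", "T", "E", "D")

#' Simulate fragmentation of a peptide under a ground-truth rule
#'
#' @param sequence Peptide sequence.
#' @param rule A [fragmentation_rule()].
#' @param peak_seed Seed for the stochastic peak-list realization (noise);
#'   the target matrix itself is deterministic.
#' @return List with `matrix` (12 x 49 max-normalized target) and `peaks`
#'   (data.frame `mz`, `intensity` realized at theoretical m/z with noise).
#' @export
simulate_fragmentation <- function(sequence, rule, peak_seed = NULL) {
  letters <- .check_sequence(sequence)
  L <- length(letters)
  stopifnot(L >= 2L, L <= MAX_PEPTIDE_LENGTH)
  sites <- seq_len(L - 1L)
  flank_w <- rule$basicity_n[letters[sites]] * rule$basicity_c[letters[sites + 1L]]
  y1 <- flank_w * exp(-rule$decay * (L - sites) / L)
  b1 <- rule$b_ratio * flank_w * exp(-rule$decay * sites / L)
  # 2+ rows favor long fragments
  frac2 <- function(len_frag) .sigmoid((len_frag - 9) / 2.5) * rule$charge2_scale
  y2 <- y1 * frac2(L - sites)
  b2 <- b1 * frac2(sites)
  has_prefix <- function(set) {
    inset <- letters %in% set
    cumsum(inset)[sites] > 0
  }
  has_suffix <- function(set) {
    inset <- rev(letters %in% set)
    rev(cumsum(inset)[L - sites] > 0)
  }
  b_nh3 <- ifelse(has_prefix(NH3_LOSS_RESIDUES), rule$loss_strong, rule$loss_weak)
  b_h2o <- ifelse(has_prefix(H2O_LOSS_RESIDUES), rule$loss_strong, rule$loss_weak)
  y_nh3 <- ifelse(has_suffix(NH3_LOSS_RESIDUES), rule$loss_strong, rule$loss_weak)
  y_h2o <- ifelse(has_suffix(H2O_LOSS_RESIDUES), rule$loss_strong, rule$loss_weak)
  mat <- empty_fragment_matrix()
  mat["b1", sites] <- b1;            mat["y1", sites] <- y1
  mat["b1-NH3", sites] <- b1 * b_nh3; mat["y1-NH3", sites] <- y1 * y_nh3
  mat["b1-H2O", sites] <- b1 * b_h2o; mat["y1-H2O", sites] <- y1 * y_h2o
  mat["b2", sites] <- b2;            mat["y2", sites] <- y2
  mat["b2-NH3", sites] <- b2 * b_nh3; mat["y2-NH3", sites] <- y2 * y_nh3
  mat["b2-H2O", sites] <- b2 * b_h2o; mat["y2-H2O", sites] <- y2 * y_h2o
  mat <- mat / max(mat)

  peaks <- synthesize_peaks(sequence, mat, noise_sigma = rule$noise_sigma,
                            noise_peak_rate = rule$noise_peak_rate,
                            seed = peak_seed)
  list(matrix = mat, peaks = peaks)
}

#' Realize a peak list from a fragment-intensity matrix
#'
#' Places a peak at the theoretical m/z of every nonzero matrix cell,
#' optionally perturbed by multiplicative log-normal noise and spiked with
#' spurious peaks at random m/z. The inverse operation is
#' [annotate_spectrum()]; matrices that are themselves annotation outputs
#' are exact fixed points of synthesize-then-annotate (up to theoretical
#' m/z collisions, which annotation has already collapsed).
#'
#' @param sequence Peptide sequence the matrix belongs to.
#' @param matrix 12 x 49 intensity matrix.
#' @param noise_sigma Log-normal intensity noise (0 = none).
#' @param noise_peak_rate Spurious peaks as a fraction of true peaks.
#' @param seed Optional seed for the noise.
#' @return Data.frame with `mz`, `intensity`, sorted by m/z.
#' @export
synthesize_peaks <- function(sequence, matrix, noise_sigma = 0,
                             noise_peak_rate = 0, seed = NULL) {
  mzs <- fragment_mz_matrix(sequence)
  nz <- which(matrix > 0 & !is.na(mzs))
  peaks <- data.frame(mz = mzs[nz], intensity = matrix[nz])
  if (!is.null(seed)) set.seed(seed)
  if (noise_sigma > 0)
    peaks$intensity <- peaks$intensity * exp(rnorm(nrow(peaks), 0, noise_sigma))
  n_noise <- round(noise_peak_rate * nrow(peaks))
  if (n_noise > 0)
    peaks <- rbind(peaks, data.frame(mz = runif(n_noise, 100, 1500),
                                     intensity = runif(n_noise, 0, 0.05)))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Ground-truth additive retention rule
#'
#' iRT = sum of per-residue retention coefficients + a length term +
#' Gaussian noise, emulating classical retention-index behaviour.
#' Coefficients are drawn from the seed around zero.
#'
#' @param coef_sd Spread of the per-residue coefficients (default 3).
#' @param length_coef iRT units per residue beyond length 15.
#' @param intercept Baseline iRT.
#' @param noise_sigma Gaussian noise on each simulated iRT (iRT units).
#' @param seed Seed for the coefficients.
#' @return An object of class `retention_rule`.
#' @export
retention_rule <- function(coef_sd = 3, length_coef = 0.8, intercept = 40,
                           noise_sigma = 1, seed = 1L) {
  set.seed(seed)
  coefs <- setNames(rnorm(20L, 0, coef_sd), AA_LETTERS)
  structure(list(coefs = coefs, length_coef = length_coef,
                 intercept = intercept, noise_sigma = noise_sigma,
                 seed = seed),
            class = "retention_rule")
}

#' Simulate iRT values under a retention rule
#'
#' @param sequences Peptide sequences.
#' @param rule A [retention_rule()].
#' @param noise_seed Seed for the additive noise; `NULL` uses the current
#'   RNG state. With `noise_sigma = 0` the output is fully deterministic.
#' @return Numeric vector of iRT values.
#' @export
simulate_rt <- function(sequences, rule, noise_seed = NULL) {
  base <- vapply(sequences, function(s) {
    letters <- .check_sequence(s)
    sum(rule$coefs[letters]) +
      rule$length_coef * (length(letters) - 15L) + rule$intercept
  }, numeric(1L), USE.NAMES = FALSE)
  if (rule$noise_sigma > 0) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    base <- base + rnorm(length(base), 0, rule$noise_sigma)
  }
  base
}

KD_HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V")

#' Ground-truth detectability rule
#'
#' P(observed) is a logistic function of simple physicochemical features:
#' the hydrophobic-residue fraction, peptide length, and the C-terminal
#' residue (K vs R). Labels are Bernoulli draws from that probability.
#'
#' @param w_hydro Weight on the centered hydrophobic fraction.
#' @param w_length Weight on centered log-length.
#' @param w_cterm_k Logit bonus for C-terminal lysine.
#' @param intercept Logit intercept.
#' @param seed Default seed for label draws.
#' @return An object of class `detectability_rule`.
#' @export
detectability_rule <- function(w_hydro = 35, w_length = -8, w_cterm_k = 1.5,
                               intercept = 0.2, seed = 1L) {
  structure(list(w_hydro = w_hydro, w_length = w_length,
                 w_cterm_k = w_cterm_k, intercept = intercept, seed = seed),
            class = "detectability_rule")
}

#' Simulate detectability probabilities and labels
#'
#' @param peptides Data.frame with `sequence` (flanks are carried along but
#'   do not enter the rule).
#' @param rule A [detectability_rule()].
#' @param label_seed Seed for the Bernoulli label draws.
#' @return The input data.frame with added `prob` and `label` columns.
#' @export
simulate_detectability <- function(peptides, rule, label_seed = rule$seed) {
  feats <- t(vapply(peptides$sequence, function(s) {
    letters <- .check_sequence(s)
    c(hydro = mean(letters %in% KD_HYDROPHOBIC),
      loglen = log(length(letters)),
      cterm_k = as.numeric(letters[length(letters)] == "K"))
  }, numeric(3L)))
  logit <- rule$intercept +
    rule$w_hydro * (feats[, "hydro"] - 0.35) +
    rule$w_length * (feats[, "loglen"] - log(14)) +
    rule$w_cterm_k * feats[, "cterm_k"]
  peptides$prob <- .sigmoid(logit)
  set.seed(label_seed)
  peptides$label <- rbinom(nrow(peptides), 1L, peptides$prob)
  peptides
}

#' Draw a set of model-ready synthetic peptides
#'
#' Digests a seeded random proteome (Trypsin/P, <= 1 missed cleavage),
#' applies the 7-50 aa / <= 6000 Da library filters, deduplicates, and
#' samples `n` peptides.
#'
#' @param n Number of peptides.
#' @param seed Seed controlling the proteome and the sample.
#' @param n_proteins Size of the underlying proteome (default scales with
#'   `n`).
#' @return Digest data.frame of `n` unique peptides with flanks.
#' @export
simulate_peptides <- function(n, seed = 1L,
                              n_proteins = max(20L, ceiling(n / 18))) {
  prot <- generate_random_proteome(n_proteins, seed = seed)
  dig <- dedupe_peptides(filter_peptides(digest_proteins(prot, "Trypsin/P", 1L)))
  if (nrow(dig) < n)
    stop("proteome yielded only ", nrow(dig), " peptides; increase n_proteins")
  set.seed(seed + 1L)
  out <- dig[sample.int(nrow(dig), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate an annotated PSM training table
#'
#' Combines [simulate_peptides()], [simulate_fragmentation()] and
#' [simulate_rt()] into a table shaped like the output of the DDA ingestion
#' path: one row per precursor with the target fragment matrix attached.
#'
#' @param n Number of precursors.
#' @param charge Precursor charge assigned to all rows.
#' @param frag_rule,rt_rule Ground-truth rules (defaults seeded from
#'   `seed`).
#' @param seed Master seed.
#' @return Data.frame with `sequence`, `charge`, `irt` and list-column
#'   `target`.
#' @export
simulate_psm_dataset <- function(n, charge = 2L,
                                 frag_rule = fragmentation_rule(seed = seed),
                                 rt_rule = retention_rule(seed = seed),
                                 seed = 1L) {
  peps <- simulate_peptides(n, seed = seed)
  targets <- lapply(peps$sequence, function(s)
    simulate_fragmentation(s, frag_rule)$matrix)
  irt <- simulate_rt(peps$sequence, rt_rule, noise_seed = seed + 2L)
  out <- data.frame(sequence = peps$sequence, charge = charge, irt = irt,
                    stringsAsFactors = FALSE)
  out$target <- targets
  out
}
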