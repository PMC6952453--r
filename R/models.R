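# User-facing model objects wrapping the network engine.
#
# A `dia_model` bundles the architecture spec, trained weights, loss history
# and training metadata (seed, epochs, charge, data fingerprint) so that a
# reloaded model reproduces its predictions exactly.

.new_dia_model <- function(type, spec, params, charge = NA_integer_,
                           history = NULL, meta = list()) {
  structure(list(type = type, spec = spec, params = params, charge = charge,
                 history = history, meta = meta),
            class = "dia_model")
}

#' @export
print.dia_model <- function(x, ...) {
  cat("<dia_model>", x$type,
      if (!is.na(x$charge)) paste0("(charge ", x$charge, "+)"), "\n")
  cat("  conv: ", x$spec$conv_filters, " filters, kernel ",
      x$spec$conv_kernel, "; BiLSTM ", x$spec$lstm_units,
      "; dropout ", x$spec$dropout_rate, "; head ", x$spec$head, "\n",
      sep = "")
  if (!is.null(x$history) && nrow(x$history))
    cat("  trained ", max(x$history$epoch), " epochs (best ",
        x$meta$best_epoch %||% NA, ")\n", sep = "")
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the model (weights plus metadata) to an RDS checkpoint;
#' reloading reproduces predictions exactly.
#'
#' @param model A `dia_model`.
#' @param path Checkpoint path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dia_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dia_model"))
  model
}

# --- MS/MS fragment-intensity model ----------------------------------------

#' Build an untrained MS/MS fragment-intensity model
#'
#' Architecture: one-hot 20 x 50 input -> conv(64 filters, kernel 2) ->
#' BiLSTM(128) -> dropout(0.5) -> position-wise dense(12, ReLU) -> 12 x 49
#' intensity matrix (one column per cleavage site). Models for 2+ and 3+
#' precursors are trained separately.
#'
#' @param charge Precursor charge the model is for (2 or 3).
#' @param seed Weight-initialization seed.
#' @param dropout_rate Dropout rate after the BiLSTM (default 0.5).
#' @return An untrained `dia_model`.
#' @export
build_msms_model <- function(charge = 2L, seed = 1L, dropout_rate = 0.5) {
  if (!charge %in% c(2L, 3L)) stop("MS/MS models are per-charge, 2+ or 3+")
  spec <- nn_spec(MAX_PEPTIDE_LENGTH, length(AA_LETTERS),
                  conv_kernel = 2L, head = "sequence_relu", head_units = 12L,
                  dropout_rate = dropout_rate)
  .new_dia_model("msms", spec, nn_init(spec, seed), charge = as.integer(charge),
                 meta = list(init_seed = seed))
}

# Stack a list of 12 x 49 target matrices into the engine's sample-fastest
# (n*49) x 12 layout.
.targets_to_y <- function(matrices) {
  n <- length(matrices)
  T2 <- N_FRAGMENT_SITES
  Y <- matrix(0, n * T2, N_ION_TYPES)
  for (i in seq_len(n)) Y[(seq_len(T2) - 1L) * n + i, ] <- t(matrices[[i]])
  Y
}

# Loss weights for the masked-loss variant: 1 at real cleavage sites
# (site < peptide length), 0 at padding cells. Same layout as the targets.
.site_mask <- function(sequences) {
  n <- length(sequences)
  T2 <- N_FRAGMENT_SITES
  W <- matrix(0, n * T2, N_ION_TYPES)
  L <- nchar(sequences)
  for (i in seq_len(n)) {
    t_valid <- seq_len(max(L[i] - 1L, 0L))
    W[(t_valid - 1L) * n + i, ] <- 1
  }
  W
}

.mask_and_normalize <- function(mat, length_pep) {
  if (length_pep <= MAX_PEPTIDE_LENGTH)
    mat[, seq_len(N_FRAGMENT_SITES) >= length_pep] <- 0
  mx <- max(mat)
  if (mx > 0) mat <- mat / mx
  dimnames(mat) <- list(ION_ROW_NAMES, NULL)
  mat
}

#' Train the MS/MS fragment-intensity model
#'
#' Minimizes mean squared error over all 12 x 49 cells (targets are
#' zero-padded beyond the L-1 real sites) with Adam. Training is
#' seed-reproducible; the best epoch by validation loss is kept.
#'
#' @param model Untrained model from [build_msms_model()].
#' @param train Data.frame with `sequence`, `charge` and a list-column
#'   `target` of 12 x 49 matrices (see [annotate_spectrum()]).
#' @param val Optional validation set of the same shape.
#' @param epochs,batch_size,lr,patience Optimizer settings.
#' @param seed Shuffling/dropout seed.
#' @param masked_loss If TRUE, cells beyond each peptide's last real site
#'   are excluded from the loss instead of being trained toward zero.
#' @return The trained `dia_model` (with `history`).
#' @export
train_msms <- function(model, train, val = NULL, epochs = 100L,
                       batch_size = 64L, lr = 1e-3, patience = 10L,
                       seed = 1L, masked_loss = FALSE) {
  stopifnot(inherits(model, "dia_model"), model$type == "msms")
  if (length(unique(train$charge)) > 1L)
    stop("mixed precursor charges in training set; train per-charge models")
  if (nrow(train) && train$charge[1L] != model$charge)
    stop("training-set charge does not match model charge")
  X <- .encode_batch(train$sequence)
  Y <- .targets_to_y(train$target)
  W <- if (masked_loss) .site_mask(train$sequence) else NULL
  Xv <- Yv <- Wv <- NULL
  if (!is.null(val) && nrow(val)) {
    Xv <- .encode_batch(val$sequence)
    Yv <- .targets_to_y(val$target)
    Wv <- if (masked_loss) .site_mask(val$sequence) else NULL
  }
  fit <- nn_train(model$spec, model$params, X, Y, Xv, Yv, epochs = epochs,
                  batch_size = batch_size, lr = lr, patience = patience,
                  seed = seed, loss = "mse", weight = W, weight_val = Wv)
  model$params <- fit$params
  model$history <- fit$history
  model$meta <- c(model$meta,
                  list(train_seed = seed, epochs_run = max(fit$history$epoch),
                       best_epoch = fit$best_epoch, n_train = nrow(train)))
  model
}

#' Predict fragment-intensity matrices for peptides
#'
#' @param model Trained MS/MS `dia_model`.
#' @param sequences Character vector of peptide sequences (7-50 residues).
#' @return Named list of 12 x 49 matrices, max-normalized to 1, with cells
#'   at sites >= peptide length forced to 0.
#' @export
predict_msms <- function(model, sequences) {
  stopifnot(inherits(model, "dia_model"), model$type == "msms")
  X <- .encode_batch(sequences)
  pred <- nn_predict(model$spec, model$params, X)
  n <- length(sequences)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mat <- .seq_pred_to_matrix(pred, i, n, N_FRAGMENT_SITES)
    out[[i]] <- .mask_and_normalize(mat, nchar(sequences[i]))
  }
  names(out) <- sequences
  out
}

# --- iRT model --------------------------------------------------------------

#' Build an untrained iRT regression model
#'
#' Same hybrid architecture as the MS/MS model except for a kernel size of
#' 5 and a scalar linear head on the final BiLSTM states. iRT targets are
#' internally scaled by 1/100 during optimization and rescaled on output.
#'
#' @param seed Weight-initialization seed.
#' @param dropout_rate Dropout rate after the BiLSTM (default 0.5).
#' @return An untrained `dia_model`.
#' @export
build_rt_model <- function(seed = 1L, dropout_rate = 0.5) {
  spec <- nn_spec(MAX_PEPTIDE_LENGTH, length(AA_LETTERS),
                  conv_kernel = 5L, head = "scalar_linear",
                  dropout_rate = dropout_rate)
  .new_dia_model("rt", spec, nn_init(spec, seed),
                 meta = list(init_seed = seed, irt_scale = 100))
}

#' Train the iRT model
#'
#' Peptides are pooled across precursor charges (retention is
#' charge-independent); duplicate sequences with conflicting iRT values are
#' collapsed to their median before training.
#'
#' @param model Model from [build_rt_model()].
#' @param train Data.frame with `sequence` and `irt`.
#' @param val Optional validation data.frame.
#' @inheritParams train_msms
#' @return Trained `dia_model`.
#' @export
train_rt <- function(model, train, val = NULL, epochs = 100L,
                     batch_size = 64L, lr = 1e-3, patience = 10L, seed = 1L) {
  stopifnot(inherits(model, "dia_model"), model$type == "rt")
  if (any(is.na(train$irt))) stop("missing iRT values in training set")
  agg <- stats::aggregate(irt ~ sequence, data = train, FUN = median)
  X <- .encode_batch(agg$sequence)
  Y <- matrix(agg$irt / model$meta$irt_scale, ncol = 1L)
  Xv <- Yv <- NULL
  if (!is.null(val) && nrow(val)) {
    Xv <- .encode_batch(val$sequence)
    Yv <- matrix(val$irt / model$meta$irt_scale, ncol = 1L)
  }
  fit <- nn_train(model$spec, model$params, X, Y, Xv, Yv, epochs = epochs,
                  batch_size = batch_size, lr = lr, patience = patience,
                  seed = seed, loss = "mse")
  model$params <- fit$params
  model$history <- fit$history
  model$meta <- c(model$meta,
                  list(train_seed = seed, epochs_run = max(fit$history$epoch),
                       best_epoch = fit$best_epoch, n_train = nrow(agg)))
  model
}

#' Predict iRT for peptides
#' @param model Trained RT `dia_model`.
#' @param sequences Peptide sequences.
#' @return Numeric vector of predicted iRT values.
#' @export
predict_rt <- function(model, sequences) {
  stopifnot(inherits(model, "dia_model"), model$type == "rt")
  X <- .encode_batch(sequences)
  as.numeric(nn_predict(model$spec, model$params, X)) * model$meta$irt_scale
}

# --- detectability model ----------------------------------------------------

#' Build an untrained peptide-detectability model
#'
#' The iRT architecture (kernel 5, scalar head) on the 22 x 66 flanked
#' encoding, with a sigmoid head trained by binary cross-entropy so that
#' scores are calibrated to [0, 1].
#'
#' @param seed Weight-initialization seed.
#' @param dropout_rate Dropout rate after the BiLSTM (default 0.5).
#' @return An untrained `dia_model`.
#' @export
build_detectability_model <- function(seed = 1L, dropout_rate = 0.5) {
  spec <- nn_spec(FLANKED_WIDTH, length(FLANKED_ALPHABET),
                  conv_kernel = 5L, head = "scalar_sigmoid",
                  dropout_rate = dropout_rate)
  .new_dia_model("detectability", spec, nn_init(spec, seed),
                 meta = list(init_seed = seed))
}

#' Train the detectability model
#'
#' @param model Model from [build_detectability_model()].
#' @param train Data.frame with `n_flank`, `sequence`, `c_flank` and binary
#'   `label` (1 = observed by MS).
#' @param val Optional validation data.frame.
#' @inheritParams train_msms
#' @return Trained `dia_model`.
#' @export
train_detectability <- function(model, train, val = NULL, epochs = 100L,
                                batch_size = 64L, lr = 1e-3, patience = 10L,
                                seed = 1L) {
  stopifnot(inherits(model, "dia_model"), model$type == "detectability")
  if (length(unique(train$label)) < 2L)
    stop("single-class training set; need both observed and unobserved peptides")
  X <- .encode_flanked_batch(train$n_flank, train$sequence, train$c_flank)
  Y <- matrix(as.numeric(train$label), ncol = 1L)
  Xv <- Yv <- NULL
  if (!is.null(val) && nrow(val)) {
    Xv <- .encode_flanked_batch(val$n_flank, val$sequence, val$c_flank)
    Yv <- matrix(as.numeric(val$label), ncol = 1L)
  }
  fit <- nn_train(model$spec, model$params, X, Y, Xv, Yv, epochs = epochs,
                  batch_size = batch_size, lr = lr, patience = patience,
                  seed = seed, loss = "bce")
  model$params <- fit$params
  model$history <- fit$history
  model$meta <- c(model$meta,
                  list(train_seed = seed, epochs_run = max(fit$history$epoch),
                       best_epoch = fit$best_epoch, n_train = nrow(train)))
  model
}

#' Score peptide detectability
#'
#' @param model Trained detectability `dia_model`.
#' @param peptides Data.frame with `n_flank`, `sequence`, `c_flank` (e.g.
#'   a digest from [digest_proteins()]).
#' @return Numeric scores in [0, 1].
#' @export
score_detectability <- function(model, peptides) {
  stopifnot(inherits(model, "dia_model"), model$type == "detectability")
  X <- .encode_flanked_batch(peptides$n_flank, peptides$sequence,
                             peptides$c_flank)
  as.numeric(nn_predict(model$spec, model$params, X))
}

#' Filter peptides by detectability score
#'
#' Inclusive threshold: peptides with score >= threshold are retained,
#' order-preserving. Thresholds outside [0, 1] are clamped.
#'
#' @param peptides Data.frame of peptides (any columns).
#' @param scores Numeric scores aligned with `peptides` rows.
#' @param threshold Detectability cutoff (e.g. 0.5 or 0.6).
#' @return The retained rows of `peptides`.
#' @export
filter_by_detectability <- function(peptides, scores, threshold = 0.5) {
  if (nrow(peptides) != length(scores)) stop("scores do not align with peptides")
  threshold <- min(max(threshold, 0), 1)
  out <- peptides[scores >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a labeled detectability training set from DDA results
#'
#' Positives are peptides identified by DDA; negatives are in silico
#' tryptic peptides (same digest filters) of the identified proteins that
#' were never observed. Negatives are restricted to proteins with at least
#' one identified peptide (so absence is informative) and downsampled to
#' class balance with a seeded draw. Flanking context comes from the
#' protein sequence.
#'
#' @param identified_peptides Character vector of observed peptide
#'   sequences.
#' @param proteins Protein data.frame from [read_fasta()].
#' @param enzyme,max_missed Digestion settings for the negative candidates
#'   (default Trypsin/P, <= 2 missed cleavages).
#' @param min_length,max_length,max_mass Digest filters.
#' @param balance_seed Seed for negative downsampling.
#' @return Data.frame with `n_flank`, `sequence`, `c_flank`, `label`.
#' @export
build_detectability_dataset <- function(identified_peptides, proteins,
                                        enzyme = "Trypsin/P", max_missed = 2L,
                                        min_length = 7L, max_length = 50L,
                                        max_mass = 6000, balance_seed = 1L) {
  identified_peptides <- unique(identified_peptides)
  dig <- filter_peptides(digest_proteins(proteins, enzyme, max_missed),
                         min_length, max_length, max_mass)
  dig <- dedupe_peptides(dig)
  found <- dig$sequence %in% identified_peptides
  missing <- setdiff(identified_peptides, dig$sequence)
  if (length(missing))
    warning(length(missing), " identified peptide(s) not found in the ",
            "digested FASTA were skipped: ",
            paste(head(missing, 3L), collapse = ", "),
            if (length(missing) > 3L) ", ...")
  pos <- dig[found, , drop = FALSE]
  # only proteins that yielded at least one observed peptide
  obs_prot <- unique(unlist(strsplit(pos$accession, ";", fixed = TRUE)))
  neg <- dig[!found, , drop = FALSE]
  neg_prot <- strsplit(neg$accession, ";", fixed = TRUE)
  neg <- neg[vapply(neg_prot, function(a) any(a %in% obs_prot), NA), ,
             drop = FALSE]
  n_bal <- min(nrow(pos), nrow(neg))
  set.seed(balance_seed)
  pos <- pos[sample.int(nrow(pos), n_bal), , drop = FALSE]
  neg <- neg[sample.int(nrow(neg), n_bal), , drop = FALSE]
  out <- rbind(
    data.frame(n_flank = pos$n_flank, sequence = pos$sequence,
               c_flank = pos$c_flank, label = 1L, stringsAsFactors = FALSE),
    data.frame(n_flank = neg$n_flank, sequence = neg$sequence,
               c_flank = neg$c_flank, label = 0L, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
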