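# Metrics used to judge predicted spectra and libraries.

#' Normalized dot product between two fragment-intensity patterns
#'
#' Cosine similarity over the flattened cell vectors (zeros included):
#' sum(p*e) / sqrt(sum(p^2) * sum(e^2)). Returns 0 (with a warning) if
#' either pattern is all-zero. With `by_only = TRUE` the comparison is
#' restricted to the six b/y rows without neutral losses.
#'
#' @param pred,exp Nonnegative fragment matrices (or vectors) of identical
#'   shape.
#' @param by_only Restrict to plain b/y rows (no -NH3/-H2O), default FALSE.
#' @return Dot product in [0, 1].
#' @export
dot_product <- function(pred, exp, by_only = FALSE) {
  if (!identical(dim(pred), dim(exp)))
    stop("shape mismatch between predicted and experimental matrices")
  if (any(pred < 0) || any(exp < 0)) stop("intensities must be nonnegative")
  if (by_only && !is.null(dim(pred))) {
    keep <- ION_TYPES$loss == "noloss"
    pred <- pred[keep, , drop = FALSE]
    exp <- exp[keep, , drop = FALSE]
  }
  p <- as.numeric(pred); e <- as.numeric(exp)
  np <- sqrt(sum(p^2)); ne <- sqrt(sum(e^2))
  if (np == 0 || ne == 0) {
    warning("all-zero intensity vector; dot product undefined, returning 0")
    return(0)
  }
  sum(p * e) / (np * ne)
}

#' iRT agreement statistics
#'
#' Pearson correlation of predicted vs experimental iRT plus the spread of
#' their differences: the interquartile range and selected quantiles of
#' (predicted - experimental).
#'
#' @param pred_irt,exp_irt Paired numeric vectors (n >= 3).
#' @param probs Quantiles of the difference to report.
#' @return List with `pearson_r`, `diff_iqr`, `diff_median`,
#'   `diff_quantiles`.
#' @export
irt_stats <- function(pred_irt, exp_irt, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (length(pred_irt) != length(exp_irt)) stop("length mismatch")
  if (length(pred_irt) < 3L) stop("need at least 3 pairs")
  d <- pred_irt - exp_irt
  list(pearson_r = cor(pred_irt, exp_irt),
       diff_iqr = unname(diff(quantile(d, c(0.25, 0.75)))),
       diff_median = median(d),
       diff_quantiles = quantile(d, probs))
}

#' Entrapment percentage of an identification table
#'
#' Percentage of accepted hits that come from entrapment (foreign-organism)
#' entries: 100 * #entrapment / #all hits, after deduplicating ids.
#'
#' @param table Data.frame with columns `id` and `entrapment` (logical).
#' @return Percentage in [0, 100].
#' @export
entrapment_percentage <- function(table) {
  if (!nrow(table)) stop("empty identification table")
  tab <- table[!duplicated(table$id), , drop = FALSE]
  100 * sum(tab$entrapment) / nrow(tab)
}

#' Identification sensitivity against a reference library
#'
#' Percentage of the reference identifications recovered by the predicted
#' library: 100 * |pred intersect ref| / |ref| on deduplicated ids.
#'
#' @param pred_ids,reference_ids Character vectors of identified peptide or
#'   protein-group ids.
#' @return Percentage in [0, 100].
#' @export
sensitivity <- function(pred_ids, reference_ids) {
  reference_ids <- unique(reference_ids)
  if (!length(reference_ids)) stop("empty reference set")
  pred_ids <- unique(pred_ids)
  100 * length(intersect(pred_ids, reference_ids)) / length(reference_ids)
}

#' Coefficient of variation per feature across replicate runs
#'
#' CV = sd/mean * 100 with the sample standard deviation (n-1 denominator),
#' computed per feature over the replicate columns.
#'
#' @param quantities Numeric matrix, features x replicates (>= 2 columns).
#' @return Named numeric vector of CV percentages.
#' @export
cv_per_feature <- function(quantities) {
  quantities <- as.matrix(quantities)
  if (ncol(quantities) < 2L) stop("need at least 2 replicates")
  mu <- rowMeans(quantities)
  if (any(mu == 0)) stop("zero mean quantity; CV undefined")
  100 * apply(quantities, 1L, sd) / mu
}

#' Percent change of mean quantities between two sample groups
#'
#' 100 * (mean(B) - mean(A)) / mean(A) per feature, using the replicate
#' means of each group.
#'
#' @param quant_a,quant_b Feature x replicate matrices for groups A and B,
#'   with matching rows.
#' @return Named numeric vector of percent changes.
#' @export
percent_change <- function(quant_a, quant_b) {
  quant_a <- as.matrix(quant_a); quant_b <- as.matrix(quant_b)
  if (nrow(quant_a) != nrow(quant_b)) stop("feature mismatch between groups")
  ma <- rowMeans(quant_a); mb <- rowMeans(quant_b)
  if (any(ma == 0)) stop("zero mean in reference group; percent change undefined")
  100 * (mb - ma) / ma
}

#' Match detected precursors to reference retention times
#'
#' Joins two RT tables on precursor key and keeps pairs whose absolute RT
#' difference is strictly below the window (default 0.5 min).
#'
#' @param detected Data.frame with columns `key` and `rt`.
#' @param reference Data.frame with columns `key` and `rt`.
#' @param window_min Matching window in minutes; comparison is strict `<`.
#' @return Data.frame of matched pairs with `key`, `rt_detected`,
#'   `rt_reference`, `delta_rt`.
#' @export
rt_match <- function(detected, reference, window_min = 0.5) {
  m <- merge(detected, reference, by = "key", suffixes = c("_detected", "_reference"))
  m$delta_rt <- m$rt_detected - m$rt_reference
  out <- m[abs(m$delta_rt) < window_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC for a binary label and a score, used to
#' evaluate the detectability classifier.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher = more likely positive.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need both classes to compute AUC")
  r <- rank(scores)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
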