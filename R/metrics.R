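# Evaluation metrics: Pearson correlation, normalized spectral angle,
# median summaries, median absolute error, delta-t95 and linear-fit R^2.

# Valid-cell vectors of a predicted/target matrix pair. The target's
# mask (cells != -1) defines the comparison support.
spectrum_pair_vectors <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)))
  valid <- target != -1
  list(pred = pred[valid], target = target[valid])
}

#' Pearson correlation between predicted and target spectrum
#'
#' Product-moment correlation over the cells valid in the target mask
#' (-1 sentinel cells excluded). Returns `NA` when either vector has
#' zero variance.
#'
#' @param pred,target Fragment matrices of identical shape (-1 marks
#'   invalid cells in `target`).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_cc <- function(pred, target) {
  v <- spectrum_pair_vectors(pred, target)
  if (length(v$pred) < 2L) return(NA_real_)
  if (stats::sd(v$pred) == 0 || stats::sd(v$target) == 0) return(NA_real_)
  stats::cor(v$pred, v$target)
}

#' Normalized spectral angle
#'
#' `SA = 1 - 2 * acos(p . t) / pi` with both valid-cell vectors scaled to
#' unit L2 norm; the dot product is clamped to `[-1, 1]` to guard float
#' error. Identical spectra give 1, orthogonal spectra 0.
#'
#' @inheritParams pearson_cc
#' @return Spectral angle in `[0, 1]` for nonnegative spectra, or `NA`
#'   when either vector has zero norm.
#' @export
spectral_angle <- function(pred, target) {
  v <- spectrum_pair_vectors(pred, target)
  np <- sqrt(sum(v$pred^2)); nt <- sqrt(sum(v$target^2))
  if (np == 0 || nt == 0) return(NA_real_)
  d <- sum(v$pred / np * v$target / nt)
  d <- min(1, max(-1, d))
  1 - 2 * acos(d) / pi
}

#' Median summary of per-peptide metrics
#'
#' Drops missing values; even counts average the central pair.
#'
#' @param values Numeric vector (per-peptide PCC/SA values).
#' @return List with `median` and `n` (count used).
#' @export
median_summary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no non-missing values to summarize")
  list(median = stats::median(v), n = length(v))
}

#' Median absolute retention-time error
#'
#' The median (not mean) of absolute deviations between predicted and
#' observed RT.
#'
#' @param pred_rt,true_rt Paired numeric vectors.
#' @return Scalar in RT units.
#' @export
median_absolute_error <- function(pred_rt, true_rt) {
  if (length(pred_rt) != length(true_rt)) stop("length mismatch")
  if (!length(pred_rt)) stop("empty input")
  stats::median(abs(pred_rt - true_rt))
}

#' Delta-t95: the 95% RT deviation window
#'
#' Twice the 95th percentile (nearest-rank on the sorted absolute
#' deviations) of |observed - predicted|: the minimal time window
#' containing the RT deviations of 95% of the peptides.
#'
#' @inheritParams median_absolute_error
#' @param prob Rank probability (default 0.95).
#' @return Scalar in RT units.
#' @export
delta_t95 <- function(pred_rt, true_rt, prob = 0.95) {
  if (length(pred_rt) != length(true_rt)) stop("length mismatch")
  n <- length(pred_rt)
  if (!n) stop("empty input")
  if (n < 20L) warning("delta_t95 on fewer than 20 pairs is unstable")
  dev <- sort(abs(pred_rt - true_rt))
  2 * dev[ceiling(prob * n)]
}

#' Coefficient of determination of the RT linear fit
#'
#' Ordinary least squares of observed on predicted RT; returns R^2.
#'
#' @inheritParams median_absolute_error
#' @return R^2 in `[0, 1]`.
#' @export
linear_fit_r2 <- function(pred_rt, true_rt) {
  if (length(pred_rt) != length(true_rt)) stop("length mismatch")
  if (length(pred_rt) < 3L) stop("need at least 3 pairs")
  if (stats::sd(pred_rt) == 0) return(0)
  summary(stats::lm(true_rt ~ pred_rt))$r.squared
}

#' Evaluate a set of predicted/target spectrum pairs
#'
#' @param preds,targets Lists of fragment matrices, aligned.
#' @param labels Optional per-pair labels (e.g. modified sequences).
#' @return Data frame with per-pair `pcc` and `sa`.
#' @export
evaluate_spectra <- function(preds, targets, labels = NULL) {
  stopifnot(length(preds) == length(targets))
  data.frame(
    label = if (is.null(labels)) seq_along(preds) else labels,
    pcc = mapply(pearson_cc, preds, targets),
    sa = mapply(spectral_angle, preds, targets),
    stringsAsFactors = FALSE)
}
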