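# Error-rate estimators: reverse-decoy FDR, two-species entrapment FDR,
# synthetic-peptide FLR, and two-proteome quantification statistics
# (measured ratios, FQR, replicate CV).

#' Reverse-decoy FDR
#'
#' `FDR = 2 * Hits_reverse / (Hits_original + Hits_reverse)`: searching
#' with a target library appended with its predicted reverse-decoy
#' library gives a rough peptide-centric FDR estimate.
#'
#' @param hits_original,hits_reverse Nonnegative hit counts.
#' @return FDR fraction.
#' @export
fdr_reverse <- function(hits_original, hits_reverse) {
  stopifnot(hits_original >= 0, hits_reverse >= 0)
  den <- hits_original + hits_reverse
  if (den == 0) stop("zero denominator: no hits at all")
  2 * hits_reverse / den
}

#' Two-species entrapment FDR
#'
#' Foreign-species (entrapment) hits are scaled by the library-size
#' ratio and by `1/(1 - tolerance)` to offset the search engine's own
#' FDR tolerance:
#' `NormHits_False = Hits_False * (LibSize_main / LibSize_entrapment) / (1 - tolerance)`;
#' `FDR = NormHits_False / (Hits_True + NormHits_False)`.
#'
#' @param hits_true,hits_false Main-species and entrapment-species hit
#'   counts.
#' @param libsize_main,libsize_entrapment Unique-phosphopeptide counts
#'   of the two sub-libraries.
#' @param tolerance Inherent FDR tolerance of the search (default 0.01).
#' @return List with `norm_hits_false` and `fdr`.
#' @export
fdr_entrapment <- function(hits_true, hits_false, libsize_main,
                           libsize_entrapment, tolerance = 0.01) {
  stopifnot(hits_true >= 0, hits_false >= 0, libsize_main > 0,
            libsize_entrapment > 0, tolerance >= 0, tolerance < 1)
  norm_false <- hits_false * (libsize_main / libsize_entrapment) / (1 - tolerance)
  den <- hits_true + norm_false
  if (den == 0) stop("zero denominator: no hits at all")
  list(norm_hits_false = norm_false, fdr = norm_false / den)
}

#' False localization rate on a synthetic-peptide set
#'
#' FLR = identified sites not in the ground truth / all identified
#' sites; also reports the true-site recovery rate.
#'
#' @param identified_sites,truth_sites Character vectors of site
#'   identifiers (e.g. `"PEP1:S5"`).
#' @return List with `flr`, `recovery`, `n_identified`, `n_false`.
#' @export
flr_synthetic <- function(identified_sites, truth_sites) {
  if (!length(truth_sites)) stop("empty ground-truth site set")
  if (!length(identified_sites)) stop("no identifications")
  identified_sites <- unique(identified_sites)
  truth_sites <- unique(truth_sites)
  n_false <- sum(!identified_sites %in% truth_sites)
  list(flr = n_false / length(identified_sites),
       recovery = sum(truth_sites %in% identified_sites) / length(truth_sites),
       n_identified = length(identified_sites), n_false = n_false)
}

# mean intensity per precursor x condition after de-normalization;
# missing replicates are excluded pairwise, never imputed
condition_means <- function(quant, control) {
  q <- quant
  if ("norm_factor" %in% names(q)) q$intensity <- q$intensity / q$norm_factor
  q <- q[is.finite(q$intensity), , drop = FALSE]
  ag <- stats::aggregate(intensity ~ precursor + condition, data = q, FUN = mean)
  if (!control %in% ag$condition) stop("control condition '", control,
                                       "' absent from quant table")
  ag
}

#' Measured ratios in a dilution-series quant table
#'
#' Per precursor and condition: mean intensity over replicates divided
#' by the mean intensity at the control condition. A precursor
#' contributes at a condition only when observed in both that condition
#' and the control.
#'
#' @param quant Long data frame with columns `precursor`, `condition`,
#'   `replicate`, `intensity` and optionally `norm_factor` (intensities
#'   are de-normalized by division) and `species`.
#' @param control Name of the control condition.
#' @return Data frame with `precursor`, `condition`, `ratio` (and
#'   `species` when present).
#' @export
measured_ratios <- function(quant, control = "control") {
  ag <- condition_means(quant, control)
  ctrl <- ag[ag$condition == control, c("precursor", "intensity")]
  names(ctrl)[2] <- "control_intensity"
  rest <- ag[ag$condition != control, , drop = FALSE]
  rt <- merge(rest, ctrl, by = "precursor")
  if (!nrow(rt)) stop("no precursor observed in both a condition and the control")
  rt$ratio <- rt$intensity / rt$control_intensity
  if ("species" %in% names(quant)) {
    sp <- unique(quant[, c("precursor", "species")])
    rt <- merge(rt, sp, by = "precursor")
  }
  rt[order(rt$precursor, rt$condition), setdiff(names(rt),
                                                c("intensity", "control_intensity"))]
}

#' False quantification rate curve
#'
#' Relative error of each measurement is `|measured/expected - 1|`;
#' FQR(t) is the fraction of (precursor, condition) measurements whose
#' error exceeds t. Reported on the given threshold grid (the 0.30 and
#' 0.50 thresholds are always included).
#'
#' @param ratios Output of [measured_ratios()].
#' @param expected Named numeric vector: expected ratio per condition.
#' @param thresholds Error thresholds to evaluate.
#' @param log_scale Use `|log2(measured/expected)|` instead of the
#'   ratio-scale error.
#' @return Data frame with `threshold` and `fqr`.
#' @export
fqr_curve <- function(ratios, expected,
                      thresholds = seq(0.1, 1, by = 0.1), log_scale = FALSE) {
  if (!nrow(ratios)) stop("empty ratio table")
  missing_cond <- setdiff(unique(ratios$condition), names(expected))
  if (length(missing_cond))
    stop("expected ratio unknown for condition(s): ",
         paste(missing_cond, collapse = ", "))
  err <- if (log_scale) {
    abs(log2(ratios$ratio / expected[ratios$condition]))
  } else {
    abs(ratios$ratio / expected[ratios$condition] - 1)
  }
  thresholds <- sort(unique(c(thresholds, 0.30, 0.50)))
  data.frame(threshold = thresholds,
             fqr = vapply(thresholds, function(t) mean(err > t), numeric(1)))
}

#' Replicate coefficient of variation
#'
#' 100 x sample SD / mean per precursor and condition; conditions with
#' fewer than two observed replicates give `NA`.
#'
#' @inheritParams measured_ratios
#' @return Data frame with `precursor`, `condition`, `cv_pct`.
#' @export
replicate_cv <- function(quant) {
  q <- quant
  if ("norm_factor" %in% names(q)) q$intensity <- q$intensity / q$norm_factor
  q <- q[is.finite(q$intensity), , drop = FALSE]
  ag <- stats::aggregate(intensity ~ precursor + condition, data = q,
                         FUN = function(x) {
                           if (length(x) < 2L) return(NA_real_)
                           100 * stats::sd(x) / mean(x)
                         })
  names(ag)[names(ag) == "intensity"] <- "cv_pct"
  ag
}
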