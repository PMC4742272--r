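#' Nucleoplasmic chromatin score (Nuc-CS)
#'
#' Percent of the nucleoplasm (interior minus nucleolus) occupied by
#' condensed chromatin, where condensed means the top grayscale quartile
#' (`DN >= t_cond`, the published 193-256 band):
#' `Nuc-CS = 100 * |condensed & interior \ nucleolus| / |interior \ nucleolus|`.
#'
#' @param image calibrated [gray_image()] (or DN matrix).
#' @param seg a `nucleus_segmentation` with `continuous = TRUE`.
#' @param cfg a [threshold_config()].
#' @return Percentage in \[0, 100\].
#' @export
compute_nuc_cs <- function(image, seg, cfg = threshold_config()) {
  px <- as_pixels(image)
  if (!isTRUE(seg$continuous))
    stop("Nuc-CS is defined only for continuous (Group N) nuclei")
  denom_mask <- seg$interior_mask & !seg$nucleolus_mask
  denom <- sum(denom_mask)
  if (denom == 0L) stop("empty denominator: interior minus nucleolus has no pixels")
  100 * sum(px >= cfg$t_cond & denom_mask) / denom
}

#' Perinuclear chromatin score (Per-CS)
#'
#' Condensed area of the perinuclear rim per unit inner nuclear perimeter —
#' an effective rim thickness in pixels:
#' `Per-CS = |condensed & ring| / inner_perimeter`. The numerator counts
#' condensed (`DN >= t_cond`) pixels restricted to the ring mask, which was
#' itself isolated at `t_peri`; the two published thresholds are reconciled
#' this way.
#'
#' @inheritParams compute_nuc_cs
#' @return Non-negative length in pixels.
#' @export
compute_per_cs <- function(image, seg, cfg = threshold_config()) {
  px <- as_pixels(image)
  if (!isTRUE(seg$continuous))
    stop("Per-CS is defined only for continuous (Group N) nuclei")
  if (!is.finite(seg$inner_perimeter) || seg$inner_perimeter <= 0)
    stop("inner perimeter must be positive")
  sum(px >= cfg$t_cond & seg$ring_mask) / seg$inner_perimeter
}

#' Score one segmented nucleus
#'
#' @inheritParams compute_nuc_cs
#' @return A `nucleus_scores` list: `nucleus_id`, `nuc_cs`, `per_cs`.
#' @export
score_nucleus <- function(image, seg, cfg = threshold_config()) {
  structure(list(nucleus_id = seg$nucleus_id,
                 nuc_cs = compute_nuc_cs(image, seg, cfg),
                 per_cs = compute_per_cs(image, seg, cfg)),
            class = "nucleus_scores")
}

#' Classify a patient as Group A or Group N
#'
#' First step of the two-step algorithm. All nuclei of one specimen share
#' one phenotype in practice; any discontinuous/continuous mixture is
#' resolved by majority vote and flagged inconsistent (ties go to Group A,
#' the cautious side).
#'
#' @param nucleus_verdicts logical vector, one continuity verdict per
#'   nucleus (TRUE = continuous).
#' @return A list with `group` ("A" or "N") and `consistent` (logical).
#' @export
classify_patient <- function(nucleus_verdicts) {
  if (length(nucleus_verdicts) == 0L) stop("no nuclei to classify")
  if (anyNA(nucleus_verdicts)) stop("missing continuity verdicts")
  n_cont <- sum(nucleus_verdicts)
  consistent <- n_cont == 0L || n_cont == length(nucleus_verdicts)
  group <- if (n_cont > length(nucleus_verdicts) / 2) "N" else "A"
  if (!consistent)
    warning(sprintf("mixed nuclear phenotypes (%d continuous / %d total); majority vote -> Group %s",
                    n_cont, length(nucleus_verdicts), group))
  list(group = group, consistent = consistent)
}

#' Aggregate per-nucleus scores to the patient level
#'
#' The patient value is the arithmetic mean over nuclei; the within-patient
#' variability report carries the median and the 10th/25th/75th/90th
#' percentiles of each score (the box-plot summary).
#'
#' @param nuc_cs,per_cs numeric vectors of per-nucleus scores (equal,
#'   non-zero length).
#' @return A list with `patient_nuc_cs`, `patient_per_cs` (means), `n`, and
#'   `dispersion`, a data frame (rows nuc_cs/per_cs; columns p10, p25,
#'   median, p75, p90).
#' @export
aggregate_patient <- function(nuc_cs, per_cs) {
  if (length(nuc_cs) == 0L || length(nuc_cs) != length(per_cs))
    stop("need equal-length, non-empty score vectors")
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  q <- rbind(nuc_cs = stats::quantile(nuc_cs, probs, names = FALSE),
             per_cs = stats::quantile(per_cs, probs, names = FALSE))
  colnames(q) <- c("p10", "p25", "median", "p75", "p90")
  list(patient_nuc_cs = mean(nuc_cs), patient_per_cs = mean(per_cs),
       n = length(nuc_cs), dispersion = as.data.frame(q))
}

#' Two-step risk stratification
#'
#' Step 1: Group A (discontinuous perinuclear chromatin) is high-risk
#' regardless of scores. Step 2: a Group N patient is elevated-risk when the
#' patient-level Nuc-CS or Per-CS falls at or below its cutoff (OR rule:
#' each score is independently discriminative, with low values predicting
#' events); otherwise low-risk. No cutoffs are endorsed by default — with
#' `NULL` cutoffs every Group N patient reports low-risk and the caller is
#' expected to read the scores themselves.
#'
#' @param group "A" or "N".
#' @param patient_nuc_cs,patient_per_cs patient-level scores (required for
#'   Group N when the corresponding cutoff is supplied).
#' @param cutoff_nuc,cutoff_per score cutoffs (same units as the scores), or
#'   NULL to disable a branch.
#' @return `"high-risk"`, `"elevated-risk"` or `"low-risk"`.
#' @export
two_step_evaluate <- function(group, patient_nuc_cs = NULL, patient_per_cs = NULL,
                              cutoff_nuc = NULL, cutoff_per = NULL) {
  if (!group %in% c("A", "N")) stop("group must be 'A' or 'N'")
  if (group == "A") return("high-risk")
  low <- FALSE
  if (!is.null(cutoff_nuc)) {
    if (is.null(patient_nuc_cs)) stop("missing patient_nuc_cs for a Group N patient")
    low <- low || patient_nuc_cs <= cutoff_nuc
  }
  if (!is.null(cutoff_per)) {
    if (is.null(patient_per_cs)) stop("missing patient_per_cs for a Group N patient")
    low <- low || patient_per_cs <= cutoff_per
  }
  if (low) "elevated-risk" else "low-risk"
}
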