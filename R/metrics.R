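#' Area under the empirical ROC curve
#'
#' Step-function AUC of the operating-point curve: each true-positive-rate
#' increment contributes its height times `1 - FPR` at the operating point
#' where the increment is achieved. On tie-free data this equals the
#' Mann-Whitney concordance fraction over positive-negative pairs. Within a
#' tied block the whole TPR increment is credited at the block endpoint, a
#' conservative convention: fully tied data scores 0, not the trapezoidal 0.5.
#'
#' @param curve A `rocs_curve` (from [rocs_curve()] or [read_curve()]), or any
#'   data frame with columns `fpr`, `tpr`, `fdr`, `tdr` in `[0, 1]` ordered by
#'   descending threshold.
#' @return AUC in `[0, 1]`.
#' @examples
#' d <- labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
#' roc_auc(rocs_curve(d))  # 7/9
#' @export
roc_auc <- function(curve) {
  curve <- validate_rocs_curve(curve)
  step_auc(curve$tpr, curve$fpr)
}

#' Volume under the ROC surface (VUS)
#'
#' The ROC surface spans, at each TPR level, from the operating-point curve
#' out to `FPR = 1` at height TDR; its floor projection is the area under the
#' ordinary ROC curve. The enclosed volume is the TDR-weighted AUC
#' `sum(dTPR * TDR * (1 - FPR))`: operating points with poor precision are
#' down-weighted, so unlike the AUC the VUS is sensitive to the class ratio.
#' It reaches 1 exactly when the classes are perfectly separated (at any
#' class ratio) and approaches 0 for inseparable classes as the class ratio
#' (negatives over positives) grows.
#'
#' @inheritParams roc_auc
#' @return VUS in `[0, 1]`; never exceeds [roc_auc()] on the same curve.
#' @examples
#' d <- labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
#' vus(rocs_curve(d))  # 11/15
#' @export
vus <- function(curve) {
  curve <- validate_rocs_curve(curve)
  step_vus(curve$tpr, curve$fpr, curve$tdr)
}

#' FDR-controlled AUC (FCAUC)
#'
#' Area under the ROC curve restricted to operating points whose realized
#' false discovery rate is acceptable. The most liberal (lowest) cutoff with
#' `FDR <= fdr` is located -- the empirical FDR need not be monotone, so all
#' cutoffs are scanned -- and the ROC curve is capped at that cutoff's TPR
#' `t*`; the returned value is the step-sum area under the capped curve. If
#' no cutoff attains the FDR level the FCAUC is 0; at `fdr = 1` it equals
#' the full [roc_auc()].
#'
#' @inheritParams roc_auc
#' @param fdr Acceptable FDR level `b` in `[0, 1]`. Default 0.2.
#' @return FCAUC in `[0, 1]`.
#' @examples
#' d <- labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
#' fcauc(rocs_curve(d), fdr = 0.2)  # 2/3
#' @export
fcauc <- function(curve, fdr = 0.2) {
  if (!is.numeric(fdr) || length(fdr) != 1L || is.na(fdr) || fdr < 0 || fdr > 1) {
    rlang::abort("`fdr` must be a single value in [0, 1].",
      class = "rocsurface_invalid_input")
  }
  curve <- validate_rocs_curve(curve)
  step_fcauc(curve$tpr, curve$fpr, curve$fdr, fdr)
}
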