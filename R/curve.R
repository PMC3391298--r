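#' Compute the ROC-surface operating-point curve
#'
#' Sweep a threshold down the distinct score values of an oriented
#' labeled-scores table and record, at each cutoff, the false positive rate,
#' true positive rate, realized false discovery rate (false positives over
#' all discoveries), and true discovery rate (1 - FDR). A feature is a
#' discovery at cutoff `delta` when its score is `>= delta`; tied scores
#' enter the discovery set as one block, so the curve has one operating
#' point per distinct score value. The all-empty discovery set (where FDR is
#' 0/0) is not an operating point; the conceptual (0, 0) origin is supplied
#' by the step-sum integration in [roc_auc()] and friends.
#'
#' @param data A data frame with columns `score` and `label`, oriented so the
#'   positive class scores high (see [orient()]; `rocs_curve()` calls it for
#'   you when `reorient = TRUE`, the default).
#' @param reorient Apply [orient()] before building the curve? Default `TRUE`.
#' @return A tibble of class `rocs_curve` with columns `threshold` (strictly
#'   decreasing distinct cutoffs), `fpr`, `tpr`, `fdr`, `tdr`, and attributes
#'   `n_pos`, `n_neg` carrying the class counts.
#' @examples
#' d <- labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
#' rocs_curve(d)
#' @export
rocs_curve <- function(data, reorient = TRUE) {
  data <- validate_labeled_scores(data)
  if (reorient) data <- orient(data)
  pts <- curve_points(data$score, data$label)
  new_rocs_curve(
    tibble::tibble(
      threshold = pts$threshold,
      fpr = pts$fpr, tpr = pts$tpr, fdr = pts$fdr, tdr = pts$tdr
    ),
    n_pos = pts$n_pos, n_neg = pts$n_neg
  )
}

new_rocs_curve <- function(df, n_pos = NA_integer_, n_neg = NA_integer_) {
  attr(df, "n_pos") <- n_pos
  attr(df, "n_neg") <- n_neg
  class(df) <- c("rocs_curve", class(tibble::tibble()))
  df
}

# Vectorized operating-point computation on bare vectors. This is the hot
# path shared by the user-facing curve builder and the resampling loops in
# the inference module, which cannot afford a tibble per replicate.
curve_points <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  p <- label[o]
  n <- length(s)
  ends <- c(which(s[-n] != s[-1L]), n)  # last index of each tied block
  tp <- cumsum(p)[ends]
  fp <- ends - tp
  n_pos <- tp[length(tp)]
  n_neg <- n - n_pos
  list(
    threshold = s[ends],
    fpr = fp / n_neg,
    tpr = tp / n_pos,
    fdr = fp / ends,
    tdr = tp / ends,
    n_pos = as.integer(n_pos),
    n_neg = as.integer(n_neg)
  )
}

# Step-sum AUC/VUS/FCAUC on bare operating-point vectors; each TPR increment
# is credited at its block-endpoint FPR and TDR.
step_auc <- function(tpr, fpr) {
  sum(diff(c(0, tpr)) * (1 - fpr))
}

step_vus <- function(tpr, fpr, tdr) {
  sum(diff(c(0, tpr)) * tdr * (1 - fpr))
}

step_fcauc <- function(tpr, fpr, fdr, b) {
  ok <- which(fdr <= b)
  if (length(ok) == 0L) return(0)
  t_star <- tpr[max(ok)]  # most liberal admissible cutoff
  sum(diff(c(0, pmin(tpr, t_star))) * (1 - fpr))
}

# VUS straight from score/label vectors (oriented input assumed).
vus_from_scores <- function(score, label) {
  pts <- curve_points(score, label)
  step_vus(pts$tpr, pts$fpr, pts$tdr)
}

fcauc_from_scores <- function(score, label, b) {
  pts <- curve_points(score, label)
  step_fcauc(pts$tpr, pts$fpr, pts$fdr, b)
}

#' @keywords internal
validate_rocs_curve <- function(curve) {
  need <- c("fpr", "tpr", "fdr", "tdr")
  if (!all(need %in% names(curve))) {
    rlang::abort(
      paste0("curve must have columns ", paste(need, collapse = ", "), "."),
      class = "rocsurface_invalid_input")
  }
  for (col in need) {
    v <- curve[[col]]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      rlang::abort(paste0("curve column `", col, "` must lie in [0, 1]."),
        class = "rocsurface_invalid_input")
    }
  }
  curve
}
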