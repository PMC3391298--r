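#' Construct a labeled-scores table
#'
#' Bundle per-feature ranking scores with binary truth labels (spike-in style
#' gold standards) into the tibble that every downstream curve, metric and
#' test consumes. Scores are unitless; a larger score is expected to indicate
#' stronger evidence for the true positive class after [orient()].
#'
#' @param score Numeric vector of per-feature scores.
#' @param label Logical vector the same length as `score`; `TRUE` marks the
#'   true positive class, `FALSE` the true negative class. Numeric 0/1 and
#'   factor/character vectors with exactly two values are coerced, in which
#'   case `positive` names the positive level.
#' @param positive Value of `label` identifying the true positive class when
#'   `label` is not already logical. Default `1`.
#'
#' @return A tibble of class `labeled_scores` with columns `score` (double)
#'   and `label` (logical, `TRUE` = true positive).
#' @examples
#' labeled_scores(c(0.9, 0.8, 0.1), c(1, 1, 0))
#' @export
labeled_scores <- function(score, label, positive = 1) {
  if (!is.numeric(score)) {
    rlang::abort("`score` must be numeric.", class = "rocsurface_invalid_input")
  }
  if (!is.logical(label)) {
    label <- label == positive
  }
  out <- tibble::tibble(score = as.double(score), label = label)
  class(out) <- c("labeled_scores", class(tibble::tibble()))
  validate_labeled_scores(out)
}

#' @keywords internal
validate_labeled_scores <- function(data) {
  if (!all(c("score", "label") %in% names(data))) {
    rlang::abort("`data` must have columns `score` and `label`.",
      class = "rocsurface_invalid_input")
  }
  if (nrow(data) < 2L) {
    rlang::abort("need at least 2 features (scores).",
      class = "rocsurface_invalid_input")
  }
  if (anyNA(data$score) || !is.numeric(data$score)) {
    rlang::abort("`score` must be numeric with no missing values.",
      class = "rocsurface_invalid_input")
  }
  if (anyNA(data$label) || !is.logical(data$label)) {
    rlang::abort("`label` must be logical (TRUE = positive) with no missing values.",
      class = "rocsurface_invalid_input")
  }
  if (!any(data$label) || all(data$label)) {
    rlang::abort("single-class input: need at least one positive and one negative label.",
      class = "rocsurface_single_class")
  }
  data
}

#' Orient scores so positives sit to the right
#'
#' The ROC-surface construction assumes the true positive class scores higher
#' than the true negative class. `orient()` checks the class medians and, when
#' the positive median falls below the negative median, negates every score
#' (labels are untouched). Ties between the medians leave the data unchanged,
#' so the operation is idempotent.
#'
#' @param data A data frame with columns `score` and `label`
#'   (see [labeled_scores()]).
#' @return The same table, with `score` negated if the positive-class median
#'   was below the negative-class median.
#' @examples
#' orient(labeled_scores(1:4, c(1, 1, 0, 0)))
#' @export
orient <- function(data) {
  data <- validate_labeled_scores(data)
  med_pos <- stats::median(data$score[data$label])
  med_neg <- stats::median(data$score[!data$label])
  if (med_pos < med_neg) {
    data$score <- -data$score
  }
  data
}

#' Rank scores with random tie breaking
#'
#' Transform scores into the integer ranks 1..n, resolving tied scores by a
#' uniformly random ordering within each tied block. Used by the two-surface
#' difference test, which works on within-study ranks.
#'
#' @param score Numeric vector, length at least 1.
#' @param seed Optional integer; when supplied the tie-breaking is
#'   deterministic given the seed and the caller's RNG state is untouched.
#' @return Integer vector: a permutation of `1:length(score)` consistent with
#'   the score order.
#' @examples
#' rank_transform(c(10, 30, 20))
#' rank_transform(c(5, 5, 1), seed = 7)
#' @export
rank_transform <- function(score, seed = NULL) {
  if (length(score) < 1L || !is.numeric(score) || anyNA(score)) {
    rlang::abort("`score` must be non-empty numeric with no missing values.",
      class = "rocsurface_invalid_input")
  }
  with_seed_if(seed, as.integer(rank(score, ties.method = "random")))
}

# Evaluate `code` under a temporary RNG seeded with `seed`; NULL leaves the
# caller's RNG stream in charge.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
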