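# Shared fixtures and independent oracles.

# Worked 6-feature example used throughout: 3 positives, 3 negatives,
# positives at ranks 1, 2, 5 from the top.
six_feature <- function() {
  labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
}

# Random labeled scores, optionally with heavy ties (scores on a small
# integer lattice), always containing both classes.
random_labeled <- function(n, ties = FALSE) {
  score <- if (ties) sample(1:5, n, replace = TRUE) + 0 else rnorm(n)
  n_pos <- sample(seq_len(n - 1L), 1)
  labeled_scores(score, sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos))))
}

# Mann-Whitney concordance fraction by brute-force pair counting
# (tie-free scores).
mw_auc <- function(data) {
  pos <- data$score[data$label]
  neg <- data$score[!data$label]
  mean(outer(pos, neg, ">"))
}

# Riemann integral of TDR(t) * (1 - FPR(t)) over TPR levels t in [0, 1],
# evaluating the step functions at midpoints of a uniform grid. Exact for
# step curves whose TPR breakpoints fall on grid-cell boundaries.
riemann_vus <- function(curve, n_grid = 1e5) {
  t_mid <- (seq_len(n_grid) - 0.5) / n_grid
  idx <- findInterval(t_mid, c(0, curve$tpr), left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[idx > nrow(curve)] <- nrow(curve)
  mean(curve$tdr[idx] * (1 - curve$fpr[idx]))
}
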