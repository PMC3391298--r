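#' Label-permutation test for VUS or FCAUC
#'
#' Assess the significance of the between-class separation summarized by the
#' volume under the ROC surface (or the FDR-controlled AUC). The null
#' distribution is built by permuting the true positive / true negative
#' labels over positions `K` times with the scores fixed; each permuted set
#' is re-oriented before the statistic is recomputed, since a permutation can
#' flip the class medians. The one-sided p-value is the proportion of
#' permuted statistics at or above the observed value.
#'
#' @param data A data frame with columns `score` and `label`
#'   (see [labeled_scores()]). Oriented internally.
#' @param statistic `"vus"` (default) or `"fcauc"`.
#' @param K Number of label permutations (positive integer).
#' @param fdr Acceptable FDR level, used when `statistic = "fcauc"`.
#' @param seed Optional integer seed; the result is deterministic given it.
#' @param add_one Use the `(count + 1) / (K + 1)` correction instead of the
#'   plain proportion? Default `FALSE`.
#' @return A `rocs_test` object: observed statistic, the `K` permuted
#'   statistics, and the p-value. Use [generics::tidy()] / [generics::glance()]
#'   for a one-row tibble.
#' @examples
#' d <- simulate_two_class(n_neg = 60, n_pos = 20, mu_pos = 2, seed = 1)
#' rocs_perm_test(d, K = 99, seed = 1)
#' @export
rocs_perm_test <- function(data, statistic = c("vus", "fcauc"), K = 1000,
                           fdr = 0.2, seed = NULL, add_one = FALSE) {
  statistic <- match.arg(statistic)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1) {
    rlang::abort("`K` must be a positive integer.",
      class = "rocsurface_invalid_input")
  }
  K <- as.integer(K)
  data <- orient(validate_labeled_scores(data))
  stat_fun <- if (statistic == "vus") {
    function(s, l) vus_from_scores(s, l)
  } else {
    if (!is.numeric(fdr) || fdr < 0 || fdr > 1) {
      rlang::abort("`fdr` must lie in [0, 1].", class = "rocsurface_invalid_input")
    }
    function(s, l) fcauc_from_scores(s, l, fdr)
  }
  observed <- stat_fun(data$score, data$label)

  null_values <- with_seed_if(seed, {
    vapply(seq_len(K), function(k) {
      lab <- sample(data$label)
      sc <- data$score
      if (stats::median(sc[lab]) < stats::median(sc[!lab])) sc <- -sc
      stat_fun(sc, lab)
    }, numeric(1))
  })

  new_rocs_test(
    observed = observed, null_values = null_values,
    n_resamples = K, seed = seed, add_one = add_one,
    statistic = statistic,
    method = paste0("Label-permutation test (", toupper(statistic), ")")
  )
}

#' Bootstrap test for the difference between two ROC surfaces
#'
#' Tests whether two studies were generated from the same class-specific
#' distributions of ranks, using the absolute difference in VUS as the
#' statistic. Because the VUS depends on the class ratio, the null
#' distribution is built after equalizing the ratio influence: from each
#' study, `(n0 + m0) / 2` negatives and `(n1 + m1) / 2` positives (rounded)
#' are resampled with replacement; each study's resample is converted to
#' within-study ranks with random tie breaking; the negative ranks of both
#' studies are pooled, as are the positive ranks. Each of `B` bootstrap
#' replicates then redraws both studies at their original class sizes from
#' these pooled null distributions and recomputes the absolute VUS
#' difference. The observed statistic is computed on the full original
#' (oriented) studies, and the p-value is the proportion of bootstrap
#' differences at or above it.
#'
#' @param study1,study2 Data frames with columns `score` and `label`
#'   (see [labeled_scores()]). Oriented internally.
#' @param B Number of bootstrap replicates (positive integer); 199 or more
#'   is recommended for testing at the 0.05 level.
#' @inheritParams rocs_perm_test
#' @return A `rocs_test` object.
#' @examples
#' s1 <- simulate_two_class(n_neg = 150, n_pos = 50, mu_pos = 1, seed = 1)
#' s2 <- simulate_two_class(n_neg = 150, n_pos = 50, mu_pos = 2, seed = 2)
#' rocs_diff_test(s1, s2, B = 99, seed = 3)
#' @export
rocs_diff_test <- function(study1, study2, B = 199, seed = NULL,
                           add_one = FALSE) {
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B < 1) {
    rlang::abort("`B` must be a positive integer.",
      class = "rocsurface_invalid_input")
  }
  B <- as.integer(B)
  study1 <- orient(validate_labeled_scores(study1))
  study2 <- orient(validate_labeled_scores(study2))

  observed <- abs(vus_from_scores(study1$score, study1$label) -
                  vus_from_scores(study2$score, study2$label))

  n1 <- sum(study1$label); n0 <- sum(!study1$label)
  m1 <- sum(study2$label); m0 <- sum(!study2$label)
  k_pos <- max(1L, as.integer(round((n1 + m1) / 2)))
  k_neg <- max(1L, as.integer(round((n0 + m0) / 2)))

  null_values <- with_seed_if(seed, {
    pools <- lapply(list(study1, study2), function(st) {
      neg <- sample(st$score[!st$label], k_neg, replace = TRUE)
      pos <- sample(st$score[st$label], k_pos, replace = TRUE)
      r <- rank(c(neg, pos), ties.method = "random")
      list(neg = r[seq_len(k_neg)], pos = r[k_neg + seq_len(k_pos)])
    })
    pool_neg <- c(pools[[1]]$neg, pools[[2]]$neg)
    pool_pos <- c(pools[[1]]$pos, pools[[2]]$pos)
    lab1 <- rep(c(FALSE, TRUE), c(n0, n1))
    lab2 <- rep(c(FALSE, TRUE), c(m0, m1))
    vapply(seq_len(B), function(b) {
      v1 <- vus_from_scores(
        c(sample(pool_neg, n0, replace = TRUE),
          sample(pool_pos, n1, replace = TRUE)), lab1)
      v2 <- vus_from_scores(
        c(sample(pool_neg, m0, replace = TRUE),
          sample(pool_pos, m1, replace = TRUE)), lab2)
      abs(v1 - v2)
    }, numeric(1))
  })

  new_rocs_test(
    observed = observed, null_values = null_values,
    n_resamples = B, seed = seed, add_one = add_one,
    statistic = "abs_vus_diff",
    method = "Bootstrap test for the difference between two ROC surfaces"
  )
}

new_rocs_test <- function(observed, null_values, n_resamples, seed, add_one,
                          statistic, method) {
  exceed <- sum(null_values >= observed)
  p_value <- if (add_one) (exceed + 1) / (n_resamples + 1) else exceed / n_resamples
  structure(
    list(
      observed = observed,
      null_values = null_values,
      p_value = p_value,
      n_resamples = n_resamples,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      statistic = statistic,
      method = method
    ),
    class = "rocs_test"
  )
}

#' @export
print.rocs_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("observed %s = %.6g\n", x$statistic, x$observed))
  cat(sprintf("resamples = %d, p-value = %.4g\n", x$n_resamples, x$p_value))
  if (!is.na(x$seed)) cat(sprintf("seed = %d\n", x$seed))
  invisible(x)
}

#' Tidy a ROC-surface test result
#'
#' @param x A `rocs_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-value, resample
#'   count and seed.
#' @exportS3Method generics::tidy
tidy.rocs_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    estimate = x$observed,
    p.value = x$p_value,
    n.resamples = x$n_resamples,
    null.mean = mean(x$null_values),
    seed = x$seed
  )
}

#' @rdname tidy.rocs_test
#' @exportS3Method generics::glance
glance.rocs_test <- function(x, ...) {
  tidy.rocs_test(x)
}
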