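#' Simulate a two-class Gaussian dataset
#'
#' Draw scores for a synthetic class-skewed study: `n_neg` true negatives
#' from `Normal(mu_neg, sigma)` and `n_pos` true positives from
#' `Normal(mu_pos, sigma)`. A shared unit standard deviation (the default)
#' makes `mu_pos - mu_neg` the separation between the classes and
#' `n_neg / n_pos` the class ratio, the two quantities that drive the VUS.
#'
#' @param n_neg,n_pos Class sizes (positive integers).
#' @param mu_pos True-positive class mean.
#' @param mu_neg True-negative class mean. Default 0.
#' @param sigma Shared standard deviation, `> 0`. Default 1.
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return A [labeled_scores()] tibble with `n_neg + n_pos` rows (negatives
#'   first).
#' @examples
#' simulate_two_class(n_neg = 1000, n_pos = 100, mu_pos = 2, seed = 1)
#' @export
simulate_two_class <- function(n_neg, n_pos, mu_pos, mu_neg = 0, sigma = 1,
                               seed = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be positive.", class = "rocsurface_invalid_input")
  }
  if (n_neg < 1 || n_pos < 1) {
    rlang::abort("`n_neg` and `n_pos` must be at least 1.",
      class = "rocsurface_invalid_input")
  }
  score <- with_seed_if(seed, c(
    stats::rnorm(n_neg, mu_neg, sigma),
    stats::rnorm(n_pos, mu_pos, sigma)
  ))
  labeled_scores(score, rep(c(FALSE, TRUE), c(n_neg, n_pos)))
}

# Split a total sample size by the class ratio (negatives : positives = r : 1),
# keeping at least one positive.
split_by_ratio <- function(n_total, ratio) {
  n_pos <- max(1L, as.integer(round(n_total / (1 + ratio))))
  c(n_neg = n_total - n_pos, n_pos = n_pos)
}

#' Mean VUS and FCAUC over a separation-by-class-ratio grid
#'
#' For each combination of class separation (distance between the Gaussian
#' class means, shared SD 1) and class ratio, simulate `reps` independent
#' datasets of `n_total` samples and average the VUS and the FCAUC at FDR
#' level `fdr`. This maps how the volume under the surface degrades with
#' overlap and skew: it approaches 1 for well-separated classes at any
#' ratio, and 0 for inseparable classes at large ratio, while the FCAUC
#' drops to exactly 0 near zero separation at every ratio.
#'
#' @param distances Numeric vector of separations `mu_pos - mu_neg`.
#' @param ratios Numeric vector of class ratios (negatives / positives),
#'   each `>= 1`.
#' @param n_total Total samples per dataset (default 2000), split by ratio.
#' @param reps Replicates per grid cell (default 50).
#' @param fdr FDR level for the FCAUC (default 0.2).
#' @param seed Optional integer seed.
#' @return A tibble with one row per `(distance, ratio)` cell: `distance`,
#'   `ratio`, `mean_vus`, `mean_fcauc`, `n_reps`.
#' @examples
#' simulate_vus_grid(c(0, 3, 6), c(1, 10), n_total = 500, reps = 5, seed = 1)
#' @export
simulate_vus_grid <- function(distances, ratios, n_total = 2000, reps = 50,
                              fdr = 0.2, seed = NULL) {
  if (length(distances) == 0L || length(ratios) == 0L) {
    rlang::abort("`distances` and `ratios` must be non-empty.",
      class = "rocsurface_invalid_input")
  }
  if (n_total < 2) {
    rlang::abort("`n_total` must be at least 2.",
      class = "rocsurface_invalid_input")
  }
  grid <- tidyr::expand_grid(distance = distances, ratio = ratios)
  with_seed_if(seed, {
    res <- purrr::pmap(grid, function(distance, ratio) {
      n <- split_by_ratio(n_total, ratio)
      lab <- rep(c(FALSE, TRUE), n)
      vals <- vapply(seq_len(reps), function(i) {
        sc <- c(stats::rnorm(n[["n_neg"]], 0, 1),
                stats::rnorm(n[["n_pos"]], distance, 1))
        pts <- curve_points(sc, lab)
        c(step_vus(pts$tpr, pts$fpr, pts$tdr),
          step_fcauc(pts$tpr, pts$fpr, pts$fdr, fdr))
      }, numeric(2))
      tibble::tibble(mean_vus = mean(vals[1, ]), mean_fcauc = mean(vals[2, ]))
    })
    dplyr::bind_cols(grid, dplyr::bind_rows(res), n_reps = as.integer(reps))
  })
}

#' Size / power study for the two-surface difference test
#'
#' Simulate `reps` pairs of studies -- negatives `N(0, 1)` in both, positives
#' `N(mu1, 1)` in study 1 and `N(mu2, 1)` in study 2 -- run
#' [rocs_diff_test()] on each pair, and report the fraction of p-values below
#' `alpha`. With `mu1 = mu2` the null holds and the rejection rate estimates
#' the size of the test (about `alpha`); with `mu1 != mu2` it estimates
#' power, which falls as the class ratio grows.
#'
#' @param mu1,mu2 True-positive class means of the two studies.
#' @param n1_total,n2_total Total samples per study (default 4000 each).
#' @param ratio1,ratio2 Class ratios (negatives / positives) of the two
#'   studies (default 1).
#' @param reps Number of simulated study pairs (default 100).
#' @param B Bootstrap replicates per test (default 199).
#' @param alpha Rejection level in (0, 1) (default 0.05).
#' @param seed Optional integer seed.
#' @return A one-row tibble with the design parameters, the `rejection_rate`,
#'   and the per-replicate `p_values` as a list column.
#' @examples
#' simulate_size_power(1, 2, n1_total = 400, n2_total = 400,
#'                     reps = 5, B = 49, seed = 1)
#' @export
simulate_size_power <- function(mu1, mu2, n1_total = 4000, n2_total = 4000,
                                ratio1 = 1, ratio2 = 1, reps = 100, B = 199,
                                alpha = 0.05, seed = NULL) {
  if (reps < 1 || B < 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("need `reps` >= 1, `B` >= 1 and `alpha` in (0, 1).",
      class = "rocsurface_invalid_input")
  }
  n1 <- split_by_ratio(n1_total, ratio1)
  n2 <- split_by_ratio(n2_total, ratio2)
  p_values <- with_seed_if(seed, {
    vapply(seq_len(reps), function(i) {
      s1 <- labeled_scores(
        c(stats::rnorm(n1[["n_neg"]]), stats::rnorm(n1[["n_pos"]], mu1)),
        rep(c(FALSE, TRUE), n1))
      s2 <- labeled_scores(
        c(stats::rnorm(n2[["n_neg"]]), stats::rnorm(n2[["n_pos"]], mu2)),
        rep(c(FALSE, TRUE), n2))
      rocs_diff_test(s1, s2, B = B)$p_value
    }, numeric(1))
  })
  tibble::tibble(
    mu1 = mu1, mu2 = mu2,
    n1_total = n1_total, n2_total = n2_total,
    ratio1 = ratio1, ratio2 = ratio2,
    reps = as.integer(reps), B = as.integer(B), alpha = alpha,
    rejection_rate = mean(p_values < alpha),
    p_values = list(p_values)
  )
}
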