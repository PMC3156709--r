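# Binomial proportion statistics used to interpret identification success:
# Wilson score intervals, the averaged-endpoint arcsine transform,
# Tukey-type multiple comparisons of proportions, and Fleiss' kappa.

#' Wilson score confidence interval for a binomial proportion
#'
#' The score-test (Wilson) interval, computed via
#' [stats::prop.test()] without continuity correction (whose confidence
#' interval is exactly the Wilson interval). Vectorized over `k` and `n`.
#'
#' @param k Number of successes.
#' @param n Number of trials (`n >= 1`).
#' @param conf Confidence level (default 0.95).
#' @return A tibble with columns `k`, `n`, `estimate`, `ci_low`, `ci_high`.
#' @examples
#' wilson_ci(0, 10)   # upper limit z^2 / (n + z^2) ~ 0.2775
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (any(n < 1L)) abort("n must be >= 1", class = "bronx_param_error")
  if (any(k < 0L | k > n)) {
    abort("k must lie in [0, n]", class = "bronx_param_error")
  }
  ci <- mapply(function(k, n) {
    # the chi-squared small-count warning concerns the test, not the interval
    suppressWarnings(
      prop.test(k, n, conf.level = conf, correct = FALSE)$conf.int
    )
  }, k, n)
  tibble::tibble(k = k, n = n, estimate = k / n,
                 ci_low = ci[1, ], ci_high = ci[2, ])
}

#' Averaged-endpoint arcsine transform of a proportion
#'
#' The variance-stabilizing transform
#' `p' = (asin(sqrt(k / (n + 1))) + asin(sqrt((k + 1) / (n + 1)))) / 2`,
#' whose `+1` denominators keep the transform strictly interior even at
#' `k = 0` or `k = n`. In degrees (the default) the transformed proportion
#' has approximate variance `820.7 / (n + 0.5)`, the constant used by the
#' Tukey-type comparison.
#'
#' @param k Successes; @param n Trials (`n >= 1`). Vectorized.
#' @param degrees Return degrees (default) rather than radians.
#' @return Numeric vector of transformed proportions.
#' @export
arcsin_transform <- function(k, n, degrees = TRUE) {
  if (any(n < 1L)) abort("n must be >= 1", class = "bronx_param_error")
  if (any(k < 0L | k > n)) {
    abort("k must lie in [0, n]", class = "bronx_param_error")
  }
  p <- (asin(sqrt(k / (n + 1))) + asin(sqrt((k + 1) / (n + 1)))) / 2
  if (degrees) p * 180 / pi else p
}

#' Tukey-type multiple comparisons of binomial proportions
#'
#' Pairwise comparisons of success proportions on the arcsine scale: for
#' each pair the statistic
#' `q = |p1' - p2'| / sqrt((v1 + v2) / 2)` with `v = 820.7 / (n + 0.5)`
#' (degrees scale; `1 / (4 (n + 0.5))`-type variance is used for radians)
#' is compared against the studentized-range critical value
#' `qtukey(1 - alpha, k_groups, Inf)`.
#'
#' @param groups A data frame with columns `k` and `n`, one row per group;
#'   an optional `group` column supplies labels.
#' @param alpha Family-wise error rate (default 0.05).
#' @param degrees Work in degrees (default) or radians.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `difference` (transformed scale), `q`, `critical`, `significant`.
#' @export
tukey_proportions <- function(groups, alpha = 0.05, degrees = TRUE) {
  if (nrow(groups) < 2L) {
    abort("need at least two groups to compare", class = "bronx_param_error")
  }
  labels <- if ("group" %in% names(groups)) as.character(groups$group) else
    paste0("group", seq_len(nrow(groups)))
  p <- arcsin_transform(groups$k, groups$n, degrees = degrees)
  v <- if (degrees) 820.7 / (groups$n + 0.5) else 0.25 / (groups$n + 0.5)
  crit <- qtukey(1 - alpha, nmeans = nrow(groups), df = Inf)
  idx <- utils::combn(nrow(groups), 2L)
  diffs <- abs(p[idx[1, ]] - p[idx[2, ]])
  se <- sqrt((v[idx[1, ]] + v[idx[2, ]]) / 2)
  q <- diffs / se
  tibble::tibble(
    group1 = labels[idx[1, ]], group2 = labels[idx[2, ]],
    difference = diffs, q = q, critical = crit,
    significant = q > crit
  )
}

#' Fleiss' kappa for interrater agreement
#'
#' Chance-corrected agreement among a fixed number of raters assigning items
#' to nominal categories, from an items-by-categories count matrix with
#' constant row sums (the number of raters).
#'
#' @param ratings Integer matrix, rows = items, columns = categories,
#'   `ratings[i, j]` = number of raters placing item `i` in category `j`.
#' @return Scalar kappa (1 = perfect agreement, 0 = chance).
#' @examples
#' fleiss_kappa(rbind(c(2, 0), c(0, 2), c(1, 1)))  # 1/3
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(ratings < 0) || any(ratings != round(ratings))) {
    abort("ratings must be non-negative integer counts",
          class = "bronx_param_error")
  }
  r <- unique(rowSums(ratings))
  if (length(r) != 1L) {
    abort("all items must be rated by the same number of raters",
          class = "bronx_param_error")
  }
  if (r < 2L) abort("need at least two raters", class = "bronx_param_error")
  N <- nrow(ratings)
  p_i <- (rowSums(ratings^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(ratings) / (N * r)
  p_e <- sum(p_j^2)
  if (p_e == 1) return(1)
  (p_bar - p_e) / (1 - p_e)
}
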