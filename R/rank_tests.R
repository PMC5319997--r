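# Thin wrappers around stats::wilcox.test with the exact/approximate policy
# used throughout the package.

#' Two-sided Mann-Whitney/Wilcoxon rank-sum test
#'
#' Uses the exact null distribution when both groups have at most
#' `exact_max` values and there are no ties, and the tie-corrected normal
#' approximation (no continuity correction) otherwise. Degenerate input
#' where every value is identical returns p = 1.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @param exact_max maximum per-group size for the exact branch.
#' @return list with `statistic` (W), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all values tied)"))
  }
  ties <- anyDuplicated(pooled) > 0
  if (!ties && length(x) <= exact_max && length(y) <= exact_max) {
    ht <- stats::wilcox.test(x, y, exact = TRUE)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. The exact distribution is used when at most
#' `exact_max` nonzero differences remain and their absolute values are
#' untied; otherwise the tie-corrected normal approximation (no continuity
#' correction) is used. All-zero differences give the degenerate p = 1 with
#' a flag; fewer than `min_n` nonzero differences is an error since no
#' useful inference is possible at that size.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max maximum n for the exact branch.
#' @param min_n minimum number of nonzero differences required.
#' @return list with `statistic` (V), `p_value`, `n` (nonzero differences),
#'   `method`, `degenerate`.
#' @export
signed_rank_test <- function(d, exact_max = 25, min_n = 5) {
  if (anyNA(d)) stop("differences must not contain NA")
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(statistic = 0, p_value = 1, n = 0,
                method = "degenerate (all differences zero)",
                degenerate = TRUE))
  }
  if (length(nz) < min_n) {
    stop("fewer than ", min_n, " nonzero paired differences; ",
         "the signed-rank null is too coarse for inference at this size")
  }
  ties <- anyDuplicated(abs(nz)) > 0
  if (!ties && length(nz) <= exact_max) {
    ht <- stats::wilcox.test(nz, exact = TRUE)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(nz, exact = FALSE, correct = FALSE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(nz), method = ht$method, degenerate = FALSE)
}
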