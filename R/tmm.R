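# Trimmed mean of M-values (TMM) between-sample normalization
# (Robinson & Oshlack 2010): weighted trimmed mean of per-gene log ratios
# against a reference sample, trimming 30% on M and 5% on A, with
# delta-method (binomial) precision weights.

#' Compute TMM normalization factors
#'
#' @param counts numeric count matrix (genes x samples) or a [count_data].
#' @param reference_sample column name or index of the reference sample;
#'   by default the sample whose upper-quartile count proportion is closest
#'   to the mean upper quartile.
#' @param trim_m,trim_a two-sided trim fractions for the log-ratio (M) and
#'   average-abundance (A) values.
#' @return list of class `"norm_factors"` with `lib_size` (column sums) and
#'   `tmm_factor` (geometric mean 1). Effective library sizes are
#'   `lib_size * tmm_factor`.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), 4, 2,
#'   dimnames = list(paste0("g", 1:4), c("a", "b")))
#' tmm_factors(m)$tmm_factor  # c(1, 1): pure depth difference
tmm_factors <- function(counts, reference_sample = NULL,
                        trim_m = 0.3, trim_a = 0.05) {
  if (inherits(counts, "count_data")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib_size <- colSums(counts)
  if (any(lib_size == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib_size == 0], collapse = ", "))
  }
  if (is.null(reference_sample)) {
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib_size
    ref <- if (max(f75) < 1e-20) which.max(lib_size) else
      which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(reference_sample)) {
      match(reference_sample, colnames(counts))
    } else as.integer(reference_sample)
    if (is.na(ref) || ref < 1 || ref > ncol(counts)) {
      stop("unknown reference sample")
    }
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             trim_m, trim_a)
  }, numeric(1))
  f <- f / geometric_mean(f)
  structure(list(lib_size = lib_size,
                 tmm_factor = stats::setNames(f, colnames(counts))),
            class = "norm_factors")
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # delta-method variance of M (binomial sampling in each library)
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Normalize counts to a common effective library size
#'
#' Scales each sample's counts by `N_common / (lib_size * tmm_factor)`
#' where `N_common` is the geometric mean of effective library sizes, so
#' normalized values stay on the read-count scale.
#'
#' @param counts count matrix or [count_data].
#' @param factors a [tmm_factors()] result; computed if `NULL`.
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  if (inherits(counts, "count_data")) counts <- counts$counts
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$lib_size * factors$tmm_factor
  n_common <- geometric_mean(eff)
  sweep(counts, 2, n_common / eff, `*`)
}
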