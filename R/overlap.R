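# Hypergeometric overlap, STEM-style temporal profile clustering, and
# generic over-representation analysis over GMT collections.

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail p-value `P(X >= observed overlap)` with
#' `X ~ Hypergeometric(N = |universe|, K = |A|, n = |B|)`. Symmetric in A
#' and B.
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe background gene identifiers (non-empty).
#' @return list with `overlap`, `p_value`, and the set sizes.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, p_value = p, n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe))
}

#' Enumerate candidate temporal model profiles
#'
#' All `(2c + 1)^T` step sequences with per-step changes in `{-c, ..., c}`,
#' rendered as cumulative profiles anchored at 0 (the anchor itself is
#' implicit and not stored).
#'
#' @param c positive integer unit parameter.
#' @param T number of measured time points.
#' @return Integer matrix, one profile per row, `T` columns.
#' @export
enumerate_profiles <- function(c, T) {
  stopifnot(c >= 1, T >= 1)
  steps <- as.matrix(expand.grid(rep(list(seq(-c, c)), T),
                                 KEEP.OUT.ATTRS = FALSE))
  prof <- t(apply(steps, 1, cumsum))
  if (T == 1) prof <- matrix(prof, ncol = 1)
  dimnames(prof) <- list(NULL, NULL)
  storage.mode(prof) <- "integer"
  prof
}

# Standardize rows after prepending the implicit 0 at time 0; rows with
# zero variance return NA rows (handled by the caller).
std_rows <- function(m) {
  m0 <- cbind(0, m)
  mu <- rowMeans(m0)
  cen <- m0 - mu
  s <- sqrt(rowSums(cen^2))
  cen / ifelse(s > 0, s, NA)
}

#' Cluster temporal fold-change profiles against model profiles
#'
#' STEM-style short time-series clustering: candidate integer profiles are
#' enumerated with unit parameter `c`; `m` representative profiles are
#' chosen by greedy max-min correlation distance; every gene is assigned to
#' the representative with the highest Pearson correlation between its
#' log2 fold-change vector and the profile (both with an implicit 0 at
#' time 0). Profile significance is the permutation p-value of the
#' assigned-gene count against `n_perm` datasets in which each gene's
#' time-point order is permuted independently; empirical p-values are
#' `(b + 1)/(n_perm + 1)`.
#'
#' Genes with a constant (all-zero) fold-change vector cannot be assigned
#' by correlation and fall back to the minimum-Euclidean-distance
#' representative, flagged in the output.
#'
#' @param lfc_matrix numeric gene x timepoint matrix of log2 fold changes
#'   (rows named by gene). Restrict rows to transcripts significant in at
#'   least one time point before calling; sub-threshold fold changes at the
#'   other time points still contribute.
#' @param c unit parameter (default 2).
#' @param m number of representative profiles (default 10).
#' @param n_perm permutations for profile significance.
#' @param seed integer seed (clustering is deterministic given the seed).
#' @return list of class `"profile_clustering"`: `representatives` (m x T
#'   integer matrix), `assignments` (data frame gene / profile /
#'   correlation / fallback flag), `profile_stats` (data frame profile /
#'   n_genes / p_value / fdr), `c`, `n_perm`.
#' @export
cluster_genes <- function(lfc_matrix, c = 2, m = 10, n_perm = 1000,
                          seed = 1) {
  lfc_matrix <- as.matrix(lfc_matrix)
  T <- ncol(lfc_matrix)
  if (T < 2) stop("need at least 2 time points to cluster profiles")
  if (is.null(rownames(lfc_matrix))) {
    rownames(lfc_matrix) <- paste0("gene", seq_len(nrow(lfc_matrix)))
  }
  cand <- enumerate_profiles(c, T)
  cand <- cand[rowSums(cand != 0) > 0, , drop = FALSE]  # drop flat profile
  cand_std <- std_rows(cand)
  m <- min(m, nrow(cand))

  # distance between candidate profiles: 1 - Pearson correlation
  cor_cand <- cand_std %*% t(cand_std)
  dist_cand <- 1 - cor_cand
  # greedy max-min selection; first pick = member of the most distant pair
  # (ties broken by lowest index) for determinism
  far <- which(dist_cand == max(dist_cand), arr.ind = TRUE)
  chosen <- min(far[, 1])
  while (length(chosen) < m) {
    mind <- apply(dist_cand[, chosen, drop = FALSE], 1, min)
    mind[chosen] <- -Inf
    chosen <- c(chosen, which.max(mind))
  }
  reps <- cand[chosen, , drop = FALSE]
  rownames(reps) <- paste0("profile", seq_len(nrow(reps)))
  reps_std <- std_rows(reps)

  assign_to_reps <- function(mat) {
    g_std <- std_rows(mat)
    cors <- g_std %*% t(reps_std)
    flat <- !is.finite(g_std[, 1])
    best <- max.col(ifelse(is.na(cors), -2, cors), ties.method = "first")
    if (any(flat)) {
      # constant vectors: minimum Euclidean distance fallback
      d2 <- outer(rowSums(cbind(0, mat)^2)[flat], rowSums(cbind(0, reps)^2),
                  `+`) - 2 * cbind(0, mat)[flat, , drop = FALSE] %*%
        t(cbind(0, reps))
      best[flat] <- max.col(-d2, ties.method = "first")
    }
    list(best = best, cors = cors, flat = flat)
  }

  obs <- assign_to_reps(lfc_matrix)
  n_prof <- nrow(reps)
  obs_counts <- tabulate(obs$best, nbins = n_prof)

  with_seed(seed, {
    exceed <- integer(n_prof)
    n_genes <- nrow(lfc_matrix)
    for (b in seq_len(n_perm)) {
      perm <- lfc_matrix
      for (i in seq_len(n_genes)) perm[i, ] <- perm[i, sample.int(T)]
      cnt <- tabulate(assign_to_reps(perm)$best, nbins = n_prof)
      exceed <- exceed + (cnt >= obs_counts)
    }
    p <- (exceed + 1) / (n_perm + 1)
  })

  assignments <- data.frame(
    gene = rownames(lfc_matrix),
    profile = rownames(reps)[obs$best],
    correlation = vapply(seq_len(nrow(lfc_matrix)), function(i) {
      if (obs$flat[i]) NA_real_ else obs$cors[i, obs$best[i]]
    }, numeric(1)),
    fallback = obs$flat, row.names = NULL)
  profile_stats <- data.frame(profile = rownames(reps),
                              n_genes = obs_counts, p_value = p,
                              fdr = bh_adjust(p), row.names = NULL)
  structure(list(representatives = reps, assignments = assignments,
                 profile_stats = profile_stats, c = c, n_perm = n_perm),
            class = "profile_clustering")
}

#' Build a gene x timepoint log2 fold-change matrix from a DE table
#'
#' Keeps genes significant (per the gate already recorded in the table) at
#' one or more time points; sub-threshold fold changes at the remaining
#' time points are retained.
#'
#' @param de_long [de_analysis()] output.
#' @param fraction which fraction to use.
#' @return Numeric matrix, rows named by gene, columns by time point.
#' @export
lfc_matrix <- function(de_long, fraction = "trap") {
  tab <- de_long[de_long$fraction == fraction, ]
  tps <- sort(unique(tab$timepoint))
  keep <- unique(tab$gene[tab$significant])
  if (!length(keep)) {
    return(matrix(numeric(0), 0, length(tps),
                  dimnames = list(NULL, as.character(tps))))
  }
  m <- sapply(tps, function(tp) {
    sub <- tab[tab$timepoint == tp, ]
    sub$log2FC[match(keep, sub$gene)]
  })
  m <- matrix(m, nrow = length(keep),
              dimnames = list(keep, as.character(tps)))
  m
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param file path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Over-representation analysis of a query set against a collection
#'
#' Per category: hypergeometric upper-tail p on the overlap with the query
#' inside the universe; categories overlapping the query in fewer than
#' `min_genes` genes are excluded before testing; BH adjustment across the
#' tested categories.
#'
#' @param query_set character vector, subset of `universe`.
#' @param collections named list of gene sets (e.g. [read_gmt()]).
#' @param universe background gene identifiers.
#' @param min_genes minimum query overlap for a category to be tested.
#' @param alpha adjusted-p significance cutoff for the `significant`
#'   column.
#' @return data frame: `category`, `n_category` (within universe),
#'   `n_query`, `overlap`, `p_value`, `fdr`, `significant`; ordered by
#'   p-value.
#' @export
ora <- function(query_set, collections, universe, min_genes = 4,
                alpha = 0.05) {
  if (!length(collections)) stop("empty collection")
  universe <- unique(universe)
  query_set <- unique(intersect(query_set, universe))
  if (!all(query_set %in% universe)) stop("query must be within universe")
  rows <- lapply(names(collections), function(nm) {
    cat_genes <- intersect(unique(collections[[nm]]), universe)
    k <- length(intersect(cat_genes, query_set))
    if (k < min_genes) return(NULL)
    p <- stats::phyper(k - 1, length(cat_genes),
                       length(universe) - length(cat_genes),
                       length(query_set), lower.tail = FALSE)
    data.frame(category = nm, n_category = length(cat_genes),
               n_query = length(query_set), overlap = k, p_value = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(category = character(0), n_category = integer(0),
                      n_query = integer(0), overlap = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- res$fdr < alpha
  res[order(res$p_value), ]
}
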