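# Exact negative-binomial differential expression with a common dispersion.
#
# Counts are modelled NB with Var = mu + phi * mu^2. Library sizes are
# equalized by quantile adjustment (counts are mapped through their NB
# mid-p percentile onto a common library size), the common dispersion is
# estimated by maximizing the conditional likelihood over genes on the
# adjusted pseudo-counts, and each gene is tested with the exact
# conditional NB test on the pseudo-count group sums.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order-preserving, output in `[0, 1]`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`; `NA`/`NaN` is an
#'   error.
#' @return Vector of BH-adjusted values.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues)) stop("p-values must not contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance gate for differential expression
#'
#' Default thresholds: FDR below 0.1 and absolute log2 fold change above
#' 0.4, both strict.
#'
#' @param fdr_max FDR cutoff (gene passes iff `fdr < fdr_max`).
#' @param abs_lfc_min log2FC magnitude cutoff (`|log2FC| > abs_lfc_min`).
#' @return list of class `"significance_gate"`.
#' @export
significance_gate <- function(fdr_max = 0.1, abs_lfc_min = 0.4) {
  if (fdr_max < 0 || abs_lfc_min < 0) stop("gate thresholds must be >= 0")
  structure(list(fdr_max = fdr_max, abs_lfc_min = abs_lfc_min),
            class = "significance_gate")
}

# Quantile-adjust counts onto a common library size: each observed count is
# mapped to its NB mid-p percentile (ties between adjacent counts resolved
# by the midpoint of the point mass) under the gene/group fitted mean, then
# to the corresponding quantile at the common library size.
equalize_lib_sizes <- function(counts, groups, dispersion, eff_lib,
                               n_common = geometric_mean(eff_lib)) {
  size <- 1 / max(dispersion, 1e-8)
  pseudo <- counts
  for (g in levels(groups)) {
    j <- which(groups == g)
    y <- counts[, j, drop = FALSE]
    lambda <- rowSums(y) / sum(eff_lib[j])
    mu <- lambda %o% eff_lib[j]
    p <- stats::pnbinom(y - 1, mu = mu, size = size) +
      0.5 * stats::dnbinom(y, mu = mu, size = size)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    mu_common <- matrix(lambda * n_common, nrow(y), length(j))
    pseudo[, j] <- stats::qnbinom(p, mu = mu_common, size = size)
  }
  pseudo
}

# Conditional NB log-likelihood for a common dispersion on equal-library
# pseudo-counts, summed over genes and groups.
common_cml <- function(dispersion, pseudo, groups) {
  r <- 1 / max(dispersion, 1e-8)
  ll <- 0
  for (g in levels(groups)) {
    j <- which(groups == g)
    n <- length(j)
    if (n < 2) next
    y <- pseudo[, j, drop = FALSE]
    z <- rowSums(y)
    ll <- ll + sum(rowSums(lgamma(y + r)) + lgamma(n * r) -
                     lgamma(z + n * r) - n * lgamma(r))
  }
  ll
}

#' Estimate a common NB dispersion
#'
#' Maximizes the conditional (quantile-adjusted) likelihood over genes,
#' iterating the quantile adjustment and the maximization twice. Falls back
#' to a method-of-moments estimate if the optimization fails.
#'
#' @param counts count matrix or [count_data].
#' @param groups factor of group labels, one per sample; at least one group
#'   needs two or more replicates.
#' @param factors optional [tmm_factors()] result for effective library
#'   sizes.
#' @param interval search interval for `phi`.
#' @return Estimated dispersion `phi >= 0`.
#' @export
nb_dispersion <- function(counts, groups, factors = NULL,
                          interval = c(0, 4)) {
  if (inherits(counts, "count_data")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  groups <- droplevels(as.factor(groups))
  if (max(table(groups)) < 2) {
    stop("at least one group must have >= 2 replicates")
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$lib_size * factors$tmm_factor
  n_common <- geometric_mean(eff)

  # method-of-moments start on depth-normalized counts
  norm <- sweep(counts, 2, n_common / eff, `*`)
  resid2 <- 0
  fitted <- matrix(0, nrow(counts), ncol(counts))
  for (g in levels(groups)) {
    j <- which(groups == g)
    fitted[, j] <- rowMeans(norm[, j, drop = FALSE])
  }
  m <- rowMeans(fitted)
  df <- ncol(counts) - nlevels(groups)
  v <- rowSums((norm - fitted)^2) / max(df, 1)
  ok <- m > 1
  phi_mom <- if (any(ok)) {
    stats::median(pmax((v[ok] - m[ok]) / m[ok]^2, 0))
  } else 0
  phi_mom <- min(max(phi_mom, 0), interval[2])

  phi <- phi_mom
  est <- try({
    for (it in 1:2) {
      pseudo <- equalize_lib_sizes(counts, groups, phi, eff, n_common)
      opt <- stats::optimize(common_cml, interval = interval,
                             pseudo = pseudo, groups = groups,
                             maximum = TRUE, tol = 1e-6)
      # the optimum can sit at the Poisson boundary
      if (common_cml(0, pseudo, groups) >= opt$objective) {
        phi <- 0
        break
      }
      phi <- opt$maximum
    }
    phi
  }, silent = TRUE)
  if (inherits(est, "try-error")) return(phi_mom)
  max(est, 0)
}

# Exact conditional NB test: two-sided p for the group sum za given the
# total z, with per-sample mean z / (na + nb) and size r per sample. The
# two-sided p sums all outcomes with conditional probability at most that
# of the observed split (double-tail); for very large totals the smaller
# tail is doubled instead.
exact_nb_p <- function(za, zb, na, nb, r, enum_max = 2e5) {
  z <- za + zb
  if (z == 0) return(1)
  mu <- z / (na + nb)
  if (z <= enum_max) {
    s <- 0:z
    logp <- stats::dnbinom(s, size = na * r, mu = na * mu, log = TRUE) +
      stats::dnbinom(z - s, size = nb * r, mu = nb * mu, log = TRUE)
    logp <- logp - max(logp)
    p <- exp(logp)
    pobs <- p[za + 1]
    min(1, sum(p[p <= pobs * (1 + 1e-10)]) / sum(p))
  } else {
    lo <- stats::pnbinom(za, size = na * r, mu = na * mu)
    hi <- stats::pnbinom(za - 1, size = na * r, mu = na * mu,
                         lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }
}

#' Exact NB differential-expression test for one two-group comparison
#'
#' @param counts count matrix or [count_data] containing exactly the
#'   samples of one time point and fraction.
#' @param groups two-level factor (`control`, `LTP`); the first level is
#'   the reference, so positive log2FC means higher in the second level.
#' @param dispersion common NB dispersion (e.g. from [nb_dispersion()]).
#' @param factors optional [tmm_factors()] result; computed from `counts`
#'   if `NULL`. Effective library sizes are `lib_size * tmm_factor`.
#' @return data frame with one row per gene: `gene`, `log2FC` (normalized
#'   group means with a pseudo-count of 0.5 per mean), `pvalue`,
#'   `mean_norm_expr`, `all_zero` flag (genes absent from both groups get
#'   p = 1 and log2FC = 0).
#' @export
de_test <- function(counts, groups, dispersion, factors = NULL) {
  if (inherits(counts, "count_data")) counts <- counts$counts
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$lib_size * factors$tmm_factor
  n_common <- geometric_mean(eff)
  ja <- which(groups == levels(groups)[1])
  jb <- which(groups == levels(groups)[2])

  pseudo <- equalize_lib_sizes(counts, groups, dispersion, eff, n_common)
  za <- round(rowSums(pseudo[, ja, drop = FALSE]))
  zb <- round(rowSums(pseudo[, jb, drop = FALSE]))
  r <- 1 / max(dispersion, 1e-8)
  pvalue <- vapply(seq_len(nrow(counts)), function(i) {
    exact_nb_p(za[i], zb[i], length(ja), length(jb), r)
  }, numeric(1))

  norm <- sweep(counts, 2, n_common / eff, `*`)
  ma <- rowMeans(norm[, ja, drop = FALSE])
  mb <- rowMeans(norm[, jb, drop = FALSE])
  log2FC <- log2((mb + 0.5) / (ma + 0.5))
  all_zero <- ma == 0 & mb == 0
  log2FC[all_zero] <- 0
  pvalue[all_zero] <- 1
  data.frame(gene = rownames(counts), log2FC = log2FC, pvalue = pvalue,
             mean_norm_expr = rowMeans(norm), all_zero = all_zero,
             row.names = NULL)
}

#' Run the per-time-point, per-fraction DE analysis
#'
#' For every fraction and time point present, subsets the control and LTP
#' samples of that stratum, computes TMM factors within the stratum
#' (normalization is per time point, never across time points), estimates
#' the common dispersion, runs the exact NB test, and BH-adjusts p-values
#' within the stratum.
#'
#' @param cd a [count_data] (may hold both fractions).
#' @param gate a [significance_gate()] used to fill the `significant` and
#'   `direction` columns.
#' @param dispersion optional fixed dispersion; estimated per stratum when
#'   `NULL`.
#' @return Long data frame: `gene`, `fraction`, `timepoint`, `log2FC`,
#'   `pvalue`, `fdr`, `mean_norm_expr`, `significant`, `direction`
#'   (`"up"`/`"down"`/`NA`).
#' @export
de_analysis <- function(cd, gate = significance_gate(), dispersion = NULL) {
  stopifnot(inherits(cd, "count_data"))
  out <- list()
  for (fr in unique(cd$samples$fraction)) {
    for (tp in sort(unique(cd$samples$timepoint))) {
      sub <- subset_samples(cd, fraction = fr, timepoint = tp)
      grp <- factor(sub$samples$condition, levels = c("control", "LTP"))
      fac <- tmm_factors(sub$counts)
      phi <- dispersion %||% nb_dispersion(sub$counts, grp, factors = fac)
      tab <- de_test(sub$counts, grp, phi, factors = fac)
      tab$fdr <- bh_adjust(tab$pvalue)
      tab$fraction <- fr
      tab$timepoint <- tp
      tab$significant <- tab$fdr < gate$fdr_max &
        abs(tab$log2FC) > gate$abs_lfc_min
      tab$direction <- ifelse(!tab$significant, NA_character_,
                              ifelse(tab$log2FC > 0, "up", "down"))
      out[[length(out) + 1L]] <- tab
    }
  }
  res <- do.call(rbind, out)
  res[c("gene", "fraction", "timepoint", "log2FC", "pvalue", "fdr",
        "mean_norm_expr", "significant", "direction")]
}

#' Split a DE table into gated up/down gene sets
#'
#' A gene enters a set iff `fdr < fdr_max` and `|log2FC| > abs_lfc_min`
#' (both strict, as printed), with direction given by the sign of log2FC.
#'
#' @param table DE table with columns `gene`, `log2FC`, `fdr`, and
#'   optionally `fraction` / `timepoint` for stratified output.
#' @param gate a [significance_gate()].
#' @return If `table` has `fraction`/`timepoint` columns, a nested list
#'   `sets[[fraction]][[timepoint]]$up` / `$down`; otherwise a list with
#'   `up` and `down` character vectors.
#' @export
gate_significant <- function(table, gate = significance_gate()) {
  pick <- function(tab) {
    sig <- tab$fdr < gate$fdr_max & abs(tab$log2FC) > gate$abs_lfc_min
    list(up = tab$gene[sig & tab$log2FC > 0],
         down = tab$gene[sig & tab$log2FC < 0])
  }
  if (!all(c("fraction", "timepoint") %in% names(table))) {
    return(pick(table))
  }
  out <- list()
  for (fr in unique(table$fraction)) {
    for (tp in sort(unique(table$timepoint[table$fraction == fr]))) {
      out[[fr]][[as.character(tp)]] <-
        pick(table[table$fraction == fr & table$timepoint == tp, ])
    }
  }
  out
}

#' Write one DE table TSV per time point and fraction
#'
#' @param de_long result of [de_analysis()].
#' @param dir output directory.
#' @return Files written, invisibly.
#' @export
write_de_tables <- function(de_long, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (fr in unique(de_long$fraction)) {
    for (tp in sort(unique(de_long$timepoint[de_long$fraction == fr]))) {
      tab <- de_long[de_long$fraction == fr & de_long$timepoint == tp, ]
      f <- file.path(dir, sprintf("de_%s_%g.tsv", fr, tp))
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
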