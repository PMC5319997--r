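# RBP motif scanning and length-constrained resampling enrichment.

#' Construct an RBP motif set
#'
#' @param table data frame with columns `motif` (identifier), `rbp`
#'   (protein name) and `consensus` (IUPAC string over A/C/G/U; T is
#'   transcribed). An optional `pwms` list supplies position weight
#'   matrices (4 x L, rows A/C/G/U, columns summing to 1) keyed by motif
#'   identifier for PWM-mode scanning.
#' @param pwms optional named list of PWMs.
#' @return data frame of class `"motif_set"` with a `pwms` attribute.
#' @export
motif_set <- function(table, pwms = NULL) {
  stopifnot(all(c("motif", "rbp", "consensus") %in% names(table)))
  if (anyDuplicated(table$motif)) stop("motif identifiers must be unique")
  table$consensus <- vapply(table$consensus, validate_iupac, character(1))
  if (!is.null(pwms)) {
    for (id in names(pwms)) {
      p <- pwms[[id]]
      if (!is.matrix(p) || nrow(p) != 4 ||
          max(abs(colSums(p) - 1)) > 1e-6) {
        stop("PWM '", id, "' must be 4 x L with columns summing to 1")
      }
      rownames(pwms[[id]]) <- c("A", "C", "G", "U")
    }
  }
  structure(as.data.frame(table), pwms = pwms, class = c("motif_set",
                                                         "data.frame"))
}

#' Read a motif table TSV (motif, rbp, consensus)
#' @param file path to the TSV.
#' @return A [motif_set].
#' @export
read_motif_table <- function(file) {
  motif_set(utils::read.delim(file, comment.char = "#"))
}

#' Count motif sites in an RNA sequence
#'
#' Sliding-window count of all (possibly overlapping) positions at which
#' the IUPAC consensus matches, or, in PWM mode, at which the log-odds
#' score reaches `threshold` times the maximal attainable score.
#'
#' @param sequence RNA (or DNA; transcribed on input) character string.
#' @param motif IUPAC consensus string, or a 4 x L PWM matrix (rows
#'   A/C/G/U, columns summing to 1).
#' @param threshold PWM-mode score threshold as a fraction of the maximal
#'   log-odds score (default 0.8).
#' @return Integer site count.
#' @export
#' @examples
#' count_motif_sites("AUUUAUUUA", "AUUUA")  # 2, overlap allowed
#' count_motif_sites("UGUACAUA", "UGUAHAUA")  # 1, H = A/C/U
count_motif_sites <- function(sequence, motif, threshold = 0.8) {
  seq <- to_rna(sequence)
  bad <- setdiff(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("invalid alphabet symbol(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  if (is.matrix(motif)) {
    return(count_pwm_sites(seq, motif, threshold))
  }
  motif <- validate_iupac(motif)
  if (nchar(motif) > nchar(seq)) return(0L)
  Biostrings::countPattern(Biostrings::RNAString(motif),
                           Biostrings::RNAString(seq), fixed = FALSE)
}

count_pwm_sites <- function(seq, pwm, threshold) {
  L <- ncol(pwm)
  n <- nchar(seq)
  if (L > n) return(0L)
  logodds <- log2(pmax(pwm, 1e-6) / 0.25)
  rownames(logodds) <- c("A", "C", "G", "U")
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  max_score <- sum(apply(logodds, 2, max))
  cutoff <- threshold * max_score
  starts <- seq_len(n - L + 1L)
  scores <- vapply(starts, function(s) {
    sum(logodds[cbind(idx[s:(s + L - 1L)], seq_len(L))])
  }, numeric(1))
  sum(scores >= cutoff)
}

# Site-count matrix: genes (rows) x motifs (columns), consensus mode.
site_count_matrix <- function(seqs, motifs, pwm_mode = FALSE,
                              threshold = 0.8) {
  pwms <- attr(motifs, "pwms")
  if (pwm_mode && is.null(pwms)) stop("PWM mode requested but no PWMs supplied")
  if (pwm_mode) {
    m <- vapply(motifs$motif, function(id) {
      vapply(seqs, count_pwm_sites, integer(1), pwm = pwms[[id]],
             threshold = threshold)
    }, integer(length(seqs)))
  } else {
    ss <- Biostrings::RNAStringSet(seqs)
    m <- vapply(motifs$consensus, function(cons) {
      Biostrings::vcountPattern(Biostrings::RNAString(cons), ss,
                                fixed = FALSE)
    }, integer(length(seqs)))
  }
  m <- matrix(m, nrow = length(seqs),
              dimnames = list(names(seqs), motifs$motif))
  m
}

#' Length-constrained resampling enrichment of RBP motifs in UTRs
#'
#' Observed statistic per motif: the total number of motif sites summed
#' over the target genes' UTRs on the chosen side. The null distribution is
#' generated by resampling UTRs from the background (brain-expressed)
#' catalog: each resample draws background UTRs without replacement, in
#' random order, until the cumulative nucleotide length first reaches the
#' targets' total length L; the final (overshooting) UTR is included, so
#' every resample's total length lies in `[L, L + max background UTR
#' length)`. The empirical enrichment p-value is `(#{null >= O} + 1)/(B +
#' 1)`, mirrored for depletion, and reported two-sided as twice the smaller
#' tail, capped at 1. Fold-enrichment is the relative excess `(O - Ehat) /
#' Ehat` over the null mean.
#'
#' @param target_genes character vector of target genes (must be in the
#'   background catalog on the chosen side).
#' @param catalog background [utr_catalog] (the brain-expressed pool).
#' @param side `"utr3"` or `"utr5"`.
#' @param motifs a [motif_set].
#' @param B number of resamples (default 5000 for 3' UTRs, 1000 for 5');
#'   at least 100.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param pwm_mode scan with PWMs instead of IUPAC consensus.
#' @param threshold PWM score threshold fraction.
#' @return data frame of class `"motif_enrichment"`, one row per motif:
#'   `motif`, `rbp`, `observed`, `expected` (null mean), `fold_enrichment`,
#'   `p_enrich`, `p_deplete`, `p_value` (two-sided), `fdr` (BH across
#'   motifs, supplementary), `B`. Attribute `resample_lengths` holds each
#'   resample's total UTR length.
#' @export
resample_enrichment <- function(target_genes, catalog, side = c("utr3", "utr5"),
                                motifs, B = NULL, seed = 1,
                                pwm_mode = FALSE, threshold = 0.8) {
  side <- match.arg(side)
  if (is.null(B)) B <- if (side == "utr3") 5000L else 1000L
  if (B < 100) stop("B must be at least 100")
  seqs <- catalog_side(catalog, side)
  if (!length(seqs)) stop("background catalog has no ", side, " sequences")
  missing <- setdiff(target_genes, names(seqs))
  if (length(missing)) {
    stop("target genes absent from background catalog on ", side, ": ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  lens <- nchar(seqs)
  L <- sum(lens[target_genes])
  if (sum(lens) < L) stop("background total UTR length is below target total")

  sites <- site_count_matrix(seqs, motifs, pwm_mode = pwm_mode,
                             threshold = threshold)
  observed <- colSums(sites[target_genes, , drop = FALSE])

  with_seed(seed, {
    null_counts <- matrix(0, B, ncol(sites))
    resample_lengths <- numeric(B)
    n_bg <- length(seqs)
    for (b in seq_len(B)) {
      ord <- sample.int(n_bg)
      cum <- cumsum(lens[ord])
      k <- which(cum >= L)[1]
      sel <- ord[seq_len(k)]
      resample_lengths[b] <- cum[k]
      null_counts[b, ] <- colSums(sites[sel, , drop = FALSE])
    }
    expected <- colMeans(null_counts)
    ge <- colSums(null_counts >= rep(observed, each = B))
    le <- colSums(null_counts <= rep(observed, each = B))
    p_enrich <- (ge + 1) / (B + 1)
    p_deplete <- (le + 1) / (B + 1)
    p_value <- pmin(1, 2 * pmin(p_enrich, p_deplete))
    fe <- ifelse(expected > 0, (observed - expected) / expected, NA_real_)
    res <- data.frame(motif = motifs$motif, rbp = motifs$rbp,
                      observed = as.numeric(observed), expected = expected,
                      fold_enrichment = fe, p_enrich = p_enrich,
                      p_deplete = p_deplete, p_value = p_value,
                      fdr = bh_adjust(p_value), B = B,
                      row.names = NULL)
    attr(res, "resample_lengths") <- resample_lengths
    attr(res, "target_length") <- L
    attr(res, "max_background_length") <- max(lens)
    class(res) <- c("motif_enrichment", "data.frame")
    res
  })
}

#' Select over- and under-represented motifs
#'
#' A motif is overrepresented iff `p < alpha` and fold-enrichment
#' `> fe_min`, and underrepresented iff `p < alpha` and fold-enrichment
#' `< -fe_min` (defaults p < 0.05, |FE| > 0.2; the raw two-sided p is used,
#' not the supplementary BH column).
#'
#' @param results a [resample_enrichment()] result.
#' @param alpha raw p-value cutoff.
#' @param fe_min fold-enrichment magnitude cutoff.
#' @return list with data-frame elements `overrepresented` and
#'   `underrepresented`.
#' @export
significant_motifs <- function(results, alpha = 0.05, fe_min = 0.2) {
  if (nrow(results) == 0) {
    return(list(overrepresented = results, underrepresented = results))
  }
  fe <- results$fold_enrichment
  sig <- results$p_value < alpha & !is.na(fe)
  list(overrepresented = results[sig & fe > fe_min, , drop = FALSE],
       underrepresented = results[sig & fe < -fe_min, , drop = FALSE])
}
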