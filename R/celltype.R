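# Cell-type enrichment scoring and the paired TRAP-vs-RNA magnitude
# comparison for neuron-enriched transcripts.

#' Per-gene cell-type enrichment factor
#'
#' `E_c = FPKM_c / sum(FPKM of all other cell types)`, with the denominator
#' floored at `floor_fpkm` (flagged) to avoid division by zero.
#'
#' @param reference a `celltype_reference` (see
#'   [simulate_celltype_reference()]) or a gene x cell-type FPKM matrix.
#' @param celltype which cell type to score.
#' @param floor_fpkm denominator floor (FPKM).
#' @return data frame: `gene`, `factor`, `floored`.
#' @export
#' @examples
#' fpkm <- matrix(c(30, 5, 5, 5, 5), 1,
#'   dimnames = list("g1", c("astrocyte", "neuron", "oligodendrocyte",
#'                           "microglia", "endothelial")))
#' enrichment_factor(fpkm, "astrocyte")$factor  # 30 / 20 = 1.5
enrichment_factor <- function(reference, celltype, floor_fpkm = 0.1) {
  fpkm <- if (inherits(reference, "celltype_reference")) reference$fpkm
          else as.matrix(reference)
  if (ncol(fpkm) < 2) stop("need at least 2 cell types")
  if (!celltype %in% colnames(fpkm)) stop("unknown cell type: ", celltype)
  if (any(fpkm < 0)) stop("FPKM must be >= 0")
  num <- fpkm[, celltype]
  den <- rowSums(fpkm[, setdiff(colnames(fpkm), celltype), drop = FALSE])
  floored <- den < floor_fpkm
  data.frame(gene = rownames(fpkm), factor = num / pmax(den, floor_fpkm),
             floored = floored, row.names = NULL)
}

#' Assign DE transcripts to enriched cell types
#'
#' A gene is counted for cell type `c` iff (1) its enrichment factor
#' `E_c >= cutoff` and (2) it is differentially expressed (in the supplied
#' DE sets, normally the total-RNA fraction gated at FDR < 0.1 and
#' |log2FC| > 0.4). Genes meeting the cutoff for no cell type are
#' `"unassigned"`; genes meeting it for several are assigned to the
#' max-factor type and flagged ambiguous.
#'
#' @param de_genes character vector of DE genes (union across time
#'   points), or a list of per-time-point gene vectors to be unioned.
#' @param reference `celltype_reference` or FPKM matrix.
#' @param cutoff enrichment-factor cutoff (inclusive).
#' @param floor_fpkm see [enrichment_factor()].
#' @return list with `assignments` (data frame gene / celltype /
#'   factor / ambiguous) and `counts` (named integer vector per cell type,
#'   plus `"unassigned"`).
#' @export
assign_celltype_de <- function(de_genes, reference, cutoff = 1.5,
                               floor_fpkm = 0.1) {
  if (is.list(de_genes)) de_genes <- unique(unlist(de_genes))
  fpkm <- if (inherits(reference, "celltype_reference")) reference$fpkm
          else as.matrix(reference)
  de_genes <- unique(de_genes)
  present <- intersect(de_genes, rownames(fpkm))
  types <- colnames(fpkm)
  if (!length(present)) {
    assignments <- data.frame(gene = character(0), celltype = character(0),
                              factor = numeric(0), ambiguous = logical(0))
    counts <- stats::setNames(rep(0L, length(types) + 1L),
                              c(types, "unassigned"))
    return(list(assignments = assignments, counts = counts))
  }
  E <- sapply(types, function(ct) {
    ef <- enrichment_factor(fpkm, ct, floor_fpkm)
    ef$factor[match(present, ef$gene)]
  })
  E <- matrix(E, nrow = length(present), dimnames = list(present, types))
  hits <- E >= cutoff
  n_hit <- rowSums(hits)
  best <- ifelse(n_hit == 0, "unassigned",
                 types[max.col(E, ties.method = "first")])
  assignments <- data.frame(
    gene = present, celltype = best,
    factor = ifelse(n_hit == 0, NA_real_,
                    E[cbind(seq_along(present),
                            max.col(E, ties.method = "first"))]),
    ambiguous = n_hit > 1, row.names = NULL)
  counts <- vapply(c(types, "unassigned"), function(ct) {
    sum(assignments$celltype == ct)
  }, integer(1))
  list(assignments = assignments, counts = counts)
}

#' Identify neuron-enriched transcripts from basal TRAP/RNA ratios
#'
#' For each gene, the neuron-enrichment ratio is the mean normalized basal
#' (control) TRAP count across all samples from all time points divided by
#' the corresponding mean for total RNA. A gene is neuron-enriched iff the
#' ratio is at least `ratio_cutoff` and both basal means are at least
#' `min_reads` (the read floor guards against inflated ratios at low
#' counts and is applied to both fractions). Genes with a zero RNA mean
#' have an undefined ratio and are excluded with a flag.
#'
#' @param basal_trap,basal_rna matrices of normalized basal counts
#'   (control samples only, matched gene universes), or [count_data]
#'   objects from which control samples are taken and TMM-normalized to a
#'   common library size.
#' @param ratio_cutoff enrichment-ratio cutoff (inclusive).
#' @param min_reads minimum normalized basal mean in both fractions.
#' @return data frame: `gene`, `trap_mean`, `rna_mean`, `ratio`,
#'   `neuron_enriched`, `undefined_ratio`.
#' @export
neuron_enriched_genes <- function(basal_trap, basal_rna, ratio_cutoff = 1.5,
                                  min_reads = 10) {
  as_basal_matrix <- function(x) {
    if (inherits(x, "count_data")) {
      x <- subset_samples(x, condition = "control")
      normalize_counts(x$counts)
    } else as.matrix(x)
  }
  trap <- as_basal_matrix(basal_trap)
  rna <- as_basal_matrix(basal_rna)
  genes <- intersect(rownames(trap), rownames(rna))
  if (!length(genes)) stop("no shared genes between fractions")
  trap_mean <- rowMeans(trap[genes, , drop = FALSE])
  rna_mean <- rowMeans(rna[genes, , drop = FALSE])
  undefined <- rna_mean == 0
  ratio <- ifelse(undefined, NA_real_, trap_mean / rna_mean)
  enriched <- !undefined & ratio >= ratio_cutoff &
    trap_mean >= min_reads & rna_mean >= min_reads
  data.frame(gene = genes, trap_mean = trap_mean, rna_mean = rna_mean,
             ratio = ratio, neuron_enriched = enriched,
             undefined_ratio = undefined, row.names = NULL)
}

#' Average log2 fold changes over the time points at which a gene is DE
#'
#' The time points are those at which the transcript passes the TRAP-seq
#' gate (the `significant` column of the TRAP rows); the same time-point
#' set is used to average the other fraction's fold changes so that the
#' TRAP and RNA values are paired.
#'
#' @param de_long [de_analysis()] output containing both fractions.
#' @param gene gene identifier; must be DE (TRAP gate) at >= 1 time point.
#' @param gating_fraction fraction whose gate defines the DE time points.
#' @return list: `timepoints`, and the averaged `log2FC` per fraction
#'   (named numeric).
#' @export
#' @examples
#' # DE at 60 (log2FC 0.6) and 120 min (1.0) -> averaged TRAP log2FC 0.8
average_de_lfc <- function(de_long, gene, gating_fraction = "trap") {
  rows <- de_long[de_long$gene == gene, ]
  if (!nrow(rows)) stop("gene not present in DE table: ", gene)
  gating <- rows[rows$fraction == gating_fraction, ]
  tps <- gating$timepoint[gating$significant]
  if (!length(tps)) {
    stop("gene ", gene, " is not DE at any time point by the ",
         gating_fraction, " gate")
  }
  lfc <- vapply(unique(rows$fraction), function(fr) {
    sub <- rows[rows$fraction == fr & rows$timepoint %in% tps, ]
    mean(sub$log2FC)
  }, numeric(1))
  list(timepoints = sort(tps), log2FC = lfc)
}

#' Paired comparison of TRAP vs RNA fold-change magnitudes
#'
#' Wilcoxon signed-rank test on paired log2 fold-change differences. Each
#' pair is oriented by the sign of its TRAP value so that up- and
#' downregulated genes both contribute "TRAP magnitude minus RNA
#' magnitude"; a positive location then means greater magnitudes at the
#' ribosome-association level. Zero differences are dropped; the exact
#' distribution is used for n <= 25 without ties, a tie-corrected normal
#' approximation otherwise. All-zero differences give the degenerate
#' p = 1 with a flag; fewer than 5 usable pairs is an error.
#'
#' @param trap_lfcs,rna_lfcs equal-length paired numeric vectors (one pair
#'   per neuron-enriched DE gene, usually averaged via
#'   [average_de_lfc()]).
#' @return list: `statistic` (V), `p_value`, `n`, `median_difference`
#'   (oriented TRAP minus RNA), `degenerate`, `method`.
#' @export
paired_magnitude_test <- function(trap_lfcs, rna_lfcs) {
  if (length(trap_lfcs) != length(rna_lfcs)) {
    stop("paired vectors must have equal length")
  }
  s <- ifelse(trap_lfcs < 0, -1, 1)
  d <- s * trap_lfcs - s * rna_lfcs
  ht <- signed_rank_test(d)
  c(ht[c("statistic", "p_value", "n")],
    list(median_difference = stats::median(d), degenerate = ht$degenerate,
         method = ht$method))
}
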