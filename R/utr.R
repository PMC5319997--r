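# UTR catalog: per-gene averaged 5'/3' UTR lengths and sequences.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

validate_iupac <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0) {
    stop("motif must be a single non-empty string")
  }
  motif <- to_rna(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC_RNA))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ", "))
  }
  motif
}

# Resolve each ambiguity code to a uniformly drawn concrete base.
instantiate_iupac <- function(motif) {
  chars <- strsplit(to_rna(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_RNA[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# Transcribe DNA to RNA (T -> U) and uppercase.
to_rna <- function(x) chartr("t", "u", chartr("T", "U", toupper(x)))

#' Average isoform UTR lengths into a per-gene catalog
#'
#' When a gene has multiple annotated UTR isoforms, the per-gene length is
#' the arithmetic mean of the isoform lengths. Genes lacking an annotation
#' on one side are flagged missing for that side and excluded from analyses
#' of that side.
#'
#' @param isoforms data frame with columns `gene`, `side` (`"utr5"` /
#'   `"utr3"`) and `length` (nt, non-negative); a `transcript` column is
#'   allowed and ignored.
#' @return data frame with one row per gene and columns `gene`, `utr5_len`,
#'   `utr3_len` (`NA` where missing).
#' @export
#' @examples
#' iso <- data.frame(gene = "a", side = "utr3", length = c(300, 500))
#' average_utr_lengths(iso)$utr3_len  # 400
average_utr_lengths <- function(isoforms) {
  stopifnot(all(c("gene", "side", "length") %in% names(isoforms)))
  if (any(isoforms$length < 0)) stop("UTR lengths must be non-negative")
  if (!all(isoforms$side %in% c("utr5", "utr3"))) {
    stop("side must be 'utr5' or 'utr3'")
  }
  genes <- unique(isoforms$gene)
  avg <- function(side) {
    sub <- isoforms[isoforms$side == side, , drop = FALSE]
    m <- tapply(sub$length, sub$gene, mean)
    as.numeric(m[genes])
  }
  data.frame(gene = genes, utr5_len = avg("utr5"), utr3_len = avg("utr3"),
             stringsAsFactors = FALSE)
}

#' Construct a UTR catalog
#'
#' @param isoforms isoform-level length table (see [average_utr_lengths()]).
#' @param seq5,seq3 named character vectors of per-gene RNA sequences
#'   (names are gene identifiers); DNA is transcribed on input.
#' @param plants optional record of planted motifs (simulator bookkeeping).
#' @return An object of class `"utr_catalog"`: list with `lengths` (per-gene
#'   averaged), `isoforms`, `seq5`, `seq3`, `plants`.
#' @export
utr_catalog <- function(isoforms, seq5 = character(0), seq3 = character(0),
                        plants = NULL) {
  lengths <- average_utr_lengths(isoforms)
  seq5 <- vapply(seq5, to_rna, character(1))
  seq3 <- vapply(seq3, to_rna, character(1))
  structure(list(lengths = lengths, isoforms = isoforms,
                 seq5 = seq5, seq3 = seq3, plants = plants),
            class = "utr_catalog")
}

#' @export
print.utr_catalog <- function(x, ...) {
  cat(sprintf("utr_catalog: %d genes (%d with 5' UTR, %d with 3' UTR)\n",
              nrow(x$lengths), sum(!is.na(x$lengths$utr5_len)),
              sum(!is.na(x$lengths$utr3_len))))
  invisible(x)
}

catalog_side <- function(catalog, side) {
  side <- match.arg(side, c("utr5", "utr3"))
  if (side == "utr5") catalog$seq5 else catalog$seq3
}

#' Write a UTR catalog to FASTA + TSV
#'
#' Sequences go to a single FASTA with headers `gene|utr5` / `gene|utr3`;
#' averaged lengths go to a TSV.
#'
#' @param catalog a [utr_catalog].
#' @param dir output directory.
#' @return Files written, invisibly.
#' @export
write_utr_catalog <- function(catalog, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "utr_sequences.fasta")
  seqs <- c(catalog$seq5, catalog$seq3)
  names(seqs) <- c(paste0(names(catalog$seq5), "|utr5"),
                   paste0(names(catalog$seq3), "|utr3"))
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), fa)
  lf <- file.path(dir, "utr_lengths.tsv")
  utils::write.table(catalog$lengths, lf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, lf))
}

#' Read a UTR catalog from FASTA + length TSV
#'
#' @param fasta_file FASTA with `gene|utr5` / `gene|utr3` headers.
#' @param lengths_file isoform or per-gene length TSV with columns `gene`,
#'   `side`, `length` (isoform-level) to be averaged.
#' @return A [utr_catalog].
#' @export
read_utr_catalog <- function(fasta_file, lengths_file) {
  ss <- Biostrings::readRNAStringSet(fasta_file)
  nm <- names(ss)
  gene <- sub("\\|utr[35]$", "", nm)
  side <- sub("^.*\\|", "", nm)
  seqs <- as.character(ss)
  iso <- utils::read.delim(lengths_file, comment.char = "#")
  if (!"side" %in% names(iso)) {
    # per-gene wide table: convert to isoform-level long form
    iso <- rbind(
      data.frame(gene = iso$gene, side = "utr5", length = iso$utr5_len),
      data.frame(gene = iso$gene, side = "utr3", length = iso$utr3_len))
    iso <- iso[!is.na(iso$length), ]
  }
  utr_catalog(iso, seq5 = stats::setNames(seqs[side == "utr5"],
                                          gene[side == "utr5"]),
              seq3 = stats::setNames(seqs[side == "utr3"],
                                     gene[side == "utr3"]))
}

#' Compare UTR length distributions between regulated gene sets
#'
#' Runs two-sided rank-sum tests (exact when both groups have at most 10
#' values and no ties, tie-corrected normal approximation otherwise) for all
#' three pairwise comparisons: up vs down, up vs background, down vs
#' background.
#'
#' @param up_lengths,down_lengths,background_lengths numeric vectors of UTR
#'   lengths (nt), each with at least 2 values.
#' @return data frame with columns `comparison`, `n1`, `n2`, `statistic`,
#'   `p_value`.
#' @export
compare_utr_lengths <- function(up_lengths, down_lengths,
                                background_lengths) {
  groups <- list(up = up_lengths, down = down_lengths,
                 background = background_lengths)
  for (nm in names(groups)) {
    g <- groups[[nm]][!is.na(groups[[nm]])]
    if (length(g) < 2) stop("fewer than 2 values in group '", nm, "'")
    groups[[nm]] <- g
  }
  pairs <- list(c("up", "down"), c("up", "background"),
                c("down", "background"))
  rows <- lapply(pairs, function(p) {
    ht <- rank_sum_test(groups[[p[1]]], groups[[p[2]]])
    data.frame(comparison = paste(p, collapse = "_vs_"),
               n1 = length(groups[[p[1]]]), n2 = length(groups[[p[2]]]),
               statistic = ht$statistic, p_value = ht$p_value)
  })
  do.call(rbind, rows)
}
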