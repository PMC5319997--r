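# End-to-end orchestration: simulate -> DE -> overlap/cluster/ORA ->
# UTR/RBP -> cell type, with deterministic per-stage seeding and a
# serialized run report.

#' Pipeline configuration
#'
#' Aggregates the stage parameters and printed thresholds: the DE gate
#' (FDR < 0.1, |log2FC| > 0.4), the TRAP background rule (mean >= 20
#' normalized reads), resample counts (5000 for 3' UTRs, 1000 for 5'),
#' and the cell-type cutoffs (enrichment factor 1.5, neuron ratio 1.5,
#' 10-read minimum). One master seed derives per-stage seeds by fixed
#' offsets, so stage reordering cannot change results.
#'
#' @param sim a [sim_config()] for the synthetic dataset.
#' @param gate a [significance_gate()].
#' @param background_min_reads minimum mean normalized TRAP read count for
#'   the background universe (inclusive).
#' @param resamples_utr3,resamples_utr5 motif-enrichment resample counts.
#' @param cluster_c,cluster_m,cluster_n_perm profile-clustering settings.
#' @param celltype_cutoff,neuron_ratio_cutoff,min_reads cell-type stage
#'   cutoffs.
#' @param motifs optional [motif_set()] for the RBP stage (skipped when
#'   `NULL`).
#' @param collections optional named list of gene sets for ORA (skipped
#'   when `NULL`).
#' @param utr_plants plant specs forwarded to [utr_sim_config()].
#' @param seed master seed.
#' @param out_dir output directory for TSV/JSON artifacts.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            gate = significance_gate(),
                            background_min_reads = 20,
                            resamples_utr3 = 5000, resamples_utr5 = 1000,
                            cluster_c = 2, cluster_m = 10,
                            cluster_n_perm = 1000,
                            celltype_cutoff = 1.5,
                            neuron_ratio_cutoff = 1.5, min_reads = 10,
                            motifs = NULL, collections = NULL,
                            utr_plants = list(), seed = 1,
                            out_dir = tempfile("trapLTP_run_")) {
  stopifnot(background_min_reads >= 0, resamples_utr3 >= 100,
            resamples_utr5 >= 100, celltype_cutoff >= 0,
            neuron_ratio_cutoff >= 0, min_reads >= 0,
            seed == round(seed))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Background transcript universe from normalized counts
#'
#' Genes whose mean normalized count across all samples of the stated
#' fraction is at least `min_norm_reads` (inclusive).
#'
#' @param norm_counts matrix of normalized counts (e.g.
#'   [normalize_counts()] of the TRAP samples), or a [count_data] to be
#'   normalized.
#' @param min_norm_reads threshold (default 20).
#' @return Character vector of background gene identifiers.
#' @export
build_background <- function(norm_counts, min_norm_reads = 20) {
  if (inherits(norm_counts, "count_data")) {
    norm_counts <- normalize_counts(norm_counts$counts)
  }
  if (!nrow(norm_counts) || !ncol(norm_counts)) return(character(0))
  rownames(norm_counts)[rowMeans(norm_counts) >= min_norm_reads]
}

write_tsv <- function(df, file, params = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("# %s=%s", names(params), unlist(params)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Stages in dependency order: simulation (counts, UTR catalog, cell-type
#' reference), per-stratum DE with gating, background construction,
#' hypergeometric overlaps (between time points and between fractions),
#' temporal profile clustering, ORA (if collections are supplied),
#' UTR-length comparison and motif resampling (if motifs are supplied),
#' and cell-type scoring with the paired TRAP-vs-RNA magnitude test. All
#' tabular outputs are written under `config$out_dir`; a run report (with
#' parameter echo, per-output row counts and md5 digests) is serialized to
#' `report.json`. A stage failure writes a `FAILED_<stage>` marker file
#' and aborts with the failing stage named; outputs from completed stages
#' are retained.
#'
#' @param config a [pipeline_config()].
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(list.files(config$out_dir, pattern = "^FAILED_",
                    full.names = TRUE))
  report <- list(parameters = list(
    gate = unclass(config$gate),
    background_min_reads = config$background_min_reads,
    resamples = c(utr3 = config$resamples_utr3,
                  utr5 = config$resamples_utr5),
    celltype = c(cutoff = config$celltype_cutoff,
                 ratio = config$neuron_ratio_cutoff,
                 min_reads = config$min_reads),
    seed = config$seed, sim = unclass(config$sim)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(config$out_dir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate -------------------------------------------------------
  sim <- stage("simulate", {
    sc <- config$sim
    sc$seed <- stage_seed(config$seed, 1)
    sim <- simulate_counts(sc)
    genes <- rownames(sim$trap$counts)
    uc <- utr_sim_config(genes, plants = config$utr_plants,
                         seed = stage_seed(config$seed, 2))
    catalog <- simulate_utr_catalog(uc)
    reference <- simulate_celltype_reference(
      genes, seed = stage_seed(config$seed, 3))
    write_simulation(sim, catalog, reference, sc, config$out_dir)
    list(sim = sim, catalog = catalog, reference = reference)
  })

  combined <- count_data(cbind(sim$sim$trap$counts, sim$sim$total$counts),
                         rbind(sim$sim$trap$samples,
                               sim$sim$total$samples))

  # --- differential expression ---------------------------------------
  de <- stage("de", {
    de <- de_analysis(combined, gate = config$gate)
    write_de_tables(de, config$out_dir)
    de
  })
  sets <- gate_significant(de, config$gate)
  de_counts <- stats::aggregate(significant ~ fraction + timepoint,
                                de, sum)
  report$de_counts <- de_counts

  # --- background -----------------------------------------------------
  background <- stage("background", {
    build_background(normalize_counts(sim$sim$trap$counts),
                     config$background_min_reads)
  })
  report$n_background <- length(background)

  # --- overlaps -------------------------------------------------------
  report$overlaps <- stage("overlap", {
    tps <- sort(unique(de$timepoint))
    all_genes <- function(fr, tp) {
      s <- sets[[fr]][[as.character(tp)]]
      intersect(c(s$up, s$down), background)
    }
    rows <- list()
    if (length(tps) > 1 && "trap" %in% names(sets)) {
      for (i in seq_len(length(tps) - 1)) for (j in (i + 1):length(tps)) {
        ov <- overlap_test(all_genes("trap", tps[i]),
                           all_genes("trap", tps[j]), background)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = sprintf("trap_%g_vs_%g", tps[i], tps[j]),
          overlap = ov$overlap, p_value = ov$p_value)
      }
    }
    if (all(c("trap", "total") %in% names(sets))) {
      for (tp in tps) {
        ov <- overlap_test(all_genes("trap", tp), all_genes("total", tp),
                           background)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = sprintf("trap_vs_total_%g", tp),
          overlap = ov$overlap, p_value = ov$p_value)
      }
    }
    ovl <- do.call(rbind, rows)
    write_tsv(ovl, file.path(config$out_dir, "overlaps.tsv"))
    ovl
  })

  # --- temporal clustering -------------------------------------------
  clustering <- stage("cluster", {
    m <- lfc_matrix(de, "trap")
    if (nrow(m) < 2 || ncol(m) < 2) NULL else {
      cl <- cluster_genes(m, c = config$cluster_c, m = config$cluster_m,
                          n_perm = config$cluster_n_perm,
                          seed = stage_seed(config$seed, 4))
      write_tsv(cl$assignments,
                file.path(config$out_dir, "profile_assignments.tsv"),
                params = list(c = cl$c, n_perm = cl$n_perm))
      write_tsv(cl$profile_stats,
                file.path(config$out_dir, "profile_stats.tsv"))
      cl
    }
  })
  if (!is.null(clustering)) report$clusters <- clustering$profile_stats

  # --- ORA ------------------------------------------------------------
  if (!is.null(config$collections)) {
    report$ora <- stage("ora", {
      res <- list()
      for (dir_ in c("up", "down")) {
        q <- unique(unlist(lapply(sets$trap, `[[`, dir_)))
        q <- intersect(q, background)
        tab <- ora(q, config$collections, background)
        tab$query <- rep(dir_, nrow(tab))
        res[[dir_]] <- tab
      }
      out <- do.call(rbind, res)
      write_tsv(out, file.path(config$out_dir, "ora.tsv"))
      out
    })
  }

  # --- UTR lengths and RBP motifs ------------------------------------
  up_genes <- unique(unlist(lapply(sets$trap, `[[`, "up")))
  down_genes <- unique(unlist(lapply(sets$trap, `[[`, "down")))
  report$utr_lengths <- stage("utr", {
    lens <- sim$catalog$lengths
    empty <- data.frame(comparison = character(0), n1 = integer(0),
                        n2 = integer(0), statistic = numeric(0),
                        p_value = numeric(0), side = character(0))
    out <- empty
    if (length(up_genes) >= 2 && length(down_genes) >= 2) {
      rows <- list()
      for (side in c("utr5_len", "utr3_len")) {
        pick <- function(g) lens[[side]][match(g, lens$gene)]
        cmp <- compare_utr_lengths(pick(up_genes), pick(down_genes),
                                   pick(intersect(background, lens$gene)))
        cmp$side <- sub("_len", "", side)
        rows[[side]] <- cmp
      }
      out <- do.call(rbind, rows)
    }
    write_tsv(out, file.path(config$out_dir, "utr_length_tests.tsv"))
    out
  })
  if (!is.null(config$motifs)) {
    report$motifs <- stage("rbp", {
      bg_genes <- intersect(background, names(sim$catalog$seq3))
      res <- list()
      for (side in c("utr3", "utr5")) {
        pool <- intersect(background, names(catalog_side(sim$catalog, side)))
        targets <- intersect(up_genes, pool)
        if (length(targets) < 2) next
        sub <- sim$catalog
        keep <- function(s) s[intersect(names(s), pool)]
        sub$seq5 <- keep(sub$seq5)
        sub$seq3 <- keep(sub$seq3)
        B <- if (side == "utr3") config$resamples_utr3 else
          config$resamples_utr5
        enr <- resample_enrichment(targets, sub, side, config$motifs,
                                   B = B,
                                   seed = stage_seed(config$seed,
                                                     4 + match(side, c("utr3", "utr5"))))
        enr$side <- side
        write_tsv(enr, file.path(config$out_dir,
                                 sprintf("motif_enrichment_%s.tsv", side)),
                  params = list(B = B, n_targets = length(targets)))
        res[[side]] <- list(
          n_significant = nrow(significant_motifs(enr)$overrepresented),
          n_tested = nrow(enr))
      }
      res
    })
  }

  # --- cell types -----------------------------------------------------
  report$celltype <- stage("celltype", {
    rna_de <- unique(de$gene[de$fraction == "total" & de$significant])
    assign <- assign_celltype_de(rna_de, sim$reference,
                                 cutoff = config$celltype_cutoff)
    write_tsv(assign$assignments,
              file.path(config$out_dir, "celltype_assignments.tsv"))
    ne <- neuron_enriched_genes(sim$sim$trap, sim$sim$total,
                                ratio_cutoff = config$neuron_ratio_cutoff,
                                min_reads = config$min_reads)
    trap_de <- unique(de$gene[de$fraction == "trap" & de$significant])
    paired_genes <- intersect(ne$gene[ne$neuron_enriched], trap_de)
    paired <- NULL
    if (length(paired_genes) >= 5) {
      lfcs <- vapply(paired_genes, function(g) {
        a <- average_de_lfc(de, g, "trap")
        c(a$log2FC[["trap"]], a$log2FC[["total"]])
      }, numeric(2))
      paired <- paired_magnitude_test(lfcs[1, ], lfcs[2, ])
      ne_tab <- data.frame(gene = paired_genes, trap_log2FC = lfcs[1, ],
                           rna_log2FC = lfcs[2, ])
      write_tsv(ne_tab, file.path(config$out_dir,
                                  "neuron_enriched_paired_lfc.tsv"))
    }
    write_tsv(ne, file.path(config$out_dir, "neuron_enrichment.tsv"))
    list(counts = as.list(assign$counts),
         n_neuron_enriched = sum(ne$neuron_enriched),
         n_paired = length(paired_genes),
         paired_test = paired[c("statistic", "p_value", "n",
                                "median_difference")])
  })

  # --- report ---------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("report\\.json$", files)]
  report$outputs <- data.frame(
    file = basename(files),
    rows = vapply(files, function(f) {
      if (grepl("\\.tsv$", f)) {
        length(readLines(f)) - sum(grepl("^#", readLines(f))) - 1L
      } else NA_integer_
    }, integer(1)),
    md5 = unname(tools::md5sum(files)), row.names = NULL)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(report)
}
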