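test_that("identical seed and config give bit-identical fixtures", {
  a <- simulate_counts(sim_config(n_genes = 60, seed = 11))
  b <- simulate_counts(sim_config(n_genes = 60, seed = 11))
  expect_identical(a, b)
  genes <- rownames(a$trap$counts)
  uc <- utr_sim_config(genes, seed = 4, missing_utr3_rate = 0,
                       plants = list(list(motif = "AUUUA", genes = genes[1:5],
                                          side = "utr3", copies = 2)))
  expect_identical(simulate_utr_catalog(uc), simulate_utr_catalog(uc))
  expect_identical(simulate_celltype_reference(genes, seed = 5),
                   simulate_celltype_reference(genes, seed = 5))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  x <- runif(1)
  set.seed(123)
  invisible(simulate_counts(sim_config(n_genes = 20, seed = 99)))
  expect_identical(runif(1), x)
})

test_that("mixture means follow the dilution closed form", {
  # neuron mu 100, other mu 100, f = 0.5, Delta = 1, no contamination:
  # expected total fold = (0.5*200 + 0.5*100)/100 = 1.5, TRAP fold = 2
  cfg <- sim_config(n_genes = 200, n_replicates = 100, timepoints = 60,
                    neuron_fraction = 0.5, contamination = 0,
                    dispersion = 0.1, de_fraction = 1,
                    nonneuronal_de_fraction = 0, depth_sdlog = 0,
                    neuron_mu = 100, other_mu = 100,
                    effect_profiles = matrix(1, 1, 1), seed = 21)
  sim <- simulate_counts(cfg)
  lfc <- function(cd) {
    ctl <- rowMeans(cd$counts[, cd$samples$condition == "control"])
    ltp <- rowMeans(cd$counts[, cd$samples$condition == "LTP"])
    mean(log2(ltp / ctl))
  }
  expect_lt(abs(lfc(sim$total) - log2(1.5)), 0.05)
  expect_lt(abs(lfc(sim$trap) - 1), 0.05)
})

test_that("dilution attenuates total-RNA fold changes relative to TRAP", {
  sim <- small_sim(400, seed = 31, dispersion = 0.05,
                   nonneuronal_de_fraction = 0)
  de_genes <- sim$truth$de_genes
  last_tp <- max(sim$trap$samples$timepoint)
  emp_lfc <- function(cd) {
    sub <- subset_samples(cd, timepoint = last_tp)
    ctl <- rowMeans(sub$counts[de_genes, sub$samples$condition == "control"])
    ltp <- rowMeans(sub$counts[de_genes, sub$samples$condition == "LTP"])
    log2((ltp + 0.5) / (ctl + 0.5))
  }
  trap_lfc <- emp_lfc(sim$trap)
  total_lfc <- emp_lfc(sim$total)
  # per-gene magnitudes are noisy; the average attenuation must show
  expect_lt(mean(abs(total_lfc)), mean(abs(trap_lfc)))
})

test_that("config validation rejects malformed designs", {
  expect_error(sim_config(n_replicates = 2.5), "positive integer")
  expect_error(sim_config(timepoints = numeric(0)), "non-empty")
  expect_error(sim_config(timepoints = c(60, 30)), "increasing")
  expect_error(sim_config(neuron_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(dispersion = -1), ">= 0")
})

test_that("planted motifs are recovered by the scanner at the planted copy number", {
  genes <- sprintf("g%03d", 1:40)
  targets <- genes[1:10]
  uc <- utr_sim_config(genes, seed = 7, missing_utr3_rate = 0,
                       plants = list(list(motif = "AUUUA", genes = targets,
                                          side = "utr3", copies = 2)))
  cat <- simulate_utr_catalog(uc)
  for (g in targets) {
    expect_gte(count_motif_sites(cat$seq3[[g]], "AUUUA"), 2)
    expect_gte(oracle_scan(cat$seq3[[g]], "AUUUA"), 2)
  }
  expect_equal(nrow(cat$plants), 20)
  expect_true(all(cat$plants$position >= 1))
  expect_true(all(cat$plants$position + 4 <= nchar(cat$seq3[cat$plants$gene])))
})

test_that("unplanted sequences match the background composition expectation", {
  genes <- sprintf("g%03d", 1:150)
  cat <- simulate_utr_catalog(utr_sim_config(genes, seed = 13))
  total_len <- sum(nchar(cat$seq3))
  obs <- sum(vapply(cat$seq3, count_motif_sites, integer(1),
                    motif = "AUUUA"))
  p_match <- 0.27 * 0.30^3 * 0.27  # per-position probability under base_freqs
  expected <- p_match * total_len  # edge effects negligible at these lengths
  expect_lt(abs(obs - expected), 4 * sqrt(expected))
})

test_that("motif longer than the UTR is an error", {
  genes <- "g1"
  uc <- utr_sim_config(genes, utr5_meanlog = log(25), utr5_sdlog = 0,
                       missing_utr5_rate = 0, seed = 1,
                       plants = list(list(motif = strrep("A", 500),
                                          genes = "g1", side = "utr5",
                                          copies = 1)))
  expect_error(simulate_utr_catalog(uc), "longer than")
})

test_that("cell-type reference plants markers above the cutoff", {
  genes <- sprintf("g%03d", 1:100)
  ref <- simulate_celltype_reference(genes, n_markers_per_type = 4, seed = 3)
  for (ct in names(ref$markers)) {
    ef <- enrichment_factor(ref, ct)
    expect_true(all(ef$factor[match(ref$markers[[ct]], ef$gene)] >= 1.5))
  }
  expect_error(simulate_celltype_reference(genes, marker_fpkm = -5),
               ">= 0")
  expect_error(simulate_celltype_reference(genes, cell_types = "neuron"),
               "at least 2")
  # zero rows exist but are never markers
  zero_rows <- rownames(ref$fpkm)[rowSums(ref$fpkm) == 0]
  expect_false(any(zero_rows %in% unlist(ref$markers)))
})

test_that("simulation round-trips through the plain-text writers", {
  sim <- small_sim(40, seed = 17)
  genes <- rownames(sim$trap$counts)
  cat <- simulate_utr_catalog(utr_sim_config(genes, seed = 2))
  ref <- simulate_celltype_reference(genes, seed = 2)
  dir <- withr::local_tempdir()
  write_simulation(sim, cat, ref, sim_config(n_genes = 40, seed = 17), dir)
  back <- read_count_data(file.path(dir, "counts_trap.tsv"),
                          file.path(dir, "samples_trap.tsv"))
  expect_equal(back$counts, sim$trap$counts)
  expect_equal(back$samples$condition, sim$trap$samples$condition)
  cat2 <- read_utr_catalog(file.path(dir, "utr_sequences.fasta"),
                           file.path(dir, "utr_lengths.tsv"))
  expect_equal(cat2$seq3, cat$seq3)
  expect_equal(cat2$lengths$utr3_len, cat$lengths$utr3_len)
})
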