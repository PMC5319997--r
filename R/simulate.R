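#' Configuration for the synthetic TRAP/total count simulator
#'
#' The generator emulates the study design this package targets: paired
#' TRAP-seq (ribosome-associated RNA from neurons) and total RNA-seq
#' libraries, biological triplicates, control vs LTP at 30/60/120 min, and a
#' neuron/non-neuron tissue mixture. Each gene has a neuronal and a
#' non-neuronal expression component; the total-RNA signal mixes them with
#' weight `neuron_fraction`, while the TRAP signal is the neuronal component
#' plus a small `contamination` leak of the non-neuronal one. LTP effects are
#' applied to the neuronal component only, unless a gene is flagged as
#' regulated in the non-neuronal compartment. Counts are negative binomial
#' with `Var = mu + dispersion * mu^2` (the single NB convention used
#' project-wide).
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition per time point.
#' @param timepoints strictly increasing vector of minutes post induction.
#' @param neuron_fraction proportion `f` of the total-RNA signal contributed
#'   by neurons.
#' @param contamination proportion `eps` of non-neuronal signal leaking into
#'   the TRAP fraction (imperfect de-enrichment).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for per-gene
#'   baseline means (heavy-tailed expression, mimicking RNA-seq dynamic
#'   range over expressed genes).
#' @param dispersion NB dispersion `phi >= 0` (0 gives Poisson counts).
#' @param de_fraction proportion of genes differentially expressed.
#' @param de_lfc magnitude of the peak true neuronal log2 effect for DE
#'   genes.
#' @param nonneuronal_de_fraction proportion of DE genes whose regulation is
#'   placed in the non-neuronal compartment instead.
#' @param depth_sdlog log-normal sd of per-sample sequencing-depth factors.
#' @param neuron_mu,other_mu optional explicit per-gene mean vectors
#'   overriding the log-normal draw (recycled to `n_genes`).
#' @param effect_profiles optional matrix (DE genes x timepoints) of true
#'   log2 effects; by default profiles are sampled from ramp / late-onset /
#'   early-transient / sustained templates scaled to `de_lfc`, half up and
#'   half down.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_replicates = 3,
                       timepoints = c(30, 60, 120),
                       neuron_fraction = 0.5, contamination = 0.02,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.1, de_fraction = 0.1, de_lfc = 1,
                       nonneuronal_de_fraction = 0.1, depth_sdlog = 0.1,
                       neuron_mu = NULL, other_mu = NULL,
                       effect_profiles = NULL, seed = 1) {
  if (n_replicates != round(n_replicates) || n_replicates < 1) {
    stop("'n_replicates' must be a positive integer")
  }
  if (length(timepoints) < 1) stop("'timepoints' must be non-empty")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("'timepoints' must be strictly increasing")
  }
  check_proportion(neuron_fraction, "neuron_fraction")
  check_proportion(contamination, "contamination")
  check_proportion(de_fraction, "de_fraction")
  check_proportion(nonneuronal_de_fraction, "nonneuronal_de_fraction")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    timepoints = as.numeric(timepoints), neuron_fraction = neuron_fraction,
    contamination = contamination, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, dispersion = dispersion,
    de_fraction = de_fraction, de_lfc = de_lfc,
    nonneuronal_de_fraction = nonneuronal_de_fraction,
    depth_sdlog = depth_sdlog, neuron_mu = neuron_mu, other_mu = other_mu,
    effect_profiles = effect_profiles, seed = seed), class = "sim_config")
}

# Temporal effect-shape templates on [0, 1], evaluated at T timepoints.
effect_templates <- function(T) {
  half <- ceiling(T / 2)
  list(
    ramp = seq_len(T) / T,
    late = if (T > 1) pmax(0, (seq_len(T) - half) / max(1, T - half)) else 1,
    early = rev(seq_len(T)) / T,
    sustained = rep(1, T)
  )
}

#' Simulate paired TRAP and total RNA count matrices with ground truth
#'
#' @param config a [sim_config()].
#' @return A list with elements `trap` and `total` (both [count_data]) and
#'   `truth`, a list holding the per-gene true log2 effect matrix `delta`
#'   (genes x timepoints; zero for non-DE genes), the logical `is_de`
#'   matrix, the DE gene identifiers, the regulated compartment per DE gene
#'   (`"neuron"` or `"non-neuron"`), and the neuronal / non-neuronal mean
#'   vectors.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' dim(sim$trap$counts)
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    T <- length(config$timepoints)
    genes <- sprintf("g%04d", seq_len(G))

    neuron_mu <- config$neuron_mu %||%
      stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    other_mu <- config$other_mu %||%
      stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    neuron_mu <- rep_len(neuron_mu, G)
    other_mu <- rep_len(other_mu, G)

    n_de <- round(config$de_fraction * G)
    de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
    delta <- matrix(0, G, T, dimnames = list(genes, config$timepoints))
    if (n_de > 0) {
      if (!is.null(config$effect_profiles)) {
        prof <- config$effect_profiles
        if (ncol(prof) != T) stop("effect_profiles must have one column per timepoint")
        delta[de_idx, ] <- prof[rep_len(seq_len(nrow(prof)), n_de), , drop = FALSE]
      } else {
        tmpl <- effect_templates(T)
        shape <- sample(length(tmpl), n_de, replace = TRUE)
        sign <- rep_len(c(1, -1), n_de)[sample.int(n_de)]
        for (i in seq_len(n_de)) {
          delta[de_idx[i], ] <- sign[i] * config$de_lfc * tmpl[[shape[i]]]
        }
      }
    }
    compartment <- rep(NA_character_, G)
    if (n_de > 0) {
      n_nn <- round(config$nonneuronal_de_fraction * n_de)
      nn <- if (n_nn > 0) sample(de_idx, n_nn) else integer(0)
      compartment[de_idx] <- "neuron"
      compartment[nn] <- "non-neuron"
    }

    build <- function(fraction) {
      meta <- expand.grid(replicate = seq_len(config$n_replicates),
                          condition = c("control", "LTP"),
                          timepoint = config$timepoints,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      meta$fraction <- fraction
      meta$sample <- sprintf("%s_%s_%g_r%d", fraction, meta$condition,
                             meta$timepoint, meta$replicate)
      counts <- matrix(0, G, nrow(meta), dimnames = list(genes, meta$sample))
      for (j in seq_len(nrow(meta))) {
        t_idx <- match(meta$timepoint[j], config$timepoints)
        ltp <- meta$condition[j] == "LTP"
        eff <- if (ltp) delta[, t_idx] else rep(0, G)
        mu_n <- neuron_mu
        mu_o <- other_mu
        neuronal_reg <- !is.na(compartment) & compartment == "neuron"
        nonneuronal_reg <- !is.na(compartment) & compartment == "non-neuron"
        mu_n[neuronal_reg] <- mu_n[neuronal_reg] * 2^eff[neuronal_reg]
        mu_o[nonneuronal_reg] <- mu_o[nonneuronal_reg] * 2^eff[nonneuronal_reg]
        depth <- stats::rlnorm(1, 0, config$depth_sdlog)
        mu <- if (fraction == "trap") {
          mu_n + config$contamination * mu_o
        } else {
          config$neuron_fraction * mu_n + (1 - config$neuron_fraction) * mu_o
        }
        mu <- mu * depth
        counts[, j] <- if (config$dispersion > 0) {
          stats::rnbinom(G, mu = mu, size = 1 / config$dispersion)
        } else {
          stats::rpois(G, mu)
        }
      }
      count_data(counts, meta[c("sample", "fraction", "condition",
                                "timepoint", "replicate")])
    }

    trap <- build("trap")
    total <- build("total")
    truth <- list(delta = delta, is_de = delta != 0,
                  de_genes = genes[de_idx],
                  compartment = stats::setNames(compartment, genes),
                  neuron_mu = stats::setNames(neuron_mu, genes),
                  other_mu = stats::setNames(other_mu, genes))
    list(trap = trap, total = total, truth = truth)
  })
}

#' Configuration for the synthetic UTR catalog
#'
#' UTR lengths are log-normal (3' UTRs several-fold longer than 5' UTRs, as
#' in mammalian annotation), sequences are i.i.d. draws from a slightly
#' AU-rich background, and RBP motifs can be planted into designated target
#' genes at a fixed copy number. Planting replaces the substring at a
#' uniformly chosen non-overlapping position so the UTR length is unchanged.
#' Sequences use the RNA alphabet (A, C, G, U); DNA input to scanning
#' functions is transcribed on read.
#'
#' @param genes character vector of gene identifiers.
#' @param utr5_meanlog,utr5_sdlog,utr3_meanlog,utr3_sdlog log-normal length
#'   parameters (nt).
#' @param base_freqs named numeric vector of A/C/G/U background frequencies
#'   summing to 1.
#' @param max_isoforms isoform count per gene is uniform on
#'   `1:max_isoforms`; the catalog stores the per-gene average length.
#' @param isoform_cv log-normal coefficient of variation of isoform lengths
#'   around the gene's base length.
#' @param missing_utr5_rate,missing_utr3_rate proportion of genes lacking an
#'   annotation on that side.
#' @param plants list of plant specs, each a list with elements `motif`
#'   (IUPAC consensus over ACGU), `genes` (targets), `side` (`"utr5"` or
#'   `"utr3"`), `copies` (per-UTR copy number).
#' @param seed integer seed.
#' @return A list of class `"utr_sim_config"`.
#' @export
utr_sim_config <- function(genes, utr5_meanlog = log(150), utr5_sdlog = 0.6,
                           utr3_meanlog = log(800), utr3_sdlog = 0.8,
                           base_freqs = c(A = 0.27, C = 0.21, G = 0.22, U = 0.30),
                           max_isoforms = 3, isoform_cv = 0.15,
                           missing_utr5_rate = 0.05, missing_utr3_rate = 0.02,
                           plants = list(), seed = 1) {
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  if (!identical(sort(names(base_freqs)), c("A", "C", "G", "U"))) {
    stop("base_freqs must be named A, C, G, U")
  }
  for (p in plants) {
    validate_iupac(p$motif)
    if (!p$side %in% c("utr5", "utr3")) stop("plant side must be utr5/utr3")
  }
  structure(list(genes = as.character(genes), utr5_meanlog = utr5_meanlog,
                 utr5_sdlog = utr5_sdlog, utr3_meanlog = utr3_meanlog,
                 utr3_sdlog = utr3_sdlog, base_freqs = base_freqs,
                 max_isoforms = as.integer(max_isoforms),
                 isoform_cv = isoform_cv,
                 missing_utr5_rate = missing_utr5_rate,
                 missing_utr3_rate = missing_utr3_rate,
                 plants = plants, seed = seed),
            class = "utr_sim_config")
}

random_rna <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate a UTR catalog with optional planted motifs
#'
#' @param config a [utr_sim_config()].
#' @return A [utr_catalog] whose `plants` element records every planted
#'   motif occurrence (gene, side, motif, 1-based position).
#' @export
simulate_utr_catalog <- function(config) {
  stopifnot(inherits(config, "utr_sim_config"))
  with_seed(config$seed, {
    genes <- config$genes
    G <- length(genes)
    sides <- list(
      utr5 = list(meanlog = config$utr5_meanlog, sdlog = config$utr5_sdlog,
                  missing = config$missing_utr5_rate, floor = 20),
      utr3 = list(meanlog = config$utr3_meanlog, sdlog = config$utr3_sdlog,
                  missing = config$missing_utr3_rate, floor = 30)
    )
    iso_rows <- list()
    seqs <- list(utr5 = character(0), utr3 = character(0))
    n_iso <- sample.int(config$max_isoforms, G, replace = TRUE)
    for (side in names(sides)) {
      sp <- sides[[side]]
      present <- stats::runif(G) >= sp$missing
      base_len <- pmax(sp$floor,
                       round(stats::rlnorm(G, sp$meanlog, sp$sdlog)))
      for (g in seq_len(G)) {
        if (!present[g]) next
        lens <- pmax(sp$floor, round(base_len[g] *
                       stats::rlnorm(n_iso[g], 0, config$isoform_cv)))
        iso_rows[[length(iso_rows) + 1L]] <- data.frame(
          gene = genes[g], transcript = sprintf("%s.t%d", genes[g],
                                                seq_along(lens)),
          side = side, length = lens)
        avg <- round(mean(lens))
        seqs[[side]][genes[g]] <- random_rna(avg, config$base_freqs)
      }
    }
    isoforms <- do.call(rbind, iso_rows)

    plants <- data.frame(gene = character(0), side = character(0),
                         motif = character(0), position = integer(0))
    occupied <- list()  # per gene|side: integer positions already planted
    for (p in config$plants) {
      copies <- p$copies %||% 1L
      w <- nchar(p$motif)
      for (g in p$genes) {
        s <- seqs[[p$side]][g]
        if (is.na(s)) stop(sprintf("no %s sequence for target gene %s", p$side, g))
        if (w > nchar(s)) {
          stop(sprintf("motif '%s' longer than %s of gene %s", p$motif, p$side, g))
        }
        key <- paste(g, p$side)
        occ <- occupied[[key]] %||% integer(0)
        for (k in seq_len(copies)) {
          valid <- setdiff(seq_len(nchar(s) - w + 1L),
                           unlist(lapply(occ, function(o) (o - w + 1L):(o + w - 1L))))
          if (!length(valid)) stop("no room left to plant motif in ", g)
          pos <- if (length(valid) == 1L) valid else sample(valid, 1L)
          inst <- instantiate_iupac(p$motif)
          substr(s, pos, pos + w - 1L) <- inst
          occ <- c(occ, pos)
          plants <- rbind(plants, data.frame(gene = g, side = p$side,
                                             motif = p$motif, position = pos))
        }
        occupied[[key]] <- occ
        seqs[[p$side]][g] <- s
      }
    }
    utr_catalog(isoforms, seq5 = seqs$utr5, seq3 = seqs$utr3, plants = plants)
  })
}

#' Simulate a cell-type reference FPKM table with planted markers
#'
#' Emulates a bulk cell-type-resolved reference (neurons, astrocytes,
#' myelinating oligodendrocytes, microglia, endothelial cells). Marker genes
#' receive a high FPKM in their assigned type and a low FPKM elsewhere so
#' that they exceed the enrichment-factor cutoff by construction;
#' non-markers are near-uniform across types.
#'
#' @param genes character vector of gene identifiers.
#' @param cell_types at least two of the five canonical types.
#' @param markers named list `cell type -> gene identifiers`, or `NULL` to
#'   auto-assign `n_markers_per_type` genes per type.
#' @param n_markers_per_type markers per cell type when auto-assigning.
#' @param marker_fpkm,marker_other_fpkm FPKM of a marker in its own type and
#'   in every other type.
#' @param base_meanlog,base_sdlog log-normal parameters of non-marker base
#'   expression.
#' @param noise_sdlog log-normal jitter applied per type.
#' @param zero_rate proportion of non-marker genes set to zero FPKM in all
#'   types (unexpressed; such rows are never used for marker assignment).
#' @param seed integer seed.
#' @return A list of class `"celltype_reference"` with elements `fpkm`
#'   (gene x cell-type matrix) and `markers` (named list).
#' @export
simulate_celltype_reference <- function(genes,
    cell_types = c("neuron", "astrocyte", "oligodendrocyte", "microglia",
                   "endothelial"),
    markers = NULL, n_markers_per_type = 20, marker_fpkm = 30,
    marker_other_fpkm = 2, base_meanlog = log(5), base_sdlog = 0.5,
    noise_sdlog = 0.1, zero_rate = 0.02, seed = 1) {
  if (length(cell_types) < 2) stop("need at least 2 cell types")
  if (marker_fpkm < 0 || marker_other_fpkm < 0) stop("FPKM must be >= 0")
  with_seed(seed, {
    G <- length(genes)
    K <- length(cell_types)
    fpkm <- matrix(stats::rlnorm(G, base_meanlog, base_sdlog) *
                     stats::rlnorm(G * K, 0, noise_sdlog),
                   G, K, dimnames = list(genes, cell_types))
    if (is.null(markers)) {
      pool <- sample(genes, min(G, n_markers_per_type * K))
      markers <- split(pool, rep(cell_types,
                                 length.out = length(pool)))[cell_types]
    }
    if (!all(names(markers) %in% cell_types)) stop("unknown cell type in markers")
    marker_genes <- unlist(markers, use.names = FALSE)
    non_markers <- setdiff(genes, marker_genes)
    zeros <- sample(non_markers, round(zero_rate * length(non_markers)))
    fpkm[zeros, ] <- 0
    for (ct in names(markers)) {
      for (g in markers[[ct]]) {
        fpkm[g, ] <- marker_other_fpkm * stats::rlnorm(K, 0, noise_sdlog)
        fpkm[g, ct] <- marker_fpkm * stats::rlnorm(1, 0, noise_sdlog)
      }
    }
    structure(list(fpkm = fpkm, markers = markers),
              class = "celltype_reference")
  })
}

#' Write simulator outputs to plain-text files
#'
#' Counts and sample sheets go to TSV, UTR sequences to FASTA (headers
#' `gene|utr5` / `gene|utr3`), UTR lengths to TSV, ground truth to JSON, the
#' cell-type reference to TSV, and the configuration to YAML.
#'
#' @param sim result of [simulate_counts()].
#' @param catalog a [utr_catalog], or `NULL` to skip.
#' @param reference a `celltype_reference`, or `NULL` to skip.
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, catalog = NULL, reference = NULL,
                             config = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  for (fr in c("trap", "total")) {
    cf <- file.path(dir, paste0("counts_", fr, ".tsv"))
    sf <- file.path(dir, paste0("samples_", fr, ".tsv"))
    write_count_data(sim[[fr]], cf, sf)
    out <- c(out, cf, sf)
  }
  tf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    de_genes = sim$truth$de_genes,
    delta = as.data.frame(sim$truth$delta),
    compartment = as.list(sim$truth$compartment[sim$truth$de_genes])),
    tf, digits = NA)
  out <- c(out, tf)
  if (!is.null(catalog)) out <- c(out, write_utr_catalog(catalog, dir))
  if (!is.null(reference)) {
    rf <- file.path(dir, "celltype_reference.tsv")
    utils::write.table(data.frame(gene = rownames(reference$fpkm),
                                  reference$fpkm, check.names = FALSE),
                       rf, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, rf)
  }
  if (!is.null(config)) {
    yf <- file.path(dir, "sim_config.yaml")
    yaml::write_yaml(unclass(config), yf)
    out <- c(out, yf)
  }
  invisible(out)
}
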