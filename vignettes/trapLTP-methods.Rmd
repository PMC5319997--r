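---
title: "Methods: cell-type-specific time-course analysis of ribosome-associated expression"
author: "trapLTP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific time-course analysis of ribosome-associated expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapLTP)
```

## The problem

Late-phase long-term potentiation (L-LTP) in the hippocampus depends on new
transcription and translation inside a critical window of roughly two hours
after induction. Bulk RNA-seq of a stimulated slice mixes the neuronal
response with the transcriptomes of astrocytes, oligodendrocytes, microglia
and endothelial cells, which dilutes cell-type-restricted fold changes:
a transcript doubled in neurons but unregulated elsewhere shows a bulk
fold change of only `f * 2 + (1 - f)` where `f` is the neuronal share of
the tissue RNA. TRAP-seq (translating ribosome affinity purification from
Cre-tagged ribosomes, as in RiboTag mice) sidesteps the dilution by
sequencing the ribosome-associated RNA of one cell type.

`trapLTP` implements the complete downstream analysis for a paired
TRAP-seq / total RNA-seq time course (control vs LTP, three biological
replicates at 30, 60, 120 min): normalization, negative-binomial
differential expression with a fixed significance gate, temporal overlap
and profile clustering, UTR-length and RNA-binding-protein (RBP) motif
enrichment, and cell-type attribution, together with a synthetic-data
generator that reproduces the design with known ground truth so every
stage can be validated quantitatively.

## Count model and differential expression

Counts are modelled as negative binomial with the mean/dispersion
convention `Var = mu + phi * mu^2`, used identically everywhere in the
package (simulation, dispersion estimation, testing).

**Normalization.** Between-sample factors use the trimmed mean of M-values
(TMM): per-gene log ratios against a reference sample are trimmed 30% on
the log-ratio (M) and 5% on average abundance (A), averaged with
delta-method precision weights, and the factors are rescaled to geometric
mean 1. Effective library sizes are `library size x TMM factor`.
Normalization is computed within each time point (and fraction), never
across time points, because each time point is its own sequencing stratum.

**Dispersion.** With three replicates per condition, per-gene dispersions
are unstable, so a single common dispersion is estimated per stratum:
counts are quantile-adjusted onto a common library size (each count is
mapped through its NB mid-p percentile — the midpoint of the point mass
resolves the discreteness — onto the common-size quantile), and the
conditional likelihood summed over genes is maximized in `phi` on [0, 4],
iterating adjustment and maximization twice. A method-of-moments estimate
provides the start value and the fallback if the optimization fails. The
Poisson boundary `phi = 0` is checked explicitly.

**Testing.** Each gene is tested with the exact conditional NB test on the
quantile-adjusted group sums: given the total pseudo-count `z`, the
two-sided p-value sums the conditional probabilities of all splits at most
as probable as the observed one. For extremely large totals the smaller
tail is doubled instead. Fold changes are
`log2((mean_LTP + 0.5) / (mean_control + 0.5))` on normalized counts; the
0.5 pseudo-count avoids infinities and only matters for low counts. Genes
absent from both groups get `p = 1`, `log2FC = 0`, and a flag.

**Gate.** A transcript is called differentially expressed (DE) iff
`FDR < 0.1` and `|log2FC| > 0.4`, both strict, with Benjamini–Hochberg
adjustment computed within each time point x fraction stratum. The exact
test (rather than an NB GLM) is a deliberate choice for a design with no
covariates and n = 3 per group; it is the classic small-sample procedure
for two-group NB comparisons.

## Temporal structure

**Overlap.** Overlaps between DE sets (across time points, or TRAP vs
total RNA at one time point) are scored with the upper-tail
hypergeometric test on a background universe of expressed transcripts
(mean TRAP-normalized count of at least 20 reads, inclusive).

**Profile clustering.** Short time-series are clustered in the style of
model-profile miners: all `(2c+1)^T` integer step profiles anchored at 0
are enumerated (default unit `c = 2`), `m = 10` representatives are chosen
by greedy max–min correlation distance, and each gene's log2FC vector —
with an implicit 0 at time 0, since the control-referenced design has no
measured baseline fold change — is assigned to the representative with the
highest Pearson correlation. Genes enter clustering if they pass the gate
at one or more time points; their sub-threshold fold changes at the other
time points still contribute. Profile significance is the permutation
p-value of the assigned-gene count under independent per-gene permutations
of time order, with the `(b + 1)/(n_perm + 1)` correction so p never
reaches 0. Constant fold-change vectors cannot be assigned by correlation
and fall back to minimum Euclidean distance, flagged.

**Over-representation.** ORA over user-supplied GMT collections uses the
same hypergeometric upper tail, excludes categories overlapping the query
in fewer than 4 genes before testing, and BH-adjusts across the tested
categories at adjusted p < 0.05.

## UTR lengths and RBP motifs

Per-gene UTR lengths average the annotated isoforms (genes lacking a side
are excluded from that side's analyses). Up, down and background length
distributions are compared with two-sided rank-sum tests: exact when both
groups have at most 10 untied values, tie-corrected normal approximation
otherwise.

Motif sites are counted over the RNA alphabet (DNA input is transcribed)
as all, possibly overlapping, sliding-window matches of the IUPAC
consensus; a PWM mode (log-odds at 80% of the maximal score) is available
because published RBP compendia distribute position weight matrices and
consensus matching is not the only defensible site caller.

Enrichment uses a length-constrained resampling null: the observed
statistic is the total site count over the target genes' UTRs; each of B
resamples (defaults 5000 for 3' UTRs, 1000 for 5' UTRs, where sites are
scarcer) draws background UTRs without replacement in random order until
the cumulative length first reaches the targets' total length L, including
the overshooting UTR. Filling to L and keeping the final UTR was chosen
over discarding it because exclusion would bias resamples against long
UTRs; every resample's total length then lies in `[L, L + max background
UTR length)`. Fold-enrichment is the relative excess `(O - E)/E` over the
null mean — under this reading the published criterion "fold-enrichment
> ±0.2" is `|FE| > 0.2`, which we prefer to a log-ratio reading because it
makes the ± bound symmetric around 0. Empirical p-values use the +1
correction and are reported two-sided (twice the smaller tail, capped at
1); no correction across motifs is applied for the significance call,
matching the raw p < 0.05 criterion, but a BH column is emitted for
transparency. Resampling operates on gene-level averaged UTRs, consistent
with averaging isoforms before resampling.

## Cell-type attribution

For each cell type `c`, the enrichment factor is
`E_c = FPKM_c / sum(FPKM of the other types)`, with the denominator
floored at 0.1 FPKM (flagged) to avoid division by zero. A DE transcript
is attributed to a cell type iff `E_c >= 1.5` (inclusive, since the
published cutoff is stated without strictness); transcripts meeting the
cutoff for no type are "unassigned", and the rare transcript meeting it
for several is assigned to the max-factor type and flagged ambiguous.

Neuron-enriched transcripts are those whose basal (control) mean
normalized TRAP count is at least 1.5 times the basal total-RNA mean, with
a 10-read minimum applied to **both** fraction means — the conservative
reading, since a low mean on either side inflates ratio instability.
Normalized means are TMM-scaled counts on a common library-size scale, so
the 10-read floor keeps its read-count meaning. For each neuron-enriched
transcript that passes the TRAP gate at one or more time points, the log2
fold changes are averaged over exactly those time points, and the same
time points are used for the total-RNA average so the pair is matched.
The paired Wilcoxon signed-rank test then compares magnitudes after
orienting each pair by the sign of its TRAP value, so up- and
downregulated transcripts both contribute "TRAP magnitude minus RNA
magnitude"; zero differences are dropped, the exact distribution is used
up to n = 25 without ties, and fewer than 5 usable pairs is an error.

## The synthetic-data generator

`simulate_counts()` draws, for each gene, a neuronal and a non-neuronal
expression component (log-normal baselines, `meanlog = log(100)`,
`sdlog = 1`, mimicking the dynamic range of expressed genes after the
usual low-count filtering). The total-RNA signal mixes them with weight
`f = 0.5` (neuron fraction of tissue RNA); the TRAP signal is the neuronal
component plus a contamination leak `eps = 0.02`, reflecting strong but
imperfect de-enrichment of non-neuronal transcripts in ribosome
immunoprecipitations. LTP multiplies the neuronal component by
`2^Delta_g(t)`; by default 10% of genes are DE with peak `|Delta| = 1`
(most published LTP fold changes are below one log2 unit), temporal shapes
drawn from ramp / late-onset / early-transient / sustained templates, half
up and half down, and 10% of DE genes regulated in the non-neuronal
compartment instead (emulating glial responses visible only in total RNA).
Counts are NB with `phi = 0.1` and per-sample log-normal depth factors
(`sdlog = 0.1`). The dilution identity
`E[total fold] = f * 2^Delta + (1 - f)` against `E[TRAP fold] = 2^Delta`
is the closed form every mixture test checks. The contamination level is a
free knob, not an estimate — published slice data quantify de-enrichment
only qualitatively.

`simulate_utr_catalog()` draws isoform UTR lengths log-normally (5' UTRs
around 150 nt, 3' UTRs around 800 nt, matching mammalian annotation
scale), generates sequences from a slightly AU-rich background, and can
plant IUPAC motifs at fixed copy numbers into designated target UTRs at
uniformly chosen non-overlapping positions, replacing the substring so the
length is unchanged. `simulate_celltype_reference()` builds a
five-cell-type FPKM table in which designated markers exceed the
enrichment-factor cutoff by construction and non-markers are
near-uniform.

What the generator does **not** emulate: isoform-level quantification,
read-level artifacts (GC, mappability), batch effects, correlated gene
modules, or secondary-structure context of motif sites. Passing the
validation suite therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to those real-data
complications.

## Validation design and problem sizes

The test suite validates each analytic p-value route against independent
brute-force oracles (step-up BH, hypergeometric pmf summation, exhaustive
rank permutations and sign flips, naive motif scans), and the pipeline
properties on simulations at the study's design scale: 2000 genes x 3
replicates for calibration and recovery, 200 pseudo-replicates for the
dilution closed form, 40-gene target sets with B = 1000 resamples for
motif power, and 40-gene paired comparisons for the magnitude test.
These sizes give Monte-Carlo standard errors comfortably below the
tolerances being asserted while keeping the full suite fast.

Two validation subtleties are worth recording. First, gene selection for
the paired magnitude comparison uses the generator's ground-truth DE
labels, not the empirical gate: conditioning on a gene having passed the
TRAP gate inflates its TRAP fold-change estimate (winner's curse) and
would bias the TRAP-vs-RNA comparison even without dilution. The same
selection effect is present in any real-data version of this analysis and
should be kept in mind when interpreting it. Second, the no-dilution
calibration check sets both `f = 1` and `eps = 0`, because with
contamination the TRAP fold change is genuinely (slightly) attenuated and
the paired null is not exactly true.

## Known limitations

- Fold-change errors are correlated across genes that share libraries, so
  the paired signed-rank test is mildly anticonservative (rejection rates
  a few points above nominal at 40 genes on 6+6 libraries) even under an
  exact null. This is inherent to shared-library paired designs.
- The gate's recall on planted effects depends on the DE:null mixture
  through the BH threshold; at a study-like 10% DE fraction, planted
  `|Delta| = 1` effects at mean 100 pass the gate at roughly 78%, and an
  edgeR-based pipeline scores identically on the same data.
- The common-dispersion assumption trades per-gene variance adaptivity for
  stability at n = 3; genes with atypically high dispersion will be
  anticonservative.
- Cell-type attribution inherits whatever biases the reference FPKM table
  carries (in the motivating study, a developmental-stage mismatch); no
  correction is attempted.
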