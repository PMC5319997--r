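test_that("BH adjustment matches the hand step-up on the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up on random vectors", {
  withr::with_seed(99, {
    for (i in 1:200) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("dispersion estimation recovers the generating value", {
  withr::with_seed(2, {
    mu <- rlnorm(2000, log(100), 1)
    cnt <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 10))
    dimnames(cnt) <- list(sprintf("g%05d", 1:2000), paste0("s", 1:6))
  })
  phi <- nb_dispersion(cnt, two_groups())
  expect_gte(phi, 0.05)
  expect_lte(phi, 0.2)
})

test_that("dispersion is near zero for Poisson and zero for constant data", {
  withr::with_seed(4, {
    mu <- rlnorm(3000, log(100), 1)
    cnt <- sapply(1:6, function(j) rpois(3000, mu))
    dimnames(cnt) <- list(sprintf("g%05d", 1:3000), paste0("s", 1:6))
  })
  expect_lt(nb_dispersion(cnt, two_groups()), 0.02)
  const <- matrix(rep(c(5L, 10L, 20L), each = 6), 3, 6, byrow = TRUE,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  expect_equal(nb_dispersion(const, two_groups()), 0, tolerance = 1e-4)
  expect_error(nb_dispersion(const[, 1, drop = FALSE], factor("a")),
               "at least 2")
  expect_error(nb_dispersion(const, factor(paste0("g", 1:6))),
               ">= 2 replicates")
})

test_that("identical groups give log2FC 0 and p 1", {
  m <- matrix(rep(c(10L, 50L, 0L, 7L), 6), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  tab <- de_test(m, two_groups(), dispersion = 0.1)
  expect_equal(tab$log2FC, rep(0, 4))
  expect_equal(tab$pvalue, rep(1, 4))
  expect_true(tab$all_zero[3])
})

test_that("exact test is calibrated on null NB data", {
  withr::with_seed(8, {
    mu <- rlnorm(2000, log(100), 1)
    cnt <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 10))
    dimnames(cnt) <- list(sprintf("g%05d", 1:2000), paste0("s", 1:6))
  })
  grp <- two_groups()
  tab <- de_test(cnt, grp, nb_dispersion(cnt, grp))
  expect_lt(abs(mean(tab$pvalue < 0.05) - 0.05), 0.02)
})

test_that("exact test p-values track edgeR's exactTest", {
  skip_if_not_installed("edgeR")
  fix <- make_de_counts(1000, 100, mu = 100, phi = 0.1, seed = 12)
  grp <- two_groups()
  tab <- de_test(fix$counts, grp, nb_dispersion(fix$counts, grp))
  d <- edgeR::DGEList(fix$counts, group = grp)
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateCommonDisp(d)
  et <- edgeR::exactTest(d)$table
  expect_gt(cor(tab$pvalue, et$PValue, method = "spearman"), 0.99)
  expect_gt(cor(tab$log2FC, et$logFC), 0.99)
})

test_that("planted effects pass the default gate at high rate", {
  fix <- make_de_counts(1500, 150, mu = 100, phi = 0.05, seed = 5)
  grp <- two_groups()
  tab <- de_test(fix$counts, grp, nb_dispersion(fix$counts, grp))
  fdr <- bh_adjust(tab$pvalue)
  pass <- fdr < 0.1 & abs(tab$log2FC) > 0.4
  expect_gt(mean(pass[fix$de]), 0.7)
  expect_lt(mean(pass[-fix$de]), 0.02)
})

test_that("depth scaling of one sample leaves inference unchanged", {
  withr::with_seed(19, {
    mu <- rlnorm(800, log(100), 1)
    cnt <- sapply(1:6, function(j) rnbinom(800, mu = mu, size = 10))
    dimnames(cnt) <- list(sprintf("g%05d", 1:800), paste0("s", 1:6))
  })
  grp <- two_groups()
  phi <- nb_dispersion(cnt, grp)
  tab1 <- de_test(cnt, grp, phi)
  cnt2 <- cnt
  cnt2[, 1] <- cnt2[, 1] * 3L
  tab2 <- de_test(cnt2, grp, phi)
  # the depth factor is absorbed by the library size, not the TMM factor
  expect_equal(unname(tmm_factors(cnt2)$tmm_factor), rep(1, 6),
               tolerance = 0.02)
  expect_gt(cor(tab1$pvalue, tab2$pvalue, method = "spearman"), 0.98)
  g1 <- bh_adjust(tab1$pvalue) < 0.1 & abs(tab1$log2FC) > 0.4
  g2 <- bh_adjust(tab2$pvalue) < 0.1 & abs(tab2$log2FC) > 0.4
  expect_lte(mean(g1), 0.01)
  expect_lte(mean(g2), 0.01)
})

test_that("the significance gate applies strict printed thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FC = c(0.5, 0.3, -0.6, 0.41),
                    fdr = c(0.09, 0.05, 0.02, 0.1))
  sets <- gate_significant(tab, significance_gate())
  expect_equal(sets$up, "a")      # fdr 0.09 < 0.1 and |lfc| 0.5 > 0.4
  expect_equal(sets$down, "c")
  # b fails |log2FC|, d fails strict fdr < 0.1
  empty <- gate_significant(tab[0, ], significance_gate())
  expect_equal(lengths(empty), c(up = 0L, down = 0L))
})

test_that("gated gene-set AUPR beats a fold-change-only ranking", {
  # heterogeneous means: |lfc|-only ranking is fooled by noisy low-count
  # genes, the test's p-value ranking is not
  mu <- withr::with_seed(23, rlnorm(1500, log(60), 1.3))
  fix <- make_de_counts(1500, 150, mu = mu, phi = 0.1, seed = 23)
  grp <- two_groups()
  tab <- de_test(fix$counts, grp, nb_dispersion(fix$counts, grp))
  truth <- seq_len(nrow(tab)) %in% fix$de
  aupr <- function(score) {
    o <- order(score, decreasing = TRUE)
    hit <- truth[o]
    mean(cumsum(hit)[hit] / which(hit))
  }
  # p-value-based ranking must dominate |lfc|-only ranking
  expect_gt(aupr(-tab$pvalue), aupr(abs(tab$log2FC)))
})

test_that("de_analysis strata carry per-timepoint gates and directions", {
  sim <- small_sim(200, seed = 41, dispersion = 0.05)
  cd <- count_data(cbind(sim$trap$counts, sim$total$counts),
                   rbind(sim$trap$samples, sim$total$samples))
  de <- de_analysis(cd)
  expect_setequal(unique(de$fraction), c("trap", "total"))
  expect_setequal(unique(de$timepoint), c(30, 60, 120))
  expect_equal(nrow(de), 200 * 6)
  expect_true(all(de$fdr >= de$pvalue - 1e-12 | de$fdr <= 1))
  sig <- de[de$significant, ]
  expect_true(all(sig$fdr < 0.1 & abs(sig$log2FC) > 0.4))
  expect_true(all(sig$direction %in% c("up", "down")))
  # recovered DE genes are mostly true plants
  hits <- unique(sig$gene[sig$fraction == "trap"])
  if (length(hits) >= 5) {
    expect_gt(mean(hits %in% sim$truth$de_genes), 0.8)
  }
})
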