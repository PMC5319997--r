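test_that("isoform UTR lengths average per gene with missing sides flagged", {
  iso <- data.frame(gene = c("a", "a", "b", "c"),
                    side = c("utr3", "utr3", "utr3", "utr5"),
                    length = c(300, 500, 250, 120))
  lens <- average_utr_lengths(iso)
  expect_equal(lens$utr3_len[lens$gene == "a"], 400)
  expect_equal(lens$utr3_len[lens$gene == "b"], 250)
  expect_true(is.na(lens$utr5_len[lens$gene == "a"]))
  expect_true(is.na(lens$utr3_len[lens$gene == "c"]))
  expect_error(average_utr_lengths(transform(iso, length = -1)),
               "non-negative")
})

test_that("rank-sum wrapper reproduces the exact enumeration", {
  ht <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$p_value, 0.1)  # 2/20 orderings as extreme
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(rank_sum_test(1, c(1, 2)), "at least 2")
  withr::with_seed(17, {
    for (i in 1:60) {
      x <- runif(sample(3:7, 1))
      y <- runif(sample(3:7, 1))
      expect_equal(rank_sum_test(x, y)$p_value, oracle_rank_sum(x, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("length comparison detects a planted median shift", {
  withr::with_seed(29, {
    up <- rlnorm(200, log(1200), 0.8)    # 2x median shift
    down <- rlnorm(200, log(600), 0.8)
    bg <- rlnorm(400, log(700), 0.8)
  })
  cmp <- compare_utr_lengths(up, down, bg)
  expect_equal(cmp$comparison,
               c("up_vs_down", "up_vs_background", "down_vs_background"))
  expect_lt(cmp$p_value[cmp$comparison == "up_vs_down"], 0.01)
  expect_error(compare_utr_lengths(1, down, bg), "fewer than 2")
})

test_that("motif site counting handles overlap and IUPAC codes", {
  expect_equal(count_motif_sites("GGAUUUAGG", "AUUUA"), 1)
  expect_equal(count_motif_sites("AUUUAUUUA", "AUUUA"), 2)
  expect_equal(count_motif_sites("UGUACAUA", "UGUAHAUA"), 1)
  expect_equal(count_motif_sites("ggauuuagg", "auuua"), 1)  # case + T/U
  expect_equal(count_motif_sites("GGATTTAGG", "AUUUA"), 1)  # DNA input
  expect_equal(count_motif_sites("ACG", "AUUUA"), 0)
  expect_error(count_motif_sites("ACGX", "AUUUA"), "invalid alphabet")
  expect_error(count_motif_sites("ACGU", "AJC"), "invalid IUPAC")
})

test_that("consensus scanning equals the naive oracle on random pairs", {
  withr::with_seed(43, {
    codes <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
    for (i in 1:1000) {
      s <- paste(sample(c("A", "C", "G", "U"), sample(20:60, 1),
                        replace = TRUE), collapse = "")
      mot <- paste(sample(codes, sample(3:7, 1), replace = TRUE,
                          prob = c(rep(4, 4), rep(1, 11))), collapse = "")
      expect_equal(count_motif_sites(s, mot), oracle_scan(s, mot))
    }
  })
})

test_that("PWM mode finds high-scoring sites at the stated threshold", {
  pwm <- matrix(0.01, 4, 5, dimnames = list(c("A", "C", "G", "U"), NULL))
  pwm[cbind(match(c("A", "U", "U", "U", "A"), rownames(pwm)), 1:5)] <- 0.97
  expect_equal(count_motif_sites("GGAUUUAGG", pwm), 1)
  expect_equal(count_motif_sites("GGAUUUGGG", pwm, threshold = 0.99), 0)
  ms <- motif_set(data.frame(motif = "m1", rbp = "r", consensus = "AUUUA"),
                  pwms = list(m1 = pwm))
  expect_error(motif_set(data.frame(motif = "m1", rbp = "r",
                                    consensus = "AUUUA"),
                         pwms = list(m1 = pwm[, 1:2] * 2)), "summing to 1")
})

test_that("resampling respects the total-length constraint", {
  genes <- sprintf("g%03d", 1:200)
  cat <- simulate_utr_catalog(utr_sim_config(genes, seed = 3))
  ms <- random_motif_set(5, seed = 2)
  targets <- names(cat$seq3)[1:30]
  enr <- resample_enrichment(targets, cat, "utr3", ms, B = 300, seed = 6)
  L <- attr(enr, "target_length")
  rl <- attr(enr, "resample_lengths")
  expect_true(all(rl >= L))
  expect_true(all(rl < L + attr(enr, "max_background_length")))
  expect_true(all(enr$p_value >= 1 / 301))
  expect_true(all(enr$fold_enrichment >= -1, na.rm = TRUE))
  expect_identical(enr, resample_enrichment(targets, cat, "utr3", ms,
                                            B = 300, seed = 6))
  expect_error(resample_enrichment(targets, cat, "utr3", ms, B = 50),
               "at least 100")
  expect_error(resample_enrichment("nope", cat, "utr3", ms, B = 300),
               "absent from background")
})

test_that("null targets are calibrated and planted motifs are detected", {
  genes <- sprintf("g%03d", 1:250)
  withr::with_seed(8, targets <- sample(genes, 35))
  ms <- random_motif_set(30, seed = 4)
  cat0 <- simulate_utr_catalog(utr_sim_config(genes, seed = 9))
  targets <- intersect(targets, names(cat0$seq3))
  enr0 <- resample_enrichment(targets, cat0, "utr3", ms, B = 500, seed = 2)
  expect_lte(mean(enr0$p_value < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
  # plant AUUUA at ~3x background density into the targets
  cat1 <- simulate_utr_catalog(utr_sim_config(genes, seed = 9,
    plants = list(list(motif = "AUUUA", genes = targets, side = "utr3",
                       copies = 4))))
  msA <- motif_set(data.frame(motif = "M_AUUUA", rbp = "Elavl",
                              consensus = "AUUUA"))
  enr1 <- resample_enrichment(targets, cat1, "utr3", msA, B = 500, seed = 2)
  expect_lt(enr1$p_value, 0.05)
  expect_gt(enr1$fold_enrichment, 0.2)
  sig <- significant_motifs(enr1)
  expect_equal(sig$overrepresented$motif, "M_AUUUA")
})

test_that("significance criteria for motifs follow p and FE jointly", {
  res <- data.frame(motif = c("a", "b", "c"), rbp = "r",
                    observed = 1, expected = 1,
                    fold_enrichment = c(0.25, 0.10, -0.30),
                    p_value = c(0.04, 0.04, 0.01))
  sig <- significant_motifs(res)
  expect_equal(sig$overrepresented$motif, "a")
  expect_equal(sig$underrepresented$motif, "c")
  empty <- significant_motifs(res[0, ])
  expect_equal(nrow(empty$overrepresented), 0)
})
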