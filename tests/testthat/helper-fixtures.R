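# Programmatic fixtures shared across test files.

make_null_counts <- function(n_genes, mu, phi, n_per_group = 3, seed = 1) {
  withr::with_seed(seed, {
    mu <- rep_len(mu, n_genes)
    cnt <- sapply(seq_len(2 * n_per_group), function(j) {
      if (phi > 0) rnbinom(n_genes, mu = mu, size = 1 / phi)
      else rpois(n_genes, mu)
    })
    dimnames(cnt) <- list(sprintf("g%05d", seq_len(n_genes)),
                          paste0("s", seq_len(2 * n_per_group)))
    cnt
  })
}

# Null fixture with a block of genes shifted by delta (log2) in group B.
make_de_counts <- function(n_genes, n_de, mu, phi, delta = 1,
                           n_per_group = 3, seed = 1) {
  withr::with_seed(seed, {
    mu <- rep_len(mu, n_genes)
    mu_b <- mu
    sgn <- rep_len(c(1, -1), n_de)
    mu_b[seq_len(n_de)] <- mu[seq_len(n_de)] * 2^(sgn * delta)
    cnt <- cbind(
      sapply(seq_len(n_per_group), function(j)
        rnbinom(n_genes, mu = mu, size = 1 / phi)),
      sapply(seq_len(n_per_group), function(j)
        rnbinom(n_genes, mu = mu_b, size = 1 / phi)))
    dimnames(cnt) <- list(sprintf("g%05d", seq_len(n_genes)),
                          paste0("s", seq_len(2 * n_per_group)))
    list(counts = cnt, de = seq_len(n_de), delta = sgn * delta)
  })
}

two_groups <- function(n_per_group = 3) {
  factor(rep(c("control", "LTP"), each = n_per_group),
         levels = c("control", "LTP"))
}

random_motif_set <- function(n, width = 5, seed = 1) {
  withr::with_seed(seed, {
    motif_set(data.frame(
      motif = paste0("M", seq_len(n)),
      rbp = paste0("RBP", seq_len(n)),
      consensus = replicate(n, paste(sample(c("A", "C", "G", "U"), width,
                                            replace = TRUE),
                                     collapse = ""))))
  })
}

small_sim <- function(n_genes = 300, seed = 1, ...) {
  simulate_counts(sim_config(n_genes = n_genes, seed = seed, ...))
}
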