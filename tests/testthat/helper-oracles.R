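# Independent brute-force oracles used by both unit and acceptance tests.
# These are deliberately naive and share no code with the package.

# Benjamini-Hochberg step-up by direct definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Upper-tail hypergeometric P(X >= k) by direct pmf summation.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- max(k, max(0, n - (N - K))):min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Naive position-by-position IUPAC scan.
oracle_scan <- function(seq, motif) {
  iupac <- list(A = "A", C = "C", G = "G", U = "U",
                R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                B = c("C", "G", "U"), D = c("A", "G", "U"),
                H = c("A", "C", "U"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "U"))
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  L <- length(m)
  if (L > length(s)) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(s[i + j - 1L] %in% iupac[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
oracle_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  w_all <- apply(combos, 2, function(id) sum(r[id])) - n1 * (n1 + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign flips.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Direct TMM factor for one sample pair (unweighted formula check helper).
oracle_tmm_pair <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  n_o <- sum(obs); n_r <- sum(ref)
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  m <- log2((obs / n_o) / (ref / n_r))
  a <- 0.5 * log2((obs / n_o) * (ref / n_r))
  w <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}
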