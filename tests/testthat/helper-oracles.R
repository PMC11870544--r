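# Independent oracles used across tests. These deliberately use brute-force
# or closed-form routes distinct from the package implementation.

# Benjamini-Hochberg by direct definition (step-up)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# two-sided exact binomial p at p0 = 0.5 by explicit tail sums
binom_two_sided_brute <- function(k, n) {
  lo <- min(k, n - k)
  hi <- max(k, n - k)
  if (lo == hi) return(1)       # the two tails coincide at the midpoint
  sum(dbinom(0:lo, n, 0.5)) + sum(dbinom(hi:n, n, 0.5))
}

# multivariate normal log-density via Cholesky (no external packages)
mvn_ll <- function(z, S) {
  ch <- chol(S)
  -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
}

# exact single-effect posterior over causal configurations of size <= 1
# (including the empty configuration) by full MVN likelihood evaluation
enumerate_single_effect_pip <- function(z, R, groups, pi, sigma2) {
  p <- length(z)
  logw <- c(0, vapply(seq_len(p), function(j) {
    S1 <- R + sigma2[groups[j]] * R[, j] %*% t(R[j, ])
    log(pi[groups[j]]) - log1p(-pi[groups[j]]) + mvn_ll(z, S1) - mvn_ll(z, R)
  }, numeric(1)))
  w <- exp(logw - max(logw))
  (w / sum(w))[-1]
}

# per-bin averaging by explicit loops (binning oracle)
bin_means_brute <- function(values, pt, n_bins) {
  out <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    sel <- if (b == n_bins) pt >= lo & pt <= hi else pt >= lo & pt < hi
    if (any(sel)) out[b] <- mean(values[sel])
  }
  out
}

# O(n^2) interval overlap: gene windows x peaks
overlap_brute <- function(win_lo, win_hi, peak_start0, peak_end) {
  n_g <- length(win_lo)
  n_p <- length(peak_start0)
  hits <- matrix(FALSE, n_g, n_p)
  for (i in seq_len(n_g)) for (j in seq_len(n_p)) {
    hits[i, j] <- (peak_start0[j] + 1) <= win_hi[i] && peak_end[j] >= win_lo[i]
  }
  hits
}

# hypergeometric two-sided enrichment p by summing point probabilities
fisher_brute <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  K <- a + b            # set size
  m <- a + c_           # hits
  support <- max(0, K + m - n):min(K, m)
  probs <- dhyper(support, m, n - m, K)
  p_obs <- dhyper(a, m, n - m, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small deterministic genotype fixture: n donors x SNP dosage columns
toy_genotypes <- function(dosage, chrom = "chr1", pos = NULL) {
  n_snp <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  snps <- tibble::tibble(
    snp_id = colnames(dosage) %||% sprintf("s%02d", seq_len(n_snp)),
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
    maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2))
  colnames(dosage) <- snps$snp_id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("d%02d", seq_len(nrow(dosage)))
  }
  stimqtl:::new_stim_genotypes(dosage, snps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
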