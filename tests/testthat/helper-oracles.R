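# Independent reference implementations used as oracles. These stay
# deliberately naive: enumeration and sorting, nothing shared with the
# package's code paths.

# Two-sided minimum-likelihood binomial p by full enumeration with exact
# dyadic probabilities (choose(n,k)/2^n is exact in doubles for n <= ~50).
oracle_binom_p <- function(ref, alt) {
  n <- ref + alt
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[alt + 1]])
}

# Sort-based Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by enumeration over all outcomes.
oracle_hyper_p <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Build allelic counts for one tumor directly from a phase table and a
# single CNA event, bypassing the simulator's own copy-state machinery.
counts_for_event <- function(phase, sample_id, direction, affected_hap,
                             purity, depth, interval = NULL, rho = 0) {
  n_alt <- rep(1, nrow(phase)); n_ref <- rep(1, nrow(phase))
  inside <- if (is.null(interval)) rep(TRUE, nrow(phase)) else {
    phase$pos > interval[1] & phase$pos <= interval[2]
  }
  aff <- phase$alt_hap == affected_hap
  if (direction == "loss") {
    n_alt[inside & aff] <- 0; n_ref[inside & aff] <- 1
    n_alt[inside & !aff] <- 1; n_ref[inside & !aff] <- 0
  } else if (direction == "gain") {
    n_alt[inside & aff] <- 2; n_ref[inside & aff] <- 1
    n_alt[inside & !aff] <- 1; n_ref[inside & !aff] <- 2
  } else if (direction == "cn_loh") {
    n_alt[inside & aff] <- 2; n_ref[inside & aff] <- 0
    n_alt[inside & !aff] <- 0; n_ref[inside & !aff] <- 2
  }
  f <- clonemap::expected_alt_fraction(n_alt, n_ref, purity)
  rc <- clonemap::sample_allelic_depth(f, depth, rho)
  data.frame(sample_id = sample_id, chrom = phase$chrom, pos = phase$pos,
             ref_count = rc$ref_count, alt_count = rc$alt_count,
             stringsAsFactors = FALSE)
}

# Phase table for one chromosome of the toy genome.
toy_phase <- function(n_snps, chrom = "chr1", chrom_len = 10e6) {
  data.frame(chrom = chrom,
             pos = sort(sample.int(chrom_len, n_snps)),
             alt_hap = sample(c("A", "B"), n_snps, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Truth-expected major allele at each phased SNP for a CNA event: the
# haplotype with more copies carries the major allele.
truth_major <- function(phase, direction, affected_hap) {
  # loss: the retained (other) haplotype is major; gain/cn_loh: the
  # affected haplotype is major
  if (direction == "loss") {
    ifelse(phase$alt_hap == affected_hap, "REF", "ALT")
  } else {
    ifelse(phase$alt_hap == affected_hap, "ALT", "REF")
  }
}

fixture_path <- function(...) {
  system.file("extdata", "filter_fixture", ..., package = "clonemap")
}
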