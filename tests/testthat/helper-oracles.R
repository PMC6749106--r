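# Independent oracles used across the suite.

# harmonic number, exact for small n, asymptotic beyond
harmonic <- function(n) {
  if (n <= 1e5) sum(1 / seq_len(n))
  else log(n) + 0.5772156649015329 + 1 / (2 * n) - 1 / (12 * n^2)
}

# occupancy expectation for a single even population: reads to see a
# fraction q of K equiprobable k-mers (q < 1)
occupancy_reads <- function(K, q, abundance = 1) {
  K * log(1 / (1 - q)) / abundance
}

# analytic bases for the single-genome effort surface oracle
analytic_bases <- function(q, l, f, k = 100) {
  (l - k + 1) * k * log(1 / (1 - q)) / f
}

# brute-force coupon-collector integral enumerating every k-mer
brute_exhaustion <- function(community) {
  gw <- seqeffort:::kmer_weights(community)
  w <- rep(gw$w, gw$m)
  f <- function(t) -expm1(sum(log1p(-exp(-w * t))))
  upper <- max((log(1) + 40) / min(w))
  stats::integrate(Vectorize(f), 0, 1, rel.tol = 1e-10)$value +
    stats::integrate(Vectorize(function(v) f(exp(v)) * exp(v)),
                     0, log(upper), rel.tol = 1e-10)$value
}

# brute-force Shannon entropy enumerating every k-mer
brute_shannon <- function(community) {
  gw <- seqeffort:::kmer_weights(community)
  w <- rep(gw$w, gw$m)
  sum(-w * log(w))
}

# literal two-population sequencing simulation: reads drawn one at a time,
# each a genome hit with probability `abundance`, hits collected uniformly
# over K k-mers until d distinct are seen
literal_genome_sim <- function(K, abundance, d) {
  seen <- logical(K)
  n_seen <- 0L
  reads <- 0L
  while (n_seen < d) {
    reads <- reads + 1L
    if (runif(1) <= abundance) {
      i <- sample.int(K, 1)
      if (!seen[i]) {
        seen[i] <- TRUE
        n_seen <- n_seen + 1L
      }
    }
  }
  reads
}
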