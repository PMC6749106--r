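test_that("community simulation matches coupon-collector closed forms", {
  # |K| = 1: a single read exhausts the population
  s1 <- simulate_community_sequencing(community_even(1), 1, seed = 1,
                                      replicates = 3)
  expect_true(all(s1$reads == 1))
  # |K| = 2: E[T] = 2 H_2 = 3
  s2 <- simulate_community_sequencing(community_even(2), 1, seed = 2,
                                      replicates = 4000)
  se <- sd(s2$reads) / sqrt(nrow(s2))
  expect_lt(abs(mean(s2$reads) - 3), 3 * se)
  # |K| = 1e4 exhaustion vs n H_n
  s3 <- simulate_community_sequencing(community_even(1e4), 1, seed = 3,
                                      replicates = 100)
  se3 <- sd(s3$reads) / 10
  expect_lt(abs(mean(s3$reads) - 1e4 * harmonic(1e4)), 3 * se3)
})

test_that("simulation results carry coherent structure", {
  sim <- simulate_community_sequencing(community_tiered(1e4, 0.9, 0.5),
                                       targets = c(0.9, 0.5, 1),
                                       seed = 7, replicates = 3)
  expect_equal(nrow(sim), 9)
  expect_equal(sim$bases, sim$reads * 100)
  # reads nondecreasing in target within each replicate
  for (r in 1:3) {
    sub <- sim[sim$replicate == r, ]
    sub <- sub[order(sub$target_fraction), ]
    expect_true(all(diff(sub$reads) >= 0))
  }
  expect_error(simulate_community_sequencing(community_even(10), 1.5,
                                             seed = 1),
               class = "seqeffort_domain_error")
  expect_error(simulate_community_sequencing(community_even(10), 1, seed = 1,
                                             max_kmers = 5),
               class = "seqeffort_domain_error")
})

test_that("checkpoint recording rounds crossings up to the interval", {
  exact <- simulate_community_sequencing(community_even(5000), c(0.5, 1),
                                         seed = 5, replicates = 2)
  chk <- simulate_community_sequencing(community_even(5000), c(0.5, 1),
                                       seed = 5, replicates = 2,
                                       checkpoint = 1000,
                                       record_mode = "checkpoint")
  expect_equal(chk$reads, ceiling(exact$reads / 1000) * 1000)
})

test_that("same seed and configuration reproduce results bit for bit", {
  cfg <- list(community_lognormal(2e4, a = 0.2), c(0.5, 0.9, 1))
  a <- simulate_community_sequencing(cfg[[1]], cfg[[2]], seed = 42,
                                     replicates = 3)
  b <- simulate_community_sequencing(cfg[[1]], cfg[[2]], seed = 42,
                                     replicates = 3)
  expect_identical(a, b)
  g1 <- simulate_genome_effort(1e5, 0.1, 0.9, seed = 42, replicates = 5)
  g2 <- simulate_genome_effort(1e5, 0.1, 0.9, seed = 42, replicates = 5)
  expect_identical(g1, g2)
  # different seeds diverge
  g3 <- simulate_genome_effort(1e5, 0.1, 0.9, seed = 43, replicates = 5)
  expect_false(identical(g1$reads, g3$reads))
})

test_that("single-genome effort matches occupancy expectations", {
  # f = 1 reduces to coupon collection on the genome alone
  g <- simulate_genome_effort(1e4 + 99, abundance = 1, target_fraction = 1,
                              seed = 1, replicates = 100)
  expect_equal(g$hits, g$reads)
  se <- sd(g$reads) / 10
  expect_lt(abs(mean(g$reads) - 1e4 * harmonic(1e4)), 3 * se)
  # f = 0.5, q = 0.5: occupancy expectation scaled by 1/f
  g2 <- simulate_genome_effort(1e5 + 99, abundance = 0.5,
                               target_fraction = 0.5, seed = 2,
                               replicates = 100)
  se2 <- sd(g2$reads) / 10
  expect_lt(abs(mean(g2$reads) - occupancy_reads(1e5, 0.5, 0.5)), 3 * se2)
  # q = 1, f = 0.01 on a small genome: n H_n / f
  g3 <- simulate_genome_effort(1e3 + 99, abundance = 0.01,
                               target_fraction = 1, seed = 3,
                               replicates = 100)
  se3 <- sd(g3$reads) / 10
  expect_lt(abs(mean(g3$reads) - 1e3 * harmonic(1e3) / 0.01), 3 * se3)
  expect_error(simulate_genome_effort(1e4, 0, 0.5, seed = 1),
               class = "seqeffort_domain_error")
  expect_error(simulate_genome_effort(200, 1, 0.001, seed = 1),
               class = "seqeffort_domain_error")
})

test_that("hits-plus-negative-binomial equals a literal two-population simulation", {
  K <- 100
  f <- 0.3
  d <- 80  # q = 0.8
  n <- 2000
  fast <- simulate_genome_effort(K + 99, abundance = f,
                                 target_fraction = 0.8, seed = 123,
                                 replicates = n)$reads
  set.seed(321)
  slow <- replicate(n, literal_genome_sim(K, f, d))
  ks <- suppressWarnings(stats::ks.test(fast, slow))
  expect_gt(ks$p.value, 0.01)
})

test_that("reads_to_bases multiplies and validates", {
  expect_equal(reads_to_bases(1e6, 100), 1e8)
  expect_equal(reads_to_bases(0, 100), 0)
  expect_equal(reads_to_bases(1.43927e7, 100), 1.43927e9)
  expect_error(reads_to_bases(-1, 100), class = "seqeffort_domain_error")
})
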