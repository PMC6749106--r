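test_that("kmer_count implements the sliding-window count with domain checks", {
  expect_equal(kmer_count(1e6, 100), 999901)
  expect_equal(kmer_count(100, 100), 1)
  expect_equal(kmer_count(150, 100), 51)
  expect_error(kmer_count(50, 100), class = "seqeffort_domain_error")
  expect_error(kmer_count(-5, 2), class = "seqeffort_domain_error")
  expect_error(kmer_count(100, 0), class = "seqeffort_domain_error")
})

test_that("community constructors normalise masses and enforce invariants", {
  even <- community_even(10)
  expect_s3_class(even, "community_structure")
  expect_equal(sum(even$mass), 1, tolerance = 1e-12)
  expect_equal(even$mass / even$size, 0.1)
  expect_equal(community_size(community_even(1)), 1)

  tiered <- community_tiered(1e6, 0.9, 0.5)
  w <- tiered$mass / tiered$size
  expect_equal(w[1] / w[2], 9)
  tiered2 <- community_tiered(1e6, 0.9, 0.1)
  w2 <- tiered2$mass / tiered2$size
  expect_equal(w2[1] / w2[2], 81)

  expect_error(community_even(0), class = "seqeffort_domain_error")
  expect_error(community_tiered(1e4, 1.2, 0.5),
               class = "seqeffort_domain_error")
  expect_error(community_tiered(3, 0.9, 0.01),
               class = "seqeffort_domain_error")
  expect_error(community_structure(c(5, 5), c(0.5, -0.1)),
               class = "seqeffort_domain_error")
})

test_that("lognormal structure follows S(R) = s0 exp(-a^2 R^2)", {
  c1 <- community_lognormal(1e6, a = 0.2)
  expect_equal(nrow(c1), 10)
  expect_equal(unique(c1$size), 1e5)
  # unnormalised weight ratio at the last octave
  expect_equal(c1$mass[10] / c1$mass[1], exp(-0.04 * 81), tolerance = 1e-12)
  # a = 0 degenerates to the even structure in every per-k-mer statistic
  c0 <- community_lognormal(1e6, a = 0)
  expect_equal(shannon_metagenome(c0), shannon_metagenome(community_even(1e6)))
  expect_equal(pielou_evenness(c0), 1)
  # alternative exponent reading
  alt <- community_lognormal(1e6, a = 0.04, exponent = "a")
  expect_equal(alt$mass[10] / alt$mass[1], exp(-0.04 * 81), tolerance = 1e-12)
  # indivisible totals: the remainder joins the most abundant group
  c2 <- community_lognormal(1004, a = 0.1, octaves = 10)
  expect_equal(community_size(c2), 1004)
  expect_equal(c2$size, c(104, rep(100, 9)))
})

test_that("group-wise Shannon entropy equals brute-force k-mer enumeration", {
  cases <- list(community_even(1000),
                community_tiered(5000, 0.9, 0.5),
                community_tiered(5000, 0.9, 0.1),
                community_lognormal(9997, a = 0.2))
  for (cc in cases) {
    expect_equal(shannon_metagenome(cc), brute_shannon(cc),
                 tolerance = 1e-12)
  }
  expect_equal(shannon_metagenome(community_even(1000)), log(1000))
  expect_equal(shannon_metagenome(community_structure(c(1, 1), c(0.9, 0.1))),
               -0.9 * log(0.9) - 0.1 * log(0.1))
})

test_that("Pielou evenness is 1 iff uniform, base-free, permutation-invariant", {
  expect_equal(pielou_evenness(community_even(1e6)), 1)
  two <- community_structure(c(1, 1), c(0.9, 0.1))
  expect_equal(pielou_evenness(two),
               (-0.9 * log(0.9) - 0.1 * log(0.1)) / log(2),
               tolerance = 1e-12)
  # permutation of groups leaves J unchanged
  a <- community_structure(c(10, 30, 60), c(0.5, 0.3, 0.2))
  b <- community_structure(c(60, 10, 30), c(0.2, 0.5, 0.3))
  expect_equal(pielou_evenness(a), pielou_evenness(b))
  # explicit base-2 computation gives the same ratio (base cancels)
  gw <- seqeffort:::kmer_weights(a)
  J2 <- sum(gw$m * (-gw$w * log2(gw$w))) / log2(community_size(a))
  expect_equal(pielou_evenness(a), J2, tolerance = 1e-12)
  # J strictly decreases with lognormal skew at fixed size
  Js <- sapply(c(0, 0.1, 0.2, 0.4),
               function(a) pielou_evenness(community_lognormal(1e4, a = a)))
  expect_true(all(diff(Js) < 0))
  expect_error(pielou_evenness(community_even(1)),
               class = "seqeffort_domain_error")
  # group-level variant: even group masses give 1
  expect_equal(pielou_evenness(community_lognormal(100, a = 0),
                               level = "group"), 1)
})

test_that("normalised rank abundance sorts masses over r/s ranks", {
  cl <- community_lognormal(1e4, a = 0.2)
  ra <- rank_abundance(cl)
  expect_equal(ra$normalized_rank, (1:10) / 10)
  expect_equal(ra$mass, sort(cl$mass, decreasing = TRUE))
  expect_equal(ra$mass,
               exp(-0.04 * (0:9)^2) / sum(exp(-0.04 * (0:9)^2)))
  flat <- rank_abundance(community_lognormal(100, a = 0))
  expect_true(all(abs(flat$mass - 0.1) < 1e-12))
})

test_that("tiered symmetry: equal mass and k-mer fractions give an even profile", {
  sym <- community_tiered(1e6, 0.5, 0.5)
  expect_equal(pielou_evenness(sym), 1)
})
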