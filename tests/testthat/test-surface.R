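# One moderately sized simulated grid is shared across the surface tests.
surface_test_grid <- function() {
  surface_grid(n_target = 6, n_abundance = 5,
               genome_sizes = c(5e5, 2e6, 5e6),
               replicates = 2, seed = 17)
}

surface_test_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- run_simulation_grid(surface_test_grid())
    tab
  }
})

test_that("grid specification and simulation behave as documented", {
  grid <- surface_test_grid()
  expect_length(grid$target_fractions, 6)
  expect_length(grid$abundances, 5)
  full <- surface_grid_full()
  expect_length(full$target_fractions, 100)
  expect_length(full$abundances, 30)
  expect_length(full$genome_sizes, 8)

  tab <- surface_test_table()
  expect_equal(nrow(tab), 6 * 5 * 3)
  expect_true(all(tab$mean_bases > 0))
  # easiest cell agrees with the occupancy oracle within 3 SE
  cell <- simulate_genome_effort(1e6, 1, 0.5, seed = 33, replicates = 30)
  se <- sd(cell$bases) / sqrt(30)
  expect_lt(abs(mean(cell$bases) - analytic_bases(0.5, 1e6, 1)), 3 * se)
  # determinism of the whole grid
  expect_identical(run_simulation_grid(surface_test_grid()), tab)
  expect_error(surface_grid(n_target = 1), class = "seqeffort_domain_error")
})

test_that("fitting the noiseless analytic surface is near-exact and idempotent", {
  grid <- expand.grid(target_fraction = seq(0.5, 0.99, length.out = 10),
                      genome_size = c(5e5, 1e6, 5e6, 2e7),
                      abundance = 10^seq(-2, 0, length.out = 8))
  grid$mean_bases <- analytic_bases(grid$target_fraction, grid$genome_size,
                                    grid$abundance)
  surf <- fit_effort_surface(grid)
  expect_gt(glance(surf)$r_squared, 0.999)
  # refit on own predictions reproduces them
  pred <- predict_effort(surf, grid$abundance, grid$genome_size,
                         grid$target_fraction)$bases
  grid2 <- grid
  grid2$mean_bases <- pred
  surf2 <- fit_effort_surface(grid2)
  pred2 <- predict_effort(surf2, grid$abundance, grid$genome_size,
                          grid$target_fraction)$bases
  # GCV re-selects the smoothing parameter on the refit, so agreement is
  # near-exact rather than bitwise
  expect_equal(log10(pred2), log10(pred), tolerance = 1e-6)
})

test_that("surface predictions match theory and scale as 1/abundance", {
  surf <- fit_effort_surface(surface_test_table())
  p <- predict_effort(surf, 1, 1e6, 0.5)
  expect_equal(p$bases, analytic_bases(0.5, 1e6, 1), tolerance = 0.1)
  expect_equal(p$reads, p$bases / 100)
  # halving the abundance doubles the effort within 10%
  p2 <- predict_effort(surf, c(0.2, 0.1), 2e6, 0.8)
  expect_equal(p2$bases[2] / p2$bases[1], 2, tolerance = 0.1)
  # extrapolation below the trained floor is flagged and log-log linear
  px <- predict_effort(surf, c(1e-2, 1e-3, 1e-4), 2e6, 0.8)
  expect_equal(px$extrapolated, c(FALSE, TRUE, TRUE))
  r1 <- log10(px$bases[2] / px$bases[1])
  r2 <- log10(px$bases[3] / px$bases[2])
  expect_equal(r1, r2, tolerance = 1e-6)  # exactly linear by construction
  expect_equal(r1, 1, tolerance = 0.15)   # effort doubles per decade: slope -1

  # domain errors name the violated bound
  expect_error(predict_effort(surf, 2e-5, 1e6, 0.8), regexp = "abundance",
               class = "seqeffort_domain_error")
  expect_error(predict_effort(surf, 0.1, 1e9, 0.8), regexp = "genome_size",
               class = "seqeffort_domain_error")
  expect_error(predict_effort(surf, 0.1, 1e6, 0.2),
               regexp = "target_fraction", class = "seqeffort_domain_error")
})

test_that("surface predictions are monotone in all three predictors", {
  surf <- fit_effort_surface(surface_test_table())
  qs <- seq(0.5, 1, length.out = 8)
  ls_ <- 10^seq(log10(5e5), log10(5e6), length.out = 8)
  fs <- 10^seq(-4, 0, length.out = 8)
  lat <- expand.grid(q = qs, l = ls_, f = fs)
  pred <- array(predict_effort(surf, lat$f, lat$l, lat$q)$bases, c(8, 8, 8))
  expect_true(all(apply(pred, c(2, 3), function(v) all(diff(v) >= 0))))
  expect_true(all(apply(pred, c(1, 3), function(v) all(diff(v) >= 0))))
  expect_true(all(apply(pred, c(1, 2), function(v) all(diff(v) <= 0))))
})

test_that("budget inversion is monotone and round-trips", {
  surf <- fit_effort_surface(surface_test_table())
  f0 <- 0.05
  b0 <- predict_effort(surf, f0, 2e6, 0.8)$bases
  inv <- invert_effort(surf, b0, 2e6, 0.8)
  expect_equal(inv$abundance, f0, tolerance = 0.005)
  # a larger budget reaches a rarer genome
  inv2 <- invert_effort(surf, c(b0, 10 * b0), 2e6, 0.8)
  expect_lt(inv2$abundance[2], inv2$abundance[1])
  # budgets outside the predictable span error informatively
  too_small <- predict_effort(surf, 1, 2e6, 0.8)$bases / 10
  expect_error(invert_effort(surf, too_small, 2e6, 0.8),
               class = "seqeffort_domain_error")
})

test_that("serialization round-trips to identical predictions", {
  surf <- fit_effort_surface(surface_test_table())
  p <- tempfile(fileext = ".json")
  write_effort_surface(surf, p)
  back <- read_effort_surface(p)
  probe <- expand.grid(q = c(0.55, 0.8, 0.99), l = c(6e5, 3e6),
                       f = c(1e-3, 0.05, 0.7))
  expect_identical(predict_effort(back, probe$f, probe$l, probe$q)$bases,
                   predict_effort(surf, probe$f, probe$l, probe$q)$bases)
  expect_error(read_effort_surface({
    bad <- tempfile(fileext = ".json")
    jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
    bad
  }), class = "seqeffort_domain_error")
})

test_that("gompertz fits couple with the surface into abundance curves", {
  surf <- fit_effort_surface(surface_test_table())
  counts <- gen_gompertz_counts(12, 1.5, 2, seed = 9)
  fit <- fit_gompertz(counts)
  curves <- effort_to_abundance_curve(fit, surf, target_fraction = 0.8,
                                      genome_sizes = c(5e5, 2e6, 5e6),
                                      n_budgets = 25)
  expect_setequal(unique(curves$genome_size), c(5e5, 2e6, 5e6))
  # MAGs nondecreasing as the cutoff drops (budget rises) per genome size
  for (l in unique(curves$genome_size)) {
    sub <- curves[curves$genome_size == l, ]
    expect_true(all(diff(sub$quality_mags) >= 0))
    expect_true(all(diff(sub$abundance_cutoff) <= 0))
  }
  # smaller genomes reach a rarer cutoff at the same budget
  b_common <- stats::median(curves$bases[curves$genome_size == 2e6])
  cut_small <- invert_effort(surf, b_common, 5e5, 0.8)$abundance
  cut_large <- invert_effort(surf, b_common, 5e6, 0.8)$abundance
  expect_lt(cut_small, cut_large)
  # endpoint: at the minimal budget the cutoff is (near) the most abundant
  first <- curves[curves$genome_size == 2e6, ][1, ]
  expect_gt(first$abundance_cutoff, 0.9)
})
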