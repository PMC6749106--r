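#' Expected reads to sequence a community metagenome to exhaustion
#'
#' Evaluates the non-uniform coupon-collector expectation
#' \deqn{E = \int_0^\infty \big(1 - \prod_j (1 - e^{-p_j t})\big)\, dt}
#' where the product runs over every unique k-mer j with sampling
#' probability p_j. Because all k-mers in a group share one probability w_g,
#' the product collapses to \eqn{\prod_g (1 - e^{-w_g t})^{m_g}} and the
#' integrand is evaluated group-wise in log space (via `log1p`/`expm1`), so
#' populations of 1e8 k-mers cost no more than populations of 10. The
#' integral is split at t = 1 and the tail is integrated in log-t; both
#' pieces use adaptive quadrature to a relative tolerance of about 1e-10.
#'
#' @param community A [community_structure()].
#' @param read_length Read length in bp used to convert reads to bases.
#' @return One-row tibble: `label`, `kmg_size`, `target_fraction` (1),
#'   `expected_reads`, `expected_bases`, `method` (`"integral"`).
#' @examples
#' expected_reads_to_exhaustion(community_even(10))  # 10 * H_10 = 29.29
#' @export
expected_reads_to_exhaustion <- function(community, read_length = 100) {
  stopifnot(inherits(community, "community_structure"))
  check_number(read_length, "read_length", lower = 1, len = 1)
  gw <- kmer_weights(community)
  E <- coupon_integral(gw$m, gw$w)
  tibble::tibble(label = community_label(community),
                 kmg_size = community_size(community),
                 target_fraction = 1,
                 expected_reads = E,
                 expected_bases = E * read_length,
                 method = "integral")
}

# grouped coupon-collector integral; m = group sizes, w = per-k-mer rates
coupon_integral <- function(m, w, rel_tol = 1e-10) {
  integrand <- function(t) {
    S <- colSums(m * log1p(-exp(-outer(w, t))))
    -expm1(S)
  }
  # beyond t_max every surviving term is < 1e-16: integrand negligible
  t_max <- max((log(m) + 37) / w)
  quad <- function(f, lower, upper) {
    res <- tryCatch(
      stats::integrate(f, lower, upper, rel.tol = rel_tol,
                       subdivisions = 2000L),
      error = function(e) {
        abort(paste0("coupon-collector integral failed to converge: ",
                     conditionMessage(e)),
              class = "seqeffort_numeric_error")
      })
    res$value
  }
  head_part <- quad(integrand, 0, 1)
  tail_part <- quad(function(v) {
    t <- exp(v)
    integrand(t) * t
  }, 0, log(t_max))
  head_part + tail_part
}

#' Expected number of distinct k-mers after t reads
#'
#' Occupancy expectation `sum_g m_g (1 - exp(-w_g t))` under independent
#' sampling with replacement; monotone nondecreasing and concave in `reads`,
#' saturating at the population cardinality.
#'
#' @param community A [community_structure()].
#' @param reads Number of sequencing reads (vectorised, >= 0).
#' @return Numeric vector of expected distinct k-mers.
#' @export
expected_distinct <- function(community, reads) {
  stopifnot(inherits(community, "community_structure"))
  check_number(reads, "reads", lower = 0)
  gw <- kmer_weights(community)
  as.numeric(colSums(gw$m * (-expm1(-outer(gw$w, reads)))))
}

#' Expected reads to a target fraction of exhaustion
#'
#' For a target fraction q < 1, solves `expected_distinct(t) = q * |K_MG|`
#' for t by monotone bracketed root finding (solved far below the 0.5-read
#' guarantee). q = 1 is routed through the exact coupon-collector integral
#' of [expected_reads_to_exhaustion()], since the occupancy expectation only
#' reaches the full population in the limit.
#'
#' @param community A [community_structure()].
#' @param target_fraction Fractions of the k-mer population in (0, 1]
#'   (vectorised).
#' @param read_length Read length in bp for the bases conversion.
#' @return A tibble with one row per target fraction: `label`, `kmg_size`,
#'   `target_fraction`, `expected_reads`, `expected_bases`, `method`.
#' @examples
#' expected_reads_to_fraction(community_even(1000), 0.5)  # 1000 * log(2)
#' @export
expected_reads_to_fraction <- function(community, target_fraction,
                                       read_length = 100) {
  stopifnot(inherits(community, "community_structure"))
  check_number(target_fraction, "target_fraction")
  if (any(target_fraction <= 0) || any(target_fraction > 1)) {
    stop_domain("`target_fraction` must lie in (0, 1].")
  }
  check_number(read_length, "read_length", lower = 1, len = 1)
  gw <- kmer_weights(community)
  K <- community_size(community)
  purrr::map_dfr(target_fraction, function(q) {
    if (q == 1) {
      return(expected_reads_to_exhaustion(community, read_length))
    }
    target <- q * K
    f <- function(t) sum(gw$m * (-expm1(-gw$w * t))) - target
    upper <- log(1 / (1 - q)) / min(gw$w)
    while (f(upper) < 0) upper <- upper * 2
    root <- stats::uniroot(f, c(0, upper), tol = max(upper * 1e-13, 1e-10))
    tibble::tibble(label = community_label(community),
                   kmg_size = K,
                   target_fraction = q,
                   expected_reads = root$root,
                   expected_bases = root$root * read_length,
                   method = "root_solve")
  })
}

#' Theoretical effort across metagenome sizes, and its power-law slope
#'
#' `effort_scaling()` holds a community structure fixed while scaling the
#' population cardinality |K_MG| and computes the expected effort to a
#' target fraction at each size. `powerlaw_slope()` then fits an ordinary
#' least-squares regression of log10(expected reads) on log10(|K_MG|) —
#' effort grows as a power of metagenome size, with exponent slightly above
#' one because the coupon-collector tail adds a log factor.
#'
#' @param builder A function `function(total_kmers)` returning a
#'   [community_structure()] of fixed shape, e.g.
#'   `function(n) community_lognormal(n, a = 0.2)`.
#' @param sizes Numeric vector of at least two |K_MG| values.
#' @param target_fraction Single fraction in (0, 1].
#' @param read_length Read length in bp.
#' @return `effort_scaling()`: a tibble with one row per size.
#'   `powerlaw_slope()`: a one-row tibble with `label`, `target_fraction`,
#'   `slope`, `intercept`, `r_squared`, `n_sizes`.
#' @examples
#' sc <- effort_scaling(community_even, sizes = c(1e4, 1e5, 1e6))
#' powerlaw_slope(sc)
#' @export
effort_scaling <- function(builder, sizes, target_fraction = 1,
                           read_length = 100) {
  stopifnot(is.function(builder))
  check_number(sizes, "sizes", lower = 1)
  if (length(sizes) < 2) {
    stop_domain("`sizes` must contain at least two metagenome sizes.")
  }
  check_number(target_fraction, "target_fraction", len = 1)
  purrr::map_dfr(sizes, function(n) {
    expected_reads_to_fraction(builder(n), target_fraction, read_length)
  })
}

#' @rdname effort_scaling
#' @param scaling A tibble from `effort_scaling()` (columns `kmg_size`,
#'   `expected_reads`).
#' @export
powerlaw_slope <- function(scaling) {
  if (!all(c("kmg_size", "expected_reads") %in% names(scaling))) {
    stop_domain("`scaling` needs columns `kmg_size` and `expected_reads`.")
  }
  if (nrow(scaling) < 2) {
    stop_domain("power-law slope needs at least two sizes.")
  }
  fit <- stats::lm(log10(expected_reads) ~ log10(kmg_size), data = scaling)
  r2 <- stats::cor(log10(scaling$expected_reads), stats::fitted(fit))^2
  tibble::tibble(label = scaling$label[1] %||% NA_character_,
                 target_fraction = scaling$target_fraction[1],
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n_sizes = nrow(scaling))
}
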