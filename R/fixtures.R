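#' Synthetic Gompertz rarefaction counts
#'
#' Generates quality-MAG counts along a Gompertz curve with additive
#' Gaussian noise, rounded to nonnegative integers — the shape of a MAG
#' rarefaction experiment with known ground truth, used throughout the test
#' suite. Deterministic under a fixed seed.
#'
#' @param A,mu,lambda Gompertz parameters (see [gompertz_eval()]).
#' @param depths Sequencing depths in Gbp; the default mimics a nine-depth
#'   rarefaction in triplicate spanning 0.2-40 Gbp.
#' @param noise_sd Standard deviation of the additive count noise (>= 0).
#' @param seed Integer seed.
#' @return A tibble: `high_quality_bases_gbp`, `quality`.
#' @examples
#' gen_gompertz_counts(15, 2, 3, seed = 1)
#' @export
gen_gompertz_counts <- function(A, mu, lambda,
                                depths = default_rarefaction_depths(),
                                noise_sd = 0.5, seed = 1) {
  check_number(noise_sd, "noise_sd", lower = 0, len = 1)
  check_number(depths, "depths")
  if (any(depths <= 0)) stop_domain("`depths` must be positive (Gbp).")
  check_number(seed, "seed", len = 1, integerish = TRUE)
  truth <- gompertz_eval(depths, A, mu, lambda)
  set.seed(seed)
  noise <- if (noise_sd > 0) rnorm(length(depths), 0, noise_sd) else 0
  tibble::tibble(high_quality_bases_gbp = depths,
                 quality = round(pmax(0, truth + noise)))
}

#' @rdname gen_gompertz_counts
#' @param n_depths Number of distinct depths.
#' @param replicates Replicates per depth.
#' @param range_gbp Depth span in Gbp.
#' @export
default_rarefaction_depths <- function(n_depths = 9, replicates = 3,
                                       range_gbp = c(0.2, 40)) {
  rep(exp(seq(log(range_gbp[1]), log(range_gbp[2]),
              length.out = n_depths)), each = replicates)
}

#' Synthetic per-MAG record table realising a quality curve
#'
#' Expands per-depth quality-MAG counts into individual MAG rows
#' (completeness/contamination draws inside the medium- or high-quality
#' boxes) plus unclassified distractor rows, so that running
#' [count_quality_mags()] on the output reproduces the requested counts
#' exactly. Replicate ids are assigned by occurrence order within each
#' depth. Deterministic under a fixed seed.
#'
#' @param environment Environment label.
#' @param quality_curve A tibble from [gen_gompertz_counts()] (columns
#'   `high_quality_bases_gbp`, `quality`).
#' @param high_fraction Fraction of quality MAGs drawn as high quality.
#' @param distractors Unclassified rows added per depth.
#' @param seed Integer seed.
#' @return A MAG record tibble accepted by [count_quality_mags()].
#' @export
gen_mag_table <- function(environment, quality_curve, high_fraction = 0.3,
                          distractors = 4, seed = 1) {
  need <- c("high_quality_bases_gbp", "quality")
  miss <- setdiff(need, names(quality_curve))
  if (length(miss)) {
    abort(paste0("`quality_curve` is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "seqeffort_schema_error")
  }
  if (any(quality_curve$quality < 0)) {
    stop_domain("`quality` counts must be nonnegative.")
  }
  check_number(seed, "seed", len = 1, integerish = TRUE)
  set.seed(seed)
  qc <- tibble::as_tibble(quality_curve)
  qc$replicate <- stats::ave(seq_len(nrow(qc)), qc$high_quality_bases_gbp,
                             FUN = seq_along)
  rows <- purrr::pmap_dfr(qc, function(high_quality_bases_gbp, quality,
                                       replicate, ...) {
    n_high <- round(high_fraction * quality)
    n_med <- quality - n_high
    comp <- c(runif(n_high, 90.5, 99.9), runif(n_med, 50.5, 89.5),
              runif(distractors, 5, 49.5))
    cont <- c(runif(n_high, 0, 4.5), runif(n_med, 0, 9.5),
              runif(distractors, 0, 30))
    tibble::tibble(environment = environment,
                   replicate = replicate,
                   high_quality_bases_gbp = high_quality_bases_gbp,
                   bin_id = sprintf("%s_b%.3g_r%d_%02d", environment,
                                    high_quality_bases_gbp, replicate,
                                    seq_along(comp)),
                   completeness_pct = comp,
                   contamination_pct = cont)
  })
  rows
}

#' The four standard hypothetical community structures
#'
#' Even; moderately uneven (90% of the sampling mass on 50% of the k-mers);
#' highly uneven (90% on 10%); and lognormal with `a = 0.2` over 10 equal
#' octave groups. Sized for fast testing by default; evenness strictly
#' decreases along the list.
#'
#' @param total_kmers Population cardinality for each structure.
#' @return A named list of four [community_structure()] objects.
#' @examples
#' suite <- gen_community_suite(1e4)
#' sapply(suite, pielou_evenness)
#' @export
gen_community_suite <- function(total_kmers = 1e5) {
  list(
    even = community_even(total_kmers),
    tiered_moderate = community_tiered(total_kmers, 0.9, 0.5,
                                       label = "tiered_moderate"),
    tiered_low = community_tiered(total_kmers, 0.9, 0.1,
                                  label = "tiered_low"),
    lognormal = community_lognormal(total_kmers, a = 0.2))
}

# Gompertz parameters representative of published environmental rarefaction
# surveys (ocean surface water, estuarine sediment, maize soil, human gut);
# used only to parameterise synthetic data.
mag_survey_params <- function() {
  tibble::tibble(
    environment = c("ocean_surface_water", "estuary_sediment",
                    "maize_soil", "human_gut"),
    A = c(14.4, 9.6, 19.0, 14.6),
    mu = c(1.1, 1.0, 0.9, 3.8),
    lambda = c(1.2, 3.7, 6.1, 0.6),
    max_depth_gbp = c(33.4, 15.9, 38.2, 4.8))
}

#' Synthetic four-environment MAG rarefaction survey
#'
#' A fully synthetic stand-in for a multi-environment MAG rarefaction data
#' set: per-MAG records for four environments whose quality-MAG counts
#' follow Gompertz curves with parameters representative of published ocean,
#' sediment, soil and gut surveys, rarefied at nine depths in triplicate up
#' to each environment's sequencing depth. Counts carry additive Gaussian
#' noise (SD 0.5 MAGs by default) before integer rounding; purely rounded
#' noiseless counts systematically bias the fitted lag upward, so a
#' realistic replicate scatter keeps fits unbiased.
#'
#' @param seed Integer seed.
#' @param noise_sd Additive count noise SD.
#' @return A MAG record tibble covering all four environments.
#' @export
synthetic_mag_survey <- function(seed = 1, noise_sd = 0.5) {
  params <- mag_survey_params()
  purrr::pmap_dfr(params, function(environment, A, mu, lambda,
                                   max_depth_gbp) {
    depths <- default_rarefaction_depths(
      range_gbp = c(max_depth_gbp / 100, max_depth_gbp))
    counts <- gen_gompertz_counts(A, mu, lambda, depths, noise_sd = noise_sd,
                                  seed = seed + match(environment,
                                                      params$environment))
    gen_mag_table(environment, counts,
                  seed = seed + 100 + match(environment, params$environment))
  })
}

#' Write the fixture files used by the command-line interface
#'
#' Writes `mags.csv` (synthetic four-environment MAG survey),
#' `gompertz_counts.csv` (one noisy rarefaction curve) and
#' `communities.json` (the four standard structures as family specs) under
#' `dir`. Byte-identical output under a fixed seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
write_fixture_files <- function(dir, seed = 7) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mags = file.path(dir, "mags.csv"),
             counts = file.path(dir, "gompertz_counts.csv"),
             communities = file.path(dir, "communities.json"))
  write_results(synthetic_mag_survey(seed = seed), paths["mags"],
                meta = list(seed = seed))
  write_results(gen_gompertz_counts(15, 2, 3, seed = seed), paths["counts"],
                meta = list(seed = seed, A = 15, mu = 2, lambda = 3))
  specs <- list(
    list(family = "even", total_kmers = 1e5),
    list(family = "tiered", total_kmers = 1e5, mass_fraction = 0.9,
         kmer_fraction = 0.5),
    list(family = "tiered", total_kmers = 1e5, mass_fraction = 0.9,
         kmer_fraction = 0.1),
    list(family = "lognormal", total_kmers = 1e5, a = 0.2))
  jsonlite::write_json(specs, paths["communities"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
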