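#' Simulate shotgun sequencing of a community metagenome
#'
#' Monte-Carlo counterpart of the coupon-collector theory: reads are drawn
#' with replacement from the community's weighted k-mer population (a group
#' is chosen by its probability mass, then a k-mer uniformly within it), a
#' per-k-mer occupancy bitmap tracks which k-mers have been seen, and the
#' read index at which each target fraction of the population is first
#' covered is recorded. `record_mode = "exact_crossing"` (default) reports
#' the precise read index; `"checkpoint"` rounds it up to the next multiple
#' of `checkpoint` reads, mimicking pipelines that evaluate coverage only at
#' fixed intervals (e.g. every 1e7 reads).
#'
#' Replicates use independent RNG substreams derived deterministically from
#' `seed`, so the same seed always reproduces the same table bit for bit.
#'
#' @param community A [community_structure()].
#' @param targets Target fractions of |K_MG| in (0, 1].
#' @param seed Integer seed.
#' @param replicates Number of independent replicates (>= 1).
#' @param read_length Read length in bp for the bases conversion.
#' @param checkpoint Reads between coverage evaluations in `"checkpoint"`
#'   mode.
#' @param record_mode `"exact_crossing"` or `"checkpoint"`.
#' @param max_kmers Guard on |K_MG| (occupancy memory cap).
#' @param max_reads Guard on simulated reads per replicate.
#' @return A tibble with one row per (replicate, target): `label`,
#'   `kmg_size`, `replicate`, `target_fraction`, `reads`, `bases`, `seed`.
#' @examples
#' sim <- simulate_community_sequencing(community_even(1000),
#'                                      targets = c(0.5, 1), seed = 1)
#' @export
simulate_community_sequencing <- function(community, targets, seed,
                                          replicates = 3, read_length = 100,
                                          checkpoint = 1e7,
                                          record_mode = c("exact_crossing",
                                                          "checkpoint"),
                                          max_kmers = 2e8, max_reads = 1e10) {
  stopifnot(inherits(community, "community_structure"))
  check_number(targets, "targets")
  if (any(targets <= 0) || any(targets > 1)) {
    stop_domain("`targets` must lie in (0, 1].")
  }
  check_number(seed, "seed", len = 1, integerish = TRUE)
  check_number(replicates, "replicates", lower = 1, len = 1,
               integerish = TRUE)
  check_number(checkpoint, "checkpoint", lower = 1, len = 1)
  record_mode <- match.arg(record_mode)
  K <- community_size(community)
  if (K > max_kmers) {
    stop_domain(sprintf(
      "|K_MG| = %g exceeds the memory guard `max_kmers` = %g.", K, max_kmers))
  }

  ord <- order(targets)
  q_sorted <- targets[ord]
  counts <- pmin(ceiling(q_sorted * K), K)

  # abundant groups first shortens the per-read group scan
  comm_ord <- order(community$mass / community$size, decreasing = TRUE)
  sizes <- community$size[comm_ord]
  masses <- community$mass[comm_ord]

  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 2 * replicates),
                      nrow = 2)
  out <- purrr::map_dfr(seq_len(replicates), function(r) {
    reads <- cpp_simulate_community(sizes, masses, counts, max_reads,
                                    rep_seeds[, r])
    if (anyNA(reads)) {
      abort(sprintf("replicate %d hit the `max_reads` cap (%g) before %s",
                    r, max_reads, "reaching every target fraction."),
            class = "seqeffort_numeric_error")
    }
    if (record_mode == "checkpoint") {
      reads <- ceiling(reads / checkpoint) * checkpoint
    }
    tibble::tibble(label = community_label(community),
                   kmg_size = K,
                   replicate = r,
                   target_fraction = q_sorted,
                   reads = reads,
                   bases = reads * read_length,
                   seed = seed)
  })
  out[order(out$replicate, match(out$target_fraction, targets)), ]
}

#' Simulate sequencing effort for one genome of given rarity
#'
#' Simulates the reads needed to observe a target fraction `q` of the
#' `K = genome_length - read_length + 1` unique k-mers of a single genome
#' whose k-mers make up a fraction `abundance` of the community's k-mer
#' pool. Only "hit" draws (reads landing on the target genome) need
#' simulating: the coupon-collection time over the genome's equiprobable
#' k-mers gives the number of hits h, and the total read count is h plus a
#' negative-binomial number of off-target reads (h successes at success
#' probability `abundance`). At `abundance = 1` this reduces exactly to
#' community coupon collection on K k-mers.
#'
#' @param genome_length Genome length in bp.
#' @param abundance Relative abundance of the genome's k-mers in (0, 1].
#' @param target_fraction Fraction of the genome's k-mers to observe,
#'   in (0, 1].
#' @param seed Integer seed.
#' @param replicates Number of replicates.
#' @param read_length Read length in bp.
#' @return A tibble with one row per replicate: `genome_length`,
#'   `kmer_count`, `abundance`, `target_fraction`, `replicate`, `hits`,
#'   `reads`, `bases`, `seed`.
#' @examples
#' simulate_genome_effort(1e5, abundance = 0.5, target_fraction = 0.5,
#'                        seed = 1)
#' @export
simulate_genome_effort <- function(genome_length, abundance, target_fraction,
                                   seed, replicates = 3, read_length = 100) {
  check_number(abundance, "abundance", len = 1)
  if (abundance <= 0 || abundance > 1) {
    stop_domain("`abundance` must lie in (0, 1].")
  }
  check_number(target_fraction, "target_fraction", len = 1)
  if (target_fraction <= 0 || target_fraction > 1) {
    stop_domain("`target_fraction` must lie in (0, 1].")
  }
  check_number(seed, "seed", len = 1, integerish = TRUE)
  check_number(replicates, "replicates", lower = 1, len = 1,
               integerish = TRUE)
  K <- kmer_count(genome_length, read_length)
  if (target_fraction * K < 1) {
    stop_domain("`target_fraction * kmer_count` must be >= 1.")
  }
  d <- ceiling(target_fraction * K)

  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 2 * replicates),
                      nrow = 2)
  purrr::map_dfr(seq_len(replicates), function(r) {
    hits <- cpp_coupon_hits(K, d, rep_seeds[, r])
    misses <- if (abundance < 1) rnbinom(1, size = hits, prob = abundance) else 0
    reads <- hits + misses
    tibble::tibble(genome_length = genome_length,
                   kmer_count = K,
                   abundance = abundance,
                   target_fraction = target_fraction,
                   replicate = r,
                   hits = hits,
                   reads = reads,
                   bases = reads * read_length,
                   seed = seed)
  })
}

#' Convert sequencing reads to bases
#'
#' @param reads Read counts (>= 0).
#' @param read_length Read length in bp (>= 1).
#' @return `reads * read_length`.
#' @examples
#' reads_to_bases(1e6, 100)
#' @export
reads_to_bases <- function(reads, read_length) {
  check_number(reads, "reads", lower = 0)
  check_number(read_length, "read_length", lower = 1)
  reads * read_length
}

#' Summarise replicate sequencing efforts
#'
#' Mean, sample standard deviation and standard error of reads and bases per
#' target fraction across replicates.
#'
#' @param sim A tibble from [simulate_community_sequencing()] or
#'   [simulate_genome_effort()].
#' @return A tibble with one row per target fraction.
#' @export
effort_summary <- function(sim) {
  if (!all(c("target_fraction", "reads", "bases") %in% names(sim))) {
    stop_domain("`sim` needs columns `target_fraction`, `reads`, `bases`.")
  }
  dplyr::summarise(
    dplyr::group_by(sim, .data$target_fraction),
    replicates = dplyr::n(),
    mean_reads = mean(.data$reads),
    sd_reads = sd(.data$reads),
    se_reads = sd(.data$reads) / sqrt(dplyr::n()),
    mean_bases = mean(.data$bases),
    sd_bases = sd(.data$bases),
    .groups = "drop")
}
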