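#' Community metagenome structures
#'
#' A community metagenome is modelled as a finite population of unique k-mers
#' partitioned into groups: all k-mers within a group are sampled with the
#' same probability, and a group is described by its `size` (number of unique
#' k-mers) and its `mass` (the total sampling probability it carries). Groups
#' arise naturally because every k-mer of one genome is equiprobable, so a
#' community of s genome classes needs only s rows regardless of how many
#' k-mers it contains. Identical k-mer sequences at different loci count as
#' distinct population members; no sequence content is ever materialised.
#'
#' `community_structure()` builds a structure from explicit group sizes and
#' masses. Masses are normalised to sum to one; the per-k-mer sampling
#' probability within group g is `mass[g] / size[g]`.
#'
#' @param size Positive integer vector: unique k-mers per group.
#' @param mass Nonnegative vector, same length: sampling-probability mass per
#'   group. Normalised to sum to 1.
#' @param label Free-text label carried through results.
#' @return A tibble of class `community_structure` with columns `group`,
#'   `size`, `mass` and a `label` attribute.
#' @examples
#' community_structure(size = c(10, 90), mass = c(0.9, 0.1), label = "toy")
#' @export
community_structure <- function(size, mass, label = "community") {
  check_number(size, "size", lower = 1, integerish = TRUE)
  if (!is.numeric(mass) || anyNA(mass) || any(mass < 0)) {
    stop_domain("`mass` must be nonnegative and non-missing.")
  }
  if (length(size) != length(mass)) {
    stop_domain("`size` and `mass` must have the same length.")
  }
  if (sum(mass) <= 0) stop_domain("total `mass` must be positive.")
  mass <- mass / sum(mass)
  out <- tibble::tibble(group = seq_along(size),
                        size = as.numeric(round(size)),
                        mass = mass)
  structure(out,
            class = c("community_structure", class(out)),
            label = label)
}

#' @export
print.community_structure <- function(x, ...) {
  cat(sprintf("<community_structure: %s>  |K_MG| = %s, %d group(s)\n",
              community_label(x), format(community_size(x), big.mark = ","),
              nrow(x)))
  NextMethod()
}

#' Total number of unique k-mers and label of a community structure
#'
#' @param community A [community_structure()].
#' @return `community_size()`: the population cardinality (sum of group
#'   sizes). `community_label()`: the label string.
#' @export
community_size <- function(community) {
  stopifnot(inherits(community, "community_structure"))
  sum(community$size)
}

#' @rdname community_size
#' @export
community_label <- function(community) {
  attr(community, "label") %||% "community"
}

# per-k-mer sampling probabilities by group, zero-mass groups dropped
kmer_weights <- function(community) {
  keep <- community$mass > 0
  list(m = community$size[keep], w = community$mass[keep] / community$size[keep])
}

#' Number of unique k-mers in a genome
#'
#' A genome of length `genome_length` bp read at length `read_length` bp
#' exposes `genome_length - read_length + 1` distinct read windows (k-mers).
#'
#' @param genome_length Genome length in bp (>= `read_length`).
#' @param read_length Read length in bp (>= 1).
#' @return Integer-valued count of unique k-mers.
#' @examples
#' kmer_count(1e6, 100)  # 999901
#' @export
kmer_count <- function(genome_length, read_length) {
  check_number(genome_length, "genome_length", lower = 1, integerish = TRUE)
  check_number(read_length, "read_length", lower = 1, integerish = TRUE)
  if (any(genome_length < read_length)) {
    stop_domain("`genome_length` must be at least `read_length`.")
  }
  genome_length - read_length + 1
}

#' Build the standard hypothetical community structures
#'
#' `community_even()` puts every k-mer at equal probability (one group).
#' `community_tiered()` splits the population in two tiers: a fraction
#' `kmer_fraction` of the k-mers carries `mass_fraction` of the total
#' sampling probability and the remainder carries the rest, e.g. "90% of the
#' sampling mass on 50% of the k-mers" for a moderately uneven community.
#' `community_lognormal()` uses `octaves` equally sized groups whose masses
#' follow a Preston-style lognormal species-abundance curve
#' `S(R) = s0 * exp(-a^2 * R^2)` over octave indices `R = 0..octaves-1`
#' (`exponent = "a"` switches to `exp(-a * R^2)`; both parameterisations are
#' in circulation). With `a = 0` all groups are equiprobable and the
#' structure is statistically identical to the even community.
#'
#' @param total_kmers Population cardinality |K_MG| (>= 1).
#' @param mass_fraction,kmer_fraction Tier fractions in (0, 1).
#' @param a Inverse width of the lognormal abundance curve (>= 0).
#' @param s0 Maximum relative abundance (scale factor; cancels on
#'   normalisation).
#' @param octaves Number of equally sized abundance groups.
#' @param exponent `"a_squared"` (default) uses `exp(-a^2 R^2)`; `"a"` uses
#'   `exp(-a R^2)`.
#' @param label Structure label.
#' @return A [community_structure()].
#' @examples
#' community_even(1e6)
#' community_tiered(1e6, 0.9, 0.5)
#' community_lognormal(1e6, a = 0.2)
#' @export
community_even <- function(total_kmers, label = "even") {
  check_number(total_kmers, "total_kmers", lower = 1, len = 1,
               integerish = TRUE)
  community_structure(size = total_kmers, mass = 1, label = label)
}

#' @rdname community_even
#' @export
community_tiered <- function(total_kmers, mass_fraction = 0.9,
                             kmer_fraction = 0.5,
                             label = sprintf("tiered_%g_%g", mass_fraction,
                                             kmer_fraction)) {
  check_number(total_kmers, "total_kmers", lower = 2, len = 1,
               integerish = TRUE)
  check_number(mass_fraction, "mass_fraction", len = 1)
  check_number(kmer_fraction, "kmer_fraction", len = 1)
  if (mass_fraction <= 0 || mass_fraction >= 1 ||
      kmer_fraction <= 0 || kmer_fraction >= 1) {
    stop_domain("`mass_fraction` and `kmer_fraction` must lie in (0, 1).")
  }
  abundant <- round(kmer_fraction * total_kmers)
  rare <- total_kmers - abundant
  if (abundant < 1 || rare < 1) {
    stop_domain("tier fractions round to an empty group; increase `total_kmers`.")
  }
  community_structure(size = c(abundant, rare),
                      mass = c(mass_fraction, 1 - mass_fraction),
                      label = label)
}

#' @rdname community_even
#' @export
community_lognormal <- function(total_kmers, a, s0 = 1, octaves = 10,
                                exponent = c("a_squared", "a"),
                                label = sprintf("lognormal_a%g", a)) {
  check_number(total_kmers, "total_kmers", lower = 1, len = 1,
               integerish = TRUE)
  check_number(a, "a", lower = 0, len = 1)
  check_number(s0, "s0", len = 1)
  check_number(octaves, "octaves", lower = 1, len = 1, integerish = TRUE)
  if (s0 <= 0) stop_domain("`s0` must be positive.")
  if (total_kmers < octaves) {
    stop_domain("`total_kmers` must be at least `octaves`.")
  }
  exponent <- match.arg(exponent)
  coefv <- if (exponent == "a_squared") a^2 else a
  R <- seq_len(octaves) - 1
  mass <- s0 * exp(-coefv * R^2)
  base <- total_kmers %/% octaves
  size <- rep(base, octaves)
  # leftover k-mers join the most abundant group (R = 0), deterministically
  size[1] <- size[1] + total_kmers - base * octaves
  community_structure(size = size, mass = mass, label = label)
}

#' Shannon diversity of a community metagenome
#'
#' Shannon entropy (nats) of the per-k-mer sampling distribution,
#' `H = sum_j -p_j log(p_j)` over the whole k-mer population, computed
#' group-wise (each group contributes `size * (-w log w)` with `w` its
#' per-k-mer probability) so the population is never enumerated.
#'
#' @param community A [community_structure()].
#' @return Entropy in nats.
#' @examples
#' shannon_metagenome(community_even(1000))  # log(1000)
#' @export
shannon_metagenome <- function(community) {
  stopifnot(inherits(community, "community_structure"))
  gw <- kmer_weights(community)
  sum(gw$m * (-gw$w * log(gw$w)))
}

#' Pielou evenness of a community metagenome
#'
#' Shannon entropy relative to its maximum, `J = H / log(|K_MG|)` at the
#' k-mer level (the default), so `J = 1` exactly when all per-k-mer
#' probabilities are equal. `level = "group"` instead compares the entropy
#' of the group masses with `log(number of groups)`, the coarse-grained
#' variant used when groups are the ecological unit of interest. J is
#' invariant to the logarithm base and to group relabelling.
#'
#' @param community A [community_structure()].
#' @param level `"kmer"` (default) or `"group"`.
#' @return Evenness in (0, 1].
#' @examples
#' pielou_evenness(community_tiered(1e4, 0.9, 0.5))
#' @export
pielou_evenness <- function(community, level = c("kmer", "group")) {
  stopifnot(inherits(community, "community_structure"))
  level <- match.arg(level)
  if (level == "kmer") {
    K <- community_size(community)
    if (K < 2) stop_domain("evenness needs at least 2 k-mers (H_max > 0).")
    shannon_metagenome(community) / log(K)
  } else {
    mass <- community$mass[community$mass > 0]
    if (nrow(community) < 2) {
      stop_domain("group-level evenness needs at least 2 groups.")
    }
    sum(-mass * log(mass)) / log(nrow(community))
  }
}

#' Normalised rank-abundance profile
#'
#' Group masses sorted in descending order, with ranks normalised by the
#' number of groups (`normalized_rank = rank / s`) so profiles of
#' populations of different cardinality are comparable.
#'
#' @param community A [community_structure()].
#' @return A tibble with columns `rank`, `normalized_rank`, `mass`.
#' @export
rank_abundance <- function(community) {
  stopifnot(inherits(community, "community_structure"))
  mass <- sort(community$mass, decreasing = TRUE)
  s <- length(mass)
  tibble::tibble(rank = seq_len(s),
                 normalized_rank = seq_len(s) / s,
                 mass = mass)
}

#' Plot a community's rank-abundance profile
#'
#' @param object A [community_structure()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.community_structure <- function(object, ...) {
  df <- rank_abundance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$normalized_rank, y = .data$mass)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "normalised rank", y = "group probability mass",
                  title = community_label(object)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
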