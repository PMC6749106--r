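#' Simulation grid for the single-genome effort surface
#'
#' Defines the lattice of (target fraction, relative abundance, genome size)
#' cells over which [run_simulation_grid()] simulates required sequencing
#' effort. The full-study grid uses 100 linearly spaced target fractions on
#' \[0.5, 1\], 30 log-spaced abundances on \[0.01, 1\] and genome sizes
#' {0.5, 1, 2, 3, 5, 10, 15, 20} Mbp in triplicate at 100 bp reads
#' (`surface_grid_full()`); the default `surface_grid()` is a coarser grid
#' of the same span that fits interactive time budgets.
#'
#' @param n_target Number of linearly spaced target fractions on
#'   `target_range`.
#' @param n_abundance Number of log-spaced abundances on `abundance_range`.
#' @param genome_sizes Genome sizes in bp.
#' @param target_range,abundance_range Spans of the two continuous axes.
#' @param replicates Simulation replicates per cell.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return A list of class `surface_grid`.
#' @export
surface_grid <- function(n_target = 12, n_abundance = 8,
                         genome_sizes = c(0.5, 1, 2, 3, 5, 10, 15, 20) * 1e6,
                         target_range = c(0.5, 1),
                         abundance_range = c(0.01, 1),
                         replicates = 3, read_length = 100, seed = 1) {
  check_number(n_target, "n_target", lower = 2, len = 1, integerish = TRUE)
  check_number(n_abundance, "n_abundance", lower = 2, len = 1,
               integerish = TRUE)
  check_number(genome_sizes, "genome_sizes", lower = 1)
  check_number(replicates, "replicates", lower = 1, len = 1,
               integerish = TRUE)
  check_number(seed, "seed", len = 1, integerish = TRUE)
  if (target_range[1] <= 0 || target_range[2] > 1 ||
      target_range[1] >= target_range[2]) {
    stop_domain("`target_range` must be increasing within (0, 1].")
  }
  if (abundance_range[1] <= 0 || abundance_range[2] > 1 ||
      abundance_range[1] >= abundance_range[2]) {
    stop_domain("`abundance_range` must be increasing within (0, 1].")
  }
  structure(list(
    target_fractions = seq(target_range[1], target_range[2],
                           length.out = n_target),
    abundances = 10^seq(log10(abundance_range[1]), log10(abundance_range[2]),
                        length.out = n_abundance),
    genome_sizes = sort(genome_sizes),
    replicates = replicates,
    read_length = read_length,
    seed = seed), class = "surface_grid")
}

#' @rdname surface_grid
#' @export
surface_grid_full <- function(replicates = 3, seed = 1) {
  surface_grid(n_target = 100, n_abundance = 30, replicates = replicates,
               seed = seed)
}

#' Run the single-genome simulation grid
#'
#' Simulates [simulate_genome_effort()] for every grid cell and records the
#' replicate-mean effort. Cell seeds are derived deterministically from the
#' grid seed, so the same grid always yields the same table.
#'
#' @param grid A [surface_grid()].
#' @return A tibble with one row per cell: `target_fraction`, `genome_size`,
#'   `abundance`, `mean_reads`, `mean_bases`, `sd_bases`, plus grid metadata
#'   in attributes `read_length`, `replicates`, `seed`.
#' @export
run_simulation_grid <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  cells <- tidyr::expand_grid(target_fraction = grid$target_fractions,
                              genome_size = grid$genome_sizes,
                              abundance = grid$abundances)
  set.seed(grid$seed)
  cells$cell_seed <- sample.int(.Machine$integer.max, nrow(cells))
  out <- purrr::pmap_dfr(cells, function(target_fraction, genome_size,
                                         abundance, cell_seed) {
    sim <- simulate_genome_effort(genome_size, abundance, target_fraction,
                                  seed = cell_seed,
                                  replicates = grid$replicates,
                                  read_length = grid$read_length)
    tibble::tibble(target_fraction = target_fraction,
                   genome_size = genome_size,
                   abundance = abundance,
                   mean_reads = mean(sim$reads),
                   mean_bases = mean(sim$bases),
                   sd_bases = sd(sim$bases))
  })
  attr(out, "read_length") <- grid$read_length
  attr(out, "replicates") <- grid$replicates
  attr(out, "seed") <- grid$seed
  out
}

#' Fit the smooth effort surface
#'
#' Penalized additive spline regression of log10(mean bases) on smooth terms
#' of the target fraction, log10 genome size and log10 relative abundance,
#' with smoothing parameters selected by generalized cross-validation
#' (`mgcv::gam`, P-spline bases). The default basis dimensions (50, 6, 29)
#' are clipped to the number of distinct values each predictor takes in the
#' training table; a predictor with fewer than three distinct values enters
#' linearly. The log transforms are chosen because occupancy theory makes
#' log10(bases) close to additive and linear in log10(size) and
#' log10(abundance).
#'
#' @param table A tibble from [run_simulation_grid()] (columns
#'   `target_fraction`, `genome_size`, `abundance`, `mean_bases`).
#' @param basis_dims Basis dimensions for (target fraction, genome size,
#'   abundance).
#' @param read_length Read length in bp (taken from the table attribute when
#'   present).
#' @return An object of class `effort_surface`.
#' @export
fit_effort_surface <- function(table, basis_dims = c(50, 6, 29),
                               read_length = NULL) {
  need <- c("target_fraction", "genome_size", "abundance", "mean_bases")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_domain(paste0("`table` is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (any(table$mean_bases <= 0)) {
    stop_domain("all `mean_bases` must be positive.")
  }
  check_number(basis_dims, "basis_dims", lower = 1, len = 3)
  read_length <- read_length %||% attr(table, "read_length") %||% 100

  df <- tibble::tibble(y = log10(table$mean_bases),
                       q = table$target_fraction,
                       ll = log10(table$genome_size),
                       lf = log10(table$abundance))
  term_for <- function(var, k_max) {
    nu <- length(unique(df[[var]]))
    if (nu < 2) {
      stop_domain(sprintf("predictor `%s` needs >= 2 distinct values.", var))
    }
    if (nu < 5) return(var)  # too few values for a cubic P-spline: linear term
    sprintf("s(%s, k = %d, bs = \"ps\")", var, min(k_max, nu - 1))
  }
  form <- stats::as.formula(paste(
    "y ~", paste(c(term_for("q", basis_dims[1]),
                   term_for("ll", basis_dims[2]),
                   term_for("lf", basis_dims[3])), collapse = " + ")))
  model <- tryCatch(
    mgcv::gam(form, data = df, method = "GCV.Cp"),
    error = function(e) {
      abort(paste0("effort surface fit failed: ", conditionMessage(e)),
            class = "seqeffort_fit_error")
    })
  structure(list(
    model = model,
    table = tibble::as_tibble(table[, need]),
    basis_dims = basis_dims,
    read_length = read_length,
    domain = list(target_fraction = range(table$target_fraction),
                  genome_size = range(table$genome_size),
                  abundance = range(table$abundance)),
    replicates = attr(table, "replicates") %||% NA_integer_,
    seed = attr(table, "seed") %||% NA_integer_,
    r_squared = stats::cor(stats::fitted(model), df$y)^2,
    residual_sd = stats::sd(stats::residuals(model))),
    class = "effort_surface")
}

#' @export
print.effort_surface <- function(x, ...) {
  cat(sprintf(paste0("<effort_surface> %d cells, R^2 = %.4f, residual SD ",
                     "(log10 bases) = %.4f\n"),
              nrow(x$table), x$r_squared, x$residual_sd))
  cat(sprintf("  target fraction [%g, %g], genome size [%g, %g] bp, %s\n",
              x$domain$target_fraction[1], x$domain$target_fraction[2],
              x$domain$genome_size[1], x$domain$genome_size[2],
              sprintf("abundance [%g, %g]", x$domain$abundance[1],
                      x$domain$abundance[2])))
  invisible(x)
}

#' @export
glance.effort_surface <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$table),
                 r_squared = x$r_squared,
                 residual_sd = x$residual_sd,
                 read_length = x$read_length,
                 replicates = x$replicates,
                 seed = x$seed)
}

#' @export
tidy.effort_surface <- function(x, ...) {
  s <- summary(x$model)
  if (length(s$s.table)) {
    st <- as.data.frame(s$s.table)
    tibble::tibble(term = rownames(st), edf = st$edf, ref_df = st$`Ref.df`)
  } else {
    tibble::tibble(term = character(), edf = numeric(), ref_df = numeric())
  }
}

# internal: predict log10(bases) inside the trained abundance span
surface_log10_bases <- function(surface, q, genome_size, abundance) {
  newd <- data.frame(q = q, ll = log10(genome_size), lf = log10(abundance))
  as.numeric(predict(surface$model, newdata = newd))
}

#' Predict required sequencing bases from the effort surface
#'
#' Evaluates the fitted surface at the requested (abundance, genome size,
#' target fraction). Below the trained abundance floor (1% on the standard
#' grid) the prediction extrapolates linearly in (log10 abundance,
#' log10 bases) using the slope of the surface at the boundary — theory puts
#' that slope at -1, since effort scales as 1/abundance — down to an
#' abundance of 1e-4; such predictions are flagged `extrapolated`.
#'
#' @param surface An [fit_effort_surface()] object.
#' @param abundance Relative abundances in \[1e-4, 1\].
#' @param genome_size Genome sizes in bp, within the trained span.
#' @param target_fraction Target fractions within the trained span
#'   (\[0.5, 1\] on the standard grid).
#' @return A tibble: `abundance`, `genome_size`, `target_fraction`, `bases`,
#'   `reads`, `extrapolated`. Inputs are recycled to a common length.
#' @export
predict_effort <- function(surface, abundance, genome_size, target_fraction) {
  stopifnot(inherits(surface, "effort_surface"))
  n <- max(length(abundance), length(genome_size), length(target_fraction))
  abundance <- rep_len(abundance, n)
  genome_size <- rep_len(genome_size, n)
  target_fraction <- rep_len(target_fraction, n)
  dom <- surface$domain
  if (any(abundance < 1e-4 - 1e-12) || any(abundance > 1)) {
    stop_domain("`abundance` outside the supported span [1e-4, 1].")
  }
  if (any(target_fraction < dom$target_fraction[1] - 1e-9) ||
      any(target_fraction > dom$target_fraction[2] + 1e-9)) {
    stop_domain(sprintf("`target_fraction` outside the trained span [%g, %g].",
                        dom$target_fraction[1], dom$target_fraction[2]))
  }
  if (any(genome_size < dom$genome_size[1] - 1e-6) ||
      any(genome_size > dom$genome_size[2] + 1e-6)) {
    stop_domain(sprintf("`genome_size` outside the trained span [%g, %g] bp.",
                        dom$genome_size[1], dom$genome_size[2]))
  }
  f_lo <- dom$abundance[1]
  extrap <- abundance < f_lo
  lb <- numeric(n)
  if (any(!extrap)) {
    lb[!extrap] <- surface_log10_bases(surface, target_fraction[!extrap],
                                       genome_size[!extrap],
                                       abundance[!extrap])
  }
  if (any(extrap)) {
    dlf <- 0.1  # finite-difference step (log10 units) for the boundary slope
    at_lo <- surface_log10_bases(surface, target_fraction[extrap],
                                 genome_size[extrap], rep(f_lo, sum(extrap)))
    above <- surface_log10_bases(surface, target_fraction[extrap],
                                 genome_size[extrap],
                                 rep(f_lo * 10^dlf, sum(extrap)))
    slope <- (above - at_lo) / dlf
    lb[extrap] <- at_lo + slope * (log10(abundance[extrap]) - log10(f_lo))
  }
  bases <- 10^lb
  tibble::tibble(abundance = abundance,
                 genome_size = genome_size,
                 target_fraction = target_fraction,
                 bases = bases,
                 reads = bases / surface$read_length,
                 extrapolated = extrap)
}

#' Invert the effort surface: budget to abundance cutoff
#'
#' Finds the smallest (rarest) relative abundance whose predicted effort
#' equals a sequencing budget, by bisection in log10 abundance (tolerance
#' 1e-3 log10 units). Any genome at least that abundant is sequenced to the
#' target fraction within the budget.
#'
#' @param surface An [fit_effort_surface()] object.
#' @param bases Sequencing budgets in bases (> 0).
#' @param genome_size Genome size in bp.
#' @param target_fraction Target fraction of exhaustion.
#' @return A tibble: `bases`, `genome_size`, `target_fraction`, `abundance`,
#'   `extrapolated`.
#' @export
invert_effort <- function(surface, bases, genome_size, target_fraction) {
  stopifnot(inherits(surface, "effort_surface"))
  check_number(bases, "bases")
  if (any(bases <= 0)) stop_domain("`bases` must be positive.")
  pred1 <- function(f) {
    predict_effort(surface, f, genome_size, target_fraction)$bases
  }
  lo_f <- 1e-4
  min_bases <- pred1(1)
  max_bases <- pred1(lo_f)
  purrr::map_dfr(bases, function(b) {
    if (b < min_bases) {
      abort(sprintf(paste0("budget %g bases is below the minimum predictable ",
                           "effort (%g bases at abundance 1)."), b, min_bases),
            class = "seqeffort_domain_error")
    }
    if (b > max_bases) {
      abort(sprintf(paste0("budget %g bases exceeds the effort at the ",
                           "abundance floor 1e-4 (%g bases)."), b, max_bases),
            class = "seqeffort_domain_error")
    }
    lo <- log10(lo_f); hi <- 0
    # predicted effort decreases in abundance: bisect on log10 f
    while (hi - lo > 1e-3) {
      mid <- (lo + hi) / 2
      if (pred1(10^mid) > b) lo <- mid else hi <- mid
    }
    f <- 10^((lo + hi) / 2)
    tibble::tibble(bases = b, genome_size = genome_size,
                   target_fraction = target_fraction, abundance = f,
                   extrapolated = f < surface$domain$abundance[1])
  })
}

#' Serialize and restore an effort surface
#'
#' The JSON file stores the training table together with the fitting
#' parameters and grid provenance (seed, replicates, read length);
#' `read_effort_surface()` refits the smooth from the stored table, which is
#' deterministic and reproduces predictions exactly.
#'
#' @param surface An [fit_effort_surface()] object.
#' @param path JSON file path.
#' @return `write_effort_surface()` returns `path` invisibly;
#'   `read_effort_surface()` returns an `effort_surface`.
#' @export
write_effort_surface <- function(surface, path) {
  stopifnot(inherits(surface, "effort_surface"))
  payload <- list(
    format = "seqeffort_surface",
    version = as.character(packageVersion("seqeffort")),
    read_length = surface$read_length,
    basis_dims = surface$basis_dims,
    replicates = surface$replicates,
    seed = surface$seed,
    # doubles as %.17g strings: JSON number serialization rounds to 15
    # significant digits, which would perturb the refit
    table = lapply(surface$table, function(col) sprintf("%.17g", col)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_effort_surface
#' @export
read_effort_surface <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "seqeffort_surface")) {
    stop_domain(sprintf("`%s` is not a seqeffort surface file.", path))
  }
  tab <- tibble::as_tibble(lapply(payload$table, as.numeric))
  attr(tab, "read_length") <- payload$read_length
  attr(tab, "replicates") <- payload$replicates
  attr(tab, "seed") <- payload$seed
  fit_effort_surface(tab, basis_dims = payload$basis_dims,
                     read_length = payload$read_length)
}

#' Load the surface shipped with the package
#'
#' A surface pre-trained on a reduced grid (documented in the file's
#' provenance fields) used as the default for quick predictions and by the
#' command-line `grase` subcommand. Retrain with [surface_grid_full()] for
#' the full-resolution study grid.
#'
#' @return An `effort_surface`.
#' @export
default_surface <- function() {
  path <- system.file("extdata", "surface_default.json",
                      package = "seqeffort", mustWork = TRUE)
  read_effort_surface(path)
}

#' Plot an effort surface as abundance-effort curves
#'
#' @param object An `effort_surface`.
#' @param target_fraction Fraction at which to slice the surface.
#' @param ... Unused.
#' @return A ggplot of predicted bases against abundance, one line per
#'   trained genome size.
#' @export
autoplot.effort_surface <- function(object, target_fraction = 0.9, ...) {
  sizes <- sort(unique(object$table$genome_size))
  f <- 10^seq(-4, 0, length.out = 60)
  df <- purrr::map_dfr(sizes, function(l) {
    predict_effort(object, f, l, target_fraction)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abundance, y = .data$bases,
                                   colour = factor(.data$genome_size))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative abundance", y = "required bases",
                  colour = "genome size (bp)",
                  title = sprintf("target fraction %.2f", target_fraction)) +
    ggplot2::theme_minimal()
}
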