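#' Classify MAGs by completeness and contamination
#'
#' MIMAG-style thresholds with strict inequalities: high quality means
#' completeness > 90% and contamination < 5%; medium quality means
#' completeness > 50% and contamination < 10% (and not high); anything else
#' is unclassified. Boundary cases (exactly 90% complete or 5%
#' contaminated) fall to the lower class.
#'
#' @param completeness Completeness percentages in \[0, 100\].
#' @param contamination Contamination percentages (>= 0).
#' @return Character vector over `"high"`, `"medium"`, `"none"`.
#' @examples
#' classify_mag(c(95, 60, 95, 40), c(3, 8, 8, 1))
#' @export
classify_mag <- function(completeness, contamination) {
  check_number(completeness, "completeness", lower = 0, upper = 100)
  check_number(contamination, "contamination", lower = 0)
  n <- max(length(completeness), length(contamination))
  completeness <- rep_len(completeness, n)
  contamination <- rep_len(contamination, n)
  out <- rep("none", n)
  out[completeness > 50 & contamination < 10] <- "medium"
  out[completeness > 90 & contamination < 5] <- "high"
  out
}

#' Count quality MAGs per rarefaction group
#'
#' Classifies each MAG record and counts medium- and high-quality MAGs per
#' (environment, sequencing depth, replicate) group. "Quality MAGs" is
#' their sum — with disjoint classes this equals the count of records with
#' completeness > 50% and contamination < 10%.
#'
#' @param records A data frame of per-MAG rows with columns `environment`,
#'   `replicate`, `high_quality_bases_gbp`, `completeness_pct`,
#'   `contamination_pct` (extra columns such as `bin_id` are ignored).
#' @return A tibble with one row per group: `environment`,
#'   `high_quality_bases_gbp`, `replicate`, `n_high`, `n_medium`,
#'   `quality`.
#' @export
count_quality_mags <- function(records) {
  need <- c("environment", "replicate", "high_quality_bases_gbp",
            "completeness_pct", "contamination_pct")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("`records` is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "seqeffort_schema_error")
  }
  if (!nrow(records)) stop_domain("`records` must contain at least one row.")
  if (any(records$high_quality_bases_gbp <= 0)) {
    stop_domain("`high_quality_bases_gbp` must be positive.")
  }
  records <- dplyr::mutate(
    tibble::as_tibble(records),
    .class = classify_mag(.data$completeness_pct, .data$contamination_pct))
  dplyr::summarise(
    dplyr::group_by(records, .data$environment,
                    .data$high_quality_bases_gbp, .data$replicate),
    n_high = sum(.data$.class == "high"),
    n_medium = sum(.data$.class == "medium"),
    quality = .data$n_high + .data$n_medium,
    .groups = "drop")
}

#' Import a CheckM quality table as MAG records
#'
#' Reads a tab-separated CheckM quality output (columns `Bin Id`,
#' `Completeness`, `Contamination`) and maps it onto the MAG record schema,
#' attaching the rarefaction coordinates supplied by the caller.
#'
#' @param path Path to the CheckM TSV.
#' @param environment Environment label for these bins.
#' @param replicate Subsample replicate id.
#' @param high_quality_bases_gbp High-quality bases sequenced (Gbp) for this
#'   subsample.
#' @return A MAG record tibble accepted by [count_quality_mags()].
#' @export
read_checkm <- function(path, environment, replicate,
                        high_quality_bases_gbp) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("Bin Id", "Completeness", "Contamination")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("CheckM table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "seqeffort_schema_error")
  }
  tibble::tibble(environment = environment,
                 replicate = replicate,
                 high_quality_bases_gbp = high_quality_bases_gbp,
                 bin_id = df[["Bin Id"]],
                 completeness_pct = df[["Completeness"]],
                 contamination_pct = df[["Contamination"]])
}

#' Gompertz rarefaction curve (Zwietering parameterisation)
#'
#' Expected quality MAGs after sequencing `bases_gbp` gigabases:
#' \deqn{g(b) = A \exp\!\big(-\exp\big(\tfrac{\mu e}{A}(\lambda - b) + 1\big)\big)}
#' with asymptote `A` (maximum quality MAGs the pipeline can yield),
#' maximum rate `mu` (MAGs per Gbp at the inflection) and lag `lambda`
#' (Gbp that must be sequenced before quality MAGs start to appear).
#'
#' @param bases_gbp Sequencing effort in Gbp (vectorised).
#' @param A Asymptotic quality-MAG count (> 0).
#' @param mu Maximum rate, MAGs per Gbp (> 0 for a rising curve).
#' @param lambda Lag, Gbp.
#' @return Expected quality MAGs.
#' @examples
#' gompertz_eval(3, A = 15, mu = 2, lambda = 3)  # = 15 * exp(-e)
#' @export
gompertz_eval <- function(bases_gbp, A, mu, lambda) {
  check_number(A, "A", len = 1)
  if (A <= 0) stop_domain("`A` must be positive.")
  check_number(mu, "mu", len = 1)
  check_number(lambda, "lambda", len = 1)
  check_number(bases_gbp, "bases_gbp")
  A * exp(-exp(mu * exp(1) / A * (lambda - bases_gbp) + 1))
}

#' Fit the Gompertz rarefaction model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of quality-MAG counts
#' against sequencing depth. Starting values follow a shape heuristic:
#' `A0 = max(count)`, `mu0` the steepest finite-difference slope, and
#' `lambda0` the deepest depth at which counts are still essentially zero
#' (<= 5% of `A0`). Parameters are bounded (`A, mu > 0`, `lambda >= 0`);
#' standard errors come from the Jacobian at the optimum. The fit is
#' invariant to row order.
#'
#' @param data A data frame of rarefaction points.
#' @param bases,count Columns (tidy-eval) holding depth in Gbp and
#'   quality-MAG counts; default `high_quality_bases_gbp` and `quality`, the
#'   names produced by [count_quality_mags()].
#' @return An object of class `gompertz_fit` with [tidy()] and [glance()]
#'   methods.
#' @examples
#' b <- rep(c(1, 2, 4, 8, 16, 32), each = 2)
#' df <- data.frame(high_quality_bases_gbp = b,
#'                  quality = round(gompertz_eval(b, 12, 1.5, 2)))
#' fit_gompertz(df)
#' @export
fit_gompertz <- function(data, bases = high_quality_bases_gbp,
                         count = quality) {
  b <- dplyr::pull(data, {{ bases }})
  y <- dplyr::pull(data, {{ count }})
  check_number(b, "bases")
  check_number(y, "count")
  if (any(b <= 0)) stop_domain("depths must be positive (Gbp).")
  if (length(b) < 4) stop_domain("Gompertz fit needs at least 4 points.")
  if (length(unique(b)) < 3) {
    stop_domain("Gompertz fit needs at least 3 distinct depths.")
  }
  if (all(y == 0)) stop_domain("all counts are zero; nothing to fit.")

  A0 <- max(y)
  ord <- order(b)
  bo <- b[ord]; yo <- y[ord]
  slopes <- diff(yo) / diff(bo)
  mu0 <- max(slopes[is.finite(slopes)], 0.1 * A0 / max(bo))
  low <- bo[yo <= 0.05 * A0]
  lambda0 <- if (length(low)) max(low) else 0
  starts <- list(
    c(A = A0, mu = mu0, lambda = lambda0),
    c(A = A0 * 1.2, mu = mu0 / 2, lambda = max(lambda0 / 2, 0.01)),
    c(A = A0, mu = mu0 * 2, lambda = min(bo)))

  df <- data.frame(b = b, y = y)
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-exp(mu * exp(1) / A * (lambda - b) + 1)),
        data = df, start = as.list(st),
        lower = c(A = 1e-8, mu = 1e-8, lambda = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("Gompertz fit did not converge; starting values tried: ",
                 paste(vapply(starts, function(s) {
                   paste(sprintf("%s=%.3g", names(s), s), collapse = ",")
                 }, character(1)), collapse = " | ")),
          class = "seqeffort_fit_error")
  }
  sm <- summary(fit)
  est <- sm$coefficients
  structure(list(
    model = fit,
    estimates = tibble::tibble(term = rownames(est),
                               estimate = est[, "Estimate"],
                               std.error = est[, "Std. Error"],
                               statistic = est[, "t value"],
                               p.value = est[, "Pr(>|t|)"]),
    residual_sd = sm$sigma,
    n = length(b),
    data = tibble::tibble(bases_gbp = b, count = y)),
    class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(paste0("<gompertz_fit> A = %.2f (SE %.2f), mu = %.2f (SE ",
                     "%.2f) MAGs/Gbp, lambda = %.2f (SE %.2f) Gbp, n = %d\n"),
              e$estimate[e$term == "A"], e$std.error[e$term == "A"],
              e$estimate[e$term == "mu"], e$std.error[e$term == "mu"],
              e$estimate[e$term == "lambda"], e$std.error[e$term == "lambda"],
              x$n))
  invisible(x)
}

#' @export
tidy.gompertz_fit <- function(x, ...) x$estimates

#' @export
glance.gompertz_fit <- function(x, ...) {
  cf <- coef_named(x)
  tibble::tibble(A = cf["A"], mu = cf["mu"], lambda = cf["lambda"],
                 residual_sd = x$residual_sd, n = x$n,
                 yield = gompertz_yield(x))
}

coef_named <- function(fit) {
  e <- fit$estimates
  stats::setNames(e$estimate, e$term)
}

#' MAG yield relative to the fitted asymptote
#'
#' `mag_yield()` is the ratio of observed quality MAGs (medium plus high) to
#' the asymptotic maximum `A` of a Gompertz fit. `gompertz_yield()` applies
#' it to a fitted object, taking the observed count as the replicate-mean
#' quality-MAG count at the deepest sequencing effort in the fit's data (the
#' convention isolated here so an alternative aggregation is a one-line
#' change).
#'
#' @param n_medium,n_high Observed medium- and high-quality MAG counts
#'   (>= 0).
#' @param A Asymptotic quality-MAG count (> 0).
#' @return The yield (dimensionless; ~1 means the survey has saturated its
#'   pipeline's potential).
#' @examples
#' mag_yield(6, 3, 10)  # 0.9
#' @export
mag_yield <- function(n_medium, n_high, A) {
  check_number(n_medium, "n_medium", lower = 0)
  check_number(n_high, "n_high", lower = 0)
  check_number(A, "A", len = 1)
  if (A <= 0) stop_domain("`A` must be positive.")
  (n_medium + n_high) / A
}

#' @rdname mag_yield
#' @param fit A [fit_gompertz()] object.
#' @export
gompertz_yield <- function(fit) {
  stopifnot(inherits(fit, "gompertz_fit"))
  deepest <- max(fit$data$bases_gbp)
  observed <- mean(fit$data$count[fit$data$bases_gbp == deepest])
  observed / coef_named(fit)["A"][[1]]
}

#' Quality MAGs as a function of the abundance cutoff
#'
#' Couples a Gompertz rarefaction fit with an effort surface: for a sweep of
#' sequencing budgets, the surface is inverted to the rarest relative
#' abundance sequenced to `target_fraction` ([invert_effort()]) and the
#' Gompertz curve predicts the quality MAGs recovered at that budget. The
#' central genome-size assumption (default 5 Mbp) is bracketed by the
#' smaller and larger sizes, which bound the abundance cutoff since smaller
#' genomes need fewer bases.
#'
#' @param fit A [fit_gompertz()] object (depths in Gbp).
#' @param surface An [fit_effort_surface()] object (efforts in bases).
#' @param target_fraction Target fraction of genome exhaustion.
#' @param genome_sizes Genome sizes in bp to evaluate.
#' @param n_budgets Number of log-spaced budgets in the sweep.
#' @return A tibble: `genome_size`, `bases`, `bases_gbp`,
#'   `abundance_cutoff`, `quality_mags`, `extrapolated`.
#' @export
effort_to_abundance_curve <- function(fit, surface, target_fraction = 0.5,
                                      genome_sizes = c(1, 5, 20) * 1e6,
                                      n_budgets = 40) {
  stopifnot(inherits(fit, "gompertz_fit"),
            inherits(surface, "effort_surface"))
  check_number(n_budgets, "n_budgets", lower = 2, len = 1, integerish = TRUE)
  cf <- coef_named(fit)
  purrr::map_dfr(genome_sizes, function(l) {
    lo <- predict_effort(surface, 1, l, target_fraction)$bases * 1.001
    hi <- predict_effort(surface, 1e-4, l, target_fraction)$bases * 0.999
    if (hi <= lo) {
      stop_domain("budget sweep does not overlap the surface domain.")
    }
    budgets <- 10^seq(log10(lo), log10(hi), length.out = n_budgets)
    inv <- invert_effort(surface, budgets, l, target_fraction)
    tibble::tibble(genome_size = l,
                   bases = budgets,
                   bases_gbp = budgets / 1e9,
                   abundance_cutoff = inv$abundance,
                   quality_mags = gompertz_eval(budgets / 1e9, cf["A"],
                                                cf["mu"], cf["lambda"]),
                   extrapolated = inv$extrapolated)
  })
}

#' Plot a Gompertz rarefaction fit over its data
#'
#' @param object A `gompertz_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  cf <- coef_named(object)
  grid <- tibble::tibble(
    bases_gbp = seq(0, max(object$data$bases_gbp), length.out = 200))
  grid$count <- gompertz_eval(grid$bases_gbp, cf["A"], cf["mu"], cf["lambda"])
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$bases_gbp, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "high-quality bases (Gbp)", y = "quality MAGs") +
    ggplot2::theme_minimal()
}
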