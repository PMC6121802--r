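#' Competition-assay selection rate
#'
#' Difference between the Malthusian parameters of the evolved and ancestral
#' competitors over the assay:
#' \deqn{r = \frac{\ln(E_d/E_0) - \ln(A_d/A_0)}{d}}
#' in units of per day, so a positive rate means the evolved competitor is
#' fitter, zero means both change by the same factor. The alternative
#' `orientation = "printed"` uses the initial/final ratio convention
#' (`ln(E_0/E_d) - ln(A_0/A_d)`), which is the same magnitude with the sign
#' flipped; the growth orientation is the default because it matches the
#' standard interpretation that above-zero means the evolved strain is more
#' fit.
#'
#' @param evolved_d0,evolved_d2 Evolved competitor density (CFU/mL) at day 0
#'   and at the final day; strictly positive.
#' @param ancestral_d0,ancestral_d2 Ancestral competitor densities; strictly
#'   positive.
#' @param duration Assay duration in days (default 2).
#' @param orientation `"growth"` (default) or `"printed"` (see Details).
#' @return Selection rate(s), per day. Vectorised over assays.
#' @export
selection_rate <- function(evolved_d0, evolved_d2, ancestral_d0, ancestral_d2,
                           duration = 2, orientation = c("growth", "printed")) {
  orientation <- match.arg(orientation)
  for (field in c("evolved_d0", "evolved_d2", "ancestral_d0", "ancestral_d2")) {
    v <- get(field)
    if (any(!is.finite(v) | v <= 0)) {
      stop("non-positive or non-finite density in ", field)
    }
  }
  if (any(duration <= 0)) stop("duration must be positive")
  r <- (log(evolved_d2 / evolved_d0) - log(ancestral_d2 / ancestral_d0)) / duration
  if (orientation == "printed") -r else r
}

#' Selection rates for a table of competition assays
#'
#' Applies [selection_rate()] to each assay row and averages replicate assays
#' of the same (population, environment) pair.
#'
#' @param assays `data.frame` as returned by [read_competition_table()] or
#'   [generate_competition_counts()].
#' @param orientation Passed to [selection_rate()].
#' @return `data.frame` with `population`, `environment`, `selection_rate`
#'   (replicate mean, per day), and `n_replicates`.
#' @export
selection_rates <- function(assays, orientation = "growth") {
  r <- selection_rate(assays$evolved_d0, assays$evolved_d2,
                      assays$ancestral_d0, assays$ancestral_d2,
                      duration = assays$duration, orientation = orientation)
  key <- paste(assays$population, assays$environment, sep = "\r")
  means <- tapply(r, key, mean)
  counts <- tapply(r, key, length)
  parts <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
  out <- data.frame(population = parts[, 1L], environment = parts[, 2L],
                    selection_rate = as.numeric(means),
                    n_replicates = as.integer(counts), stringsAsFactors = FALSE)
  out[order(out$environment, out$population), , drop = FALSE]
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Tie-corrected Kendall tau; exact p-value by enumeration for small
#' tie-free samples, normal approximation (with tie correction) otherwise,
#' as provided by [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `tau`, `p_value`, `n`, and `alternative`. `tau` is `NA`
#'   (flagged, with a warning) when either input is completely tied.
#' @export
kendall_tau <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("all-tied input: Kendall tau undefined")
    return(list(tau = NA_real_, p_value = NA_real_, n = n,
                alternative = alternative))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         alternative = alternative,
                                         exact = NULL))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = n,
       alternative = alternative)
}

#' Correlation between genetic similarity to an environment and fitness there
#'
#' For every population with a fitness measurement in `environment`, the
#' predictor is its mean similarity to the populations that evolved in that
#' environment (native populations exclude themselves, see
#' [mean_similarity_to_environment()]) and the response is its selection rate
#' measured in that environment. `include_native = FALSE` restricts to
#' populations whose home treatment is not `environment`, testing whether the
#' association is driven solely by the native populations.
#'
#' @param sim A `similarity_matrix` covering all populations.
#' @param fitness `data.frame` from [selection_rates()].
#' @param design Treatment design.
#' @param environment Treatment id of the assay environment.
#' @param include_native Keep populations native to `environment`
#'   (default `TRUE`).
#' @param alternative Passed to [kendall_tau()].
#' @return List of class `similarity_fitness_cor` with `environment`, `tau`,
#'   `p_value`, `n_points`, `native_included`, and the point table `points`.
#' @export
similarity_fitness_correlation <- function(sim, fitness, design, environment,
                                           include_native = TRUE,
                                           alternative = "two.sided") {
  fit_env <- fitness[fitness$environment == environment, , drop = FALSE]
  pops <- intersect(rownames(sim), fit_env$population)
  skipped <- setdiff(rownames(sim), pops)
  if (length(skipped)) {
    warning("population(s) without fitness in ", environment, " skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (!include_native) {
    home <- design$treatment[match(pops, design$population)]
    pops <- pops[home != environment]
  }
  if (length(pops) < 3L) stop("fewer than 3 usable populations for environment ",
                              environment)
  x <- vapply(pops, mean_similarity_to_environment, numeric(1),
              env = environment, sim = sim, design = design)
  y <- fit_env$selection_rate[match(pops, fit_env$population)]
  kt <- kendall_tau(x, y, alternative = alternative)
  structure(list(environment = environment, tau = kt$tau,
                 p_value = kt$p_value, n_points = kt$n,
                 native_included = include_native,
                 points = data.frame(population = pops, similarity = unname(x),
                                     selection_rate = y,
                                     stringsAsFactors = FALSE)),
            class = "similarity_fitness_cor")
}

#' @export
print.similarity_fitness_cor <- function(x, ...) {
  cat("Similarity-fitness correlation in ", x$environment,
      if (!x$native_included) " (nonnative populations only)", "\n", sep = "")
  cat("  Kendall tau = ", signif(x$tau, 4), ", p = ", signif(x$p_value, 4),
      ", n = ", x$n_points, "\n", sep = "")
  invisible(x)
}
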