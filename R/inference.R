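# Randomization tests for treatment structure in genetic similarity.
#
# All tests share one scheme: the pairwise similarity matrix is held fixed and
# the population -> treatment assignment is permuted (preserving group sizes),
# so the null is "treatment labels carry no information about similarity".
# One-sided p-values; ties between a permuted statistic and the observed one
# count toward rejection of nothing (i.e. toward ">= observed", conservative).

.STAT_TOL <- 1e-12

# number of distinct labelled assignments for a label multiset
.n_assignments <- function(labels) {
  counts <- table(labels)
  exp(lfactorial(sum(counts)) - sum(lfactorial(counts)))
}

# all distinct permutations of a label multiset, one row per assignment
.multiset_perms <- function(labels) {
  counts <- table(labels)
  lev <- names(counts)
  rec <- function(counts, total) {
    if (total == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
    blocks <- list()
    for (k in seq_along(counts)) {
      if (counts[k] > 0L) {
        nxt <- counts
        nxt[k] <- counts[k] - 1L
        sub <- rec(nxt, total - 1L)
        blocks[[length(blocks) + 1L]] <- cbind(rep.int(k, nrow(sub)), sub)
      }
    }
    do.call(rbind, blocks)
  }
  idx <- rec(as.integer(counts), length(labels))
  matrix(lev[idx], nrow = nrow(idx))
}

.new_randomization_result <- function(name, observed, null_values, p_value,
                                      n_permutations, seed, exhaustive) {
  structure(list(statistic_name = name, observed = observed,
                 null_values = null_values, n_permutations = n_permutations,
                 p_value = p_value, seed = seed, exhaustive = exhaustive),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat("Randomization test: ", x$statistic_name, "\n", sep = "")
  cat("  observed = ", signif(x$observed, 5),
      ", p = ", signif(x$p_value, 4),
      " (", if (x$exhaustive) "exhaustive, " else "sampled, ",
      x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

# core runner: stat_fun maps a label vector to a scalar statistic
.randomize_labels <- function(labels, stat_fun, statistic_name,
                              n_permutations, seed) {
  observed <- stat_fun(labels)
  n_total <- .n_assignments(labels)
  if (n_total <= n_permutations && n_total <= 2.5e5) {
    perms <- .multiset_perms(labels)
    null_values <- apply(perms, 1L, stat_fun)
    p <- sum(null_values >= observed - .STAT_TOL) / length(null_values)
    return(.new_randomization_result(statistic_name, observed, null_values, p,
                                     length(null_values), NA_integer_, TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  null_values <- vapply(seq_len(n_permutations),
                        function(b) stat_fun(labels[sample.int(n)]),
                        numeric(1))
  p <- (1 + sum(null_values >= observed - .STAT_TOL)) / (1 + n_permutations)
  .new_randomization_result(statistic_name, observed, null_values, p,
                            n_permutations,
                            if (is.null(seed)) NA_integer_ else seed, FALSE)
}

.sim_pairs <- function(sim, pops) {
  sub <- unclass(sim)[pops, pops, drop = FALSE]
  px <- .pair_index(length(pops))
  v <- sub[cbind(px$i, px$j)]
  # for distance matrices the one-sided alternative is reversed (within
  # smaller than between); negating gives the same test either way
  if (identical(attr(sim, "orientation"), "distance")) v <- -v
  list(i = px$i, j = px$j, v = v)
}

#' Randomization test: within- versus between-treatment similarity
#'
#' Observed statistic is BC_within - BC_between (pooled pair means, see
#' [treatment_summary()]). The null permutes the population-to-treatment
#' assignment, preserving group sizes, on the fixed similarity matrix; when
#' the number of distinct assignments does not exceed `n_permutations` the
#' null is enumerated exhaustively (and the result is seed-independent).
#'
#' @param sim A `similarity_matrix`.
#' @param design Treatment design covering all populations in `sim`.
#' @param n_permutations Number of sampled permutations (default 10000).
#' @param seed Optional integer seed for the sampled null.
#' @return A `randomization_test` with the observed statistic, null values,
#'   one-sided p-value, and an `exhaustive` flag.
#' @export
test_within_vs_between <- function(sim, design, n_permutations = 10000L,
                                   seed = NULL) {
  pops <- rownames(sim)
  labels <- design$treatment[match(pops, design$population)]
  if (anyNA(labels)) stop("population(s) absent from design: ",
                          paste(pops[is.na(labels)], collapse = ", "))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least two treatments")
  if (sum(sizes >= 2L) < 1L) stop("no treatment has >= 2 populations")
  sp <- .sim_pairs(sim, pops)
  stat_fun <- function(lab) {
    same <- lab[sp$i] == lab[sp$j]
    mean(sp$v[same], na.rm = TRUE) - mean(sp$v[!same], na.rm = TRUE)
  }
  .randomize_labels(labels, stat_fun, "bc_within - bc_between",
                    n_permutations, seed)
}

#' Randomization test for one treatment pair
#'
#' Restricts the within-versus-between test to the populations of two
#' treatments; intended to be run over all unordered treatment pairs and fed
#' to [holm_bonferroni()] (see [test_all_treatment_pairs()]).
#'
#' @inheritParams test_within_vs_between
#' @param treatment_a,treatment_b The two treatment ids.
#' @export
test_treatment_pair <- function(sim, design, treatment_a, treatment_b,
                                n_permutations = 10000L, seed = NULL) {
  keep <- design$population[design$treatment %in% c(treatment_a, treatment_b)]
  keep <- intersect(rownames(sim), keep)
  sizes <- table(design$treatment[match(keep, design$population)])
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("both treatments need >= 2 populations present in the similarity matrix")
  }
  sub <- structure(unclass(sim)[keep, keep, drop = FALSE],
                   metric = attr(sim, "metric"),
                   orientation = attr(sim, "orientation"),
                   class = class(sim))
  res <- test_within_vs_between(sub, design,
                                n_permutations = n_permutations, seed = seed)
  res$statistic_name <- paste0("bc_within - bc_between (", treatment_a,
                               " vs ", treatment_b, ")")
  res
}

#' Run all pairwise treatment tests with sequential Bonferroni control
#'
#' @inheritParams test_within_vs_between
#' @param alpha Family-wise error target (default 0.05).
#' @return `data.frame` with one row per unordered treatment pair: observed
#'   statistic, p-value, Holm-adjusted p, and reject decision.
#' @export
test_all_treatment_pairs <- function(sim, design, n_permutations = 10000L,
                                     seed = NULL, alpha = 0.05) {
  trts <- sort(unique(design$treatment[design$population %in% rownames(sim)]))
  pairs <- utils::combn(trts, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    test_treatment_pair(sim, design, pairs[1L, k], pairs[2L, k],
                        n_permutations = n_permutations,
                        seed = if (is.null(seed)) NULL else seed + k)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  mt <- holm_bonferroni(p, alpha = alpha)
  data.frame(treatment_a = pairs[1L, ], treatment_b = pairs[2L, ],
             observed = vapply(res, `[[`, numeric(1), "observed"),
             p_value = p, adjusted_p = mt$adjusted_p, reject = mt$decisions,
             stringsAsFactors = FALSE)
}

# identify the 2x2 factorial cells, dropping the bead-size control
.factorial_cells <- function(design, exclude = NULL) {
  trt <- unique(design[c("treatment", "carbon", "mode", "bead")])
  if (!is.null(exclude)) trt <- trt[!trt$treatment %in% exclude, , drop = FALSE]
  trt$cell <- paste(trt$carbon, trt$mode, sep = ":")
  dup_cells <- unique(trt$cell[duplicated(trt$cell)])
  if (is.null(exclude) && length(dup_cells)) {
    # default: the small-bead treatment duplicating a cell is the
    # population-size control and sits out of the factorial test
    drop <- trt$cell %in% dup_cells & trt$bead == "small"
    trt <- trt[!drop, , drop = FALSE]
  }
  want <- as.vector(outer(c("high", "low"), c("biofilm", "planktonic"),
                          paste, sep = ":"))
  missing <- setdiff(want, trt$cell)
  if (length(missing)) stop("missing factorial cell(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(trt$cell)) {
    stop("cannot disambiguate duplicated factorial cell(s): ",
         paste(unique(trt$cell[duplicated(trt$cell)]), collapse = ", "),
         "; pass `exclude`")
  }
  trt
}

#' Randomization test: shared selection pressure and between-treatment similarity
#'
#' For the 2x2 factorial of carbon level x growth mode, compares the mean
#' per-treatment-pair similarity over "edge" pairs (treatments sharing exactly
#' one of the two factors) against "diagonal" pairs (sharing neither).
#' The bead-size control treatment, which duplicates the high-carbon biofilm
#' cell, is excluded (override with `exclude`).
#'
#' With `unit = "population"` (default) the null permutes population labels
#' across the four cells, preserving group sizes, and recomputes all six
#' pair means per permutation — the same exchangeability unit as the other
#' randomization tests, and the only version with enough resolution for
#' small p-values. `unit = "treatment"` instead permutes the assignment of
#' the four intact population groups to the four cells (4! = 24 assignments,
#' exhaustive); because the edge/diagonal split is determined by which of the
#' 3 perfect matchings of the cells forms the diagonals, that null takes only
#' 3 distinct values and its smallest attainable p is 1/3 — it is retained
#' for illustration only.
#'
#' @inheritParams test_within_vs_between
#' @param unit Exchangeability unit of the null (see Details).
#' @param exclude Treatment id(s) to leave out of the factorial (default:
#'   auto-detect the small-bead control).
#' @export
test_shared_trait <- function(sim, design, n_permutations = 10000L,
                              seed = NULL, unit = c("population", "treatment"),
                              exclude = NULL) {
  unit <- match.arg(unit)
  cells <- .factorial_cells(design, exclude = exclude)
  des <- design[design$treatment %in% cells$treatment, , drop = FALSE]
  pops <- intersect(rownames(sim), des$population)
  cell_of_trt <- stats::setNames(cells$cell, cells$treatment)
  labels <- unname(cell_of_trt[des$treatment[match(pops, des$population)]])
  cell_levels <- sort(unique(cells$cell))
  lab_id <- match(labels, cell_levels)
  # edge = shares exactly one factor; diagonal = shares neither
  carbon <- sub(":.*", "", cell_levels)
  mode <- sub(".*:", "", cell_levels)
  shared <- outer(carbon, carbon, "==") + outer(mode, mode, "==")
  code_of <- function(a, b) (pmin(a, b) - 1L) * 4L + pmax(a, b)
  cross_codes <- code_of(row(shared), col(shared))[upper.tri(shared)]
  edge_by_code <- stats::setNames(shared[upper.tri(shared)] == 1L,
                                  as.character(cross_codes))
  sp <- .sim_pairs(sim, pops)
  stat_from_ids <- function(ids) {
    ids <- as.integer(ids)  # exhaustive enumeration yields character labels
    a <- ids[sp$i]
    b <- ids[sp$j]
    cross <- a != b
    key <- as.character(code_of(a, b)[cross])
    mv <- tapply(sp$v[cross], key, mean, na.rm = TRUE)
    edge <- edge_by_code[names(mv)]
    mean(mv[edge]) - mean(mv[!edge])
  }
  if (unit == "treatment") {
    observed <- stat_from_ids(lab_id)
    perms <- .multiset_perms(as.character(1:4))
    null_values <- apply(perms, 1L, function(pm) {
      stat_from_ids(as.integer(pm)[lab_id])
    })
    p <- sum(null_values >= observed - .STAT_TOL) / length(null_values)
    res <- .new_randomization_result("edge mean - diagonal mean", observed,
                                     null_values, p, length(null_values),
                                     NA_integer_, TRUE)
    return(res)
  }
  .randomize_labels(lab_id, stat_from_ids, "edge mean - diagonal mean",
                    n_permutations, seed)
}

#' Sequential Bonferroni (Holm step-down) decisions
#'
#' Step-down control of the family-wise error rate at target `alpha`:
#' p-values are sorted ascending and p_(k) is rejected iff
#' p_(j) <= alpha / (m - j + 1) for all j <= k.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Family-wise error target (default 0.05).
#' @return A list of class `multiple_test` with `raw_p`, `adjusted_p`,
#'   logical `decisions` (in input order), `alpha`, and `procedure`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) && (any(p_values < 0) || any(p_values > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  adjusted <- stats::p.adjust(p_values, method = "holm")
  structure(list(raw_p = p_values, adjusted_p = adjusted,
                 decisions = adjusted <= alpha, alpha = alpha,
                 procedure = "holm"),
            class = "multiple_test")
}

#' Genes mutated in parallel across populations
#'
#' @param matrix A gene-level `profile_matrix`.
#' @param min_populations Minimum number of populations with a mutation in
#'   the gene (default 2).
#' @return `data.frame` with `gene`, `n_populations`, and one column of
#'   summed mutation frequency per population; rows sorted by population
#'   count (descending) then gene id.
#' @export
gene_parallelism_summary <- function(matrix, min_populations = 2L) {
  m <- unclass(matrix)
  counts <- colSums(m > 0)
  keep <- names(counts)[counts >= min_populations]
  keep <- keep[order(-counts[keep], keep)]
  out <- data.frame(gene = keep, n_populations = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  freq <- t(m[, keep, drop = FALSE])
  colnames(freq) <- rownames(m)
  out <- cbind(out, as.data.frame(freq, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Nucleotide sites mutated in parallel across populations
#'
#' @param records Retained mutation records.
#' @param min_populations Minimum number of distinct populations sharing the
#'   site (default 2).
#' @return `data.frame` with `replicon`, `position`, `n_populations`, and a
#'   comma-separated `populations` column; sorted by count (descending) then
#'   position.
#' @export
nucleotide_parallelism_summary <- function(records, min_populations = 2L) {
  if (nrow(records) == 0L) {
    return(data.frame(replicon = character(0), position = integer(0),
                      n_populations = integer(0), populations = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$replicon, records$position, sep = "\r")
  pops <- lapply(split(records$population, key), function(p) sort(unique(p)))
  n <- vapply(pops, length, integer(1))
  keep <- n >= min_populations
  parts <- do.call(rbind, strsplit(names(pops)[keep], "\r", fixed = TRUE))
  if (is.null(parts)) {
    return(data.frame(replicon = character(0), position = integer(0),
                      n_populations = integer(0), populations = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(replicon = parts[, 1L], position = as.integer(parts[, 2L]),
                    n_populations = n[keep],
                    populations = vapply(pops[keep], paste, character(1),
                                         collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_populations, out$replicon, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
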