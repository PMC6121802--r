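#' Bray-Curtis genetic similarity between two mutation-frequency profiles
#'
#' \deqn{BC_{ij} = 1 - \frac{\sum_g |n_{ig} - n_{jg}|}{\sum_g (n_{ig} + n_{jg})}}
#'
#' where n_ig is the summed mutation frequency in gene g in population i.
#' Genes mutated in neither population contribute nothing. Ranges from 0
#' (disjoint mutated gene sets) to 1 (identical profiles).
#'
#' @param p_i,p_j Numeric gene-frequency vectors over the same gene set.
#' @return Similarity in \[0, 1\]; `NA` if both profiles are all-zero
#'   (the denominator vanishes, so the value is undefined rather than 0 or 1).
#' @export
bray_curtis <- function(p_i, p_j) {
  stopifnot(length(p_i) == length(p_j))
  denom <- sum(p_i + p_j)
  if (denom == 0) return(NA_real_)
  1 - sum(abs(p_i - p_j)) / denom
}

#' Jaccard similarity on mutated-gene presence/absence
#'
#' @inheritParams bray_curtis
#' @return |intersection| / |union| of mutated gene sets (presence means
#'   n_ig > 0); `NA` if both sets are empty.
#' @export
jaccard <- function(p_i, p_j) {
  stopifnot(length(p_i) == length(p_j))
  a <- p_i > 0
  b <- p_j > 0
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Euclidean distance between mutation-frequency profiles
#'
#' @inheritParams bray_curtis
#' @return Non-negative distance (0 for identical profiles).
#' @export
euclidean_distance <- function(p_i, p_j) {
  stopifnot(length(p_i) == length(p_j))
  sqrt(sum((p_i - p_j)^2))
}

.metric_info <- function(metric) {
  switch(metric,
         bray_curtis = list(orientation = "similarity", diag = 1),
         jaccard = list(orientation = "similarity", diag = 1),
         euclidean = list(orientation = "distance", diag = 0),
         stop("unknown metric: ", metric))
}

#' Pairwise similarity (or distance) matrix over populations
#'
#' Computes the chosen metric for every unordered pair of rows of a profile
#' matrix. Populations with an all-zero profile yield `NA` for every pair that
#' involves them (similarity is undefined there) and trigger a warning naming
#' them; downstream means skip those pairs.
#'
#' @param matrix A `profile_matrix` (populations x genes).
#' @param metric One of `"bray_curtis"` (default), `"jaccard"`, `"euclidean"`.
#' @return Symmetric matrix of class `similarity_matrix` with attributes
#'   `metric` and `orientation` (`"similarity"` or `"distance"`); diagonal is
#'   1 for similarities, 0 for distances.
#' @export
pairwise_matrix <- function(matrix, metric = c("bray_curtis", "jaccard", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(matrix) < 2L) stop("need at least 2 populations")
  info <- .metric_info(metric)
  m <- unclass(matrix)
  rs <- rowSums(m)
  out <- switch(metric,
    bray_curtis = {
      man <- as.matrix(stats::dist(m, method = "manhattan"))
      1 - man / outer(rs, rs, "+")
    },
    jaccard = {
      pres <- m > 0
      inter <- tcrossprod(pres * 1)
      sizes <- diag(inter)
      union <- outer(sizes, sizes, "+") - inter
      inter / union
    },
    euclidean = as.matrix(stats::dist(m, method = "euclidean"))
  )
  zero <- rs == 0
  if (metric %in% c("bray_curtis", "jaccard") && any(zero)) {
    warning("population(s) with all-zero profiles yield undefined similarity: ",
            paste(rownames(m)[zero], collapse = ", "))
    out[zero, ] <- NA_real_
    out[, zero] <- NA_real_
  }
  diag(out) <- info$diag
  dimnames(out) <- list(rownames(m), rownames(m))
  structure(out, metric = metric, orientation = info$orientation,
            class = c("similarity_matrix", "matrix", "array"))
}

.pair_index <- function(n) {
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  list(i = ut[, 1L], j = ut[, 2L])
}

#' Within- and between-treatment similarity summary
#'
#' BC_within is the unweighted mean of the metric over all pairs of replicate
#' populations sharing a treatment, pooled across treatments; BC_between is
#' the mean over all cross-treatment pairs. Per-treatment and per-treatment-
#' pair means are also reported. `NA` pairs (undefined similarity) are
#' skipped; treatments with fewer than two populations contribute no within
#' pairs and trigger a warning.
#'
#' @param sim A `similarity_matrix`.
#' @param design Treatment design `data.frame` covering every population in
#'   `sim`.
#' @return A list of class `treatment_similarity` with elements `bc_within`,
#'   `bc_between`, `per_treatment_within` (named vector), and
#'   `per_pair_between` (`data.frame` with `treatment_a`, `treatment_b`,
#'   `mean`, `n_pairs`).
#' @export
treatment_summary <- function(sim, design) {
  pops <- rownames(sim)
  missing <- setdiff(pops, design$population)
  if (length(missing)) stop("population(s) absent from design: ",
                            paste(missing, collapse = ", "))
  trt <- design$treatment[match(pops, design$population)]
  sizes <- table(trt)
  if (any(sizes < 2L)) {
    warning("treatment(s) with < 2 populations excluded from within-treatment means: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  px <- .pair_index(length(pops))
  v <- sim[cbind(px$i, px$j)]
  same <- trt[px$i] == trt[px$j]
  bc_within <- mean(v[same], na.rm = TRUE)
  bc_between <- mean(v[!same], na.rm = TRUE)
  tw <- tapply(v[same], trt[px$i][same], mean, na.rm = TRUE)
  per_within <- stats::setNames(as.vector(tw), dimnames(tw)[[1L]])
  cross <- !same
  ta <- pmin(trt[px$i], trt[px$j])[cross]
  tb <- pmax(trt[px$i], trt[px$j])[cross]
  key <- paste(ta, tb, sep = "\r")
  means <- tapply(v[cross], key, mean, na.rm = TRUE)
  counts <- tapply(v[cross], key, length)
  parts <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
  per_pair <- data.frame(treatment_a = parts[, 1L], treatment_b = parts[, 2L],
                         mean = as.numeric(means), n_pairs = as.integer(counts),
                         stringsAsFactors = FALSE)
  rownames(per_pair) <- NULL
  structure(list(bc_within = bc_within, bc_between = bc_between,
                 per_treatment_within = per_within,
                 per_pair_between = per_pair,
                 metric = attr(sim, "metric")),
            class = "treatment_similarity")
}

#' @export
print.treatment_similarity <- function(x, ...) {
  cat("Treatment-level ", x$metric, " summary\n", sep = "")
  cat("  mean within-treatment:  ", round(x$bc_within, 4), "\n")
  cat("  mean between-treatment: ", round(x$bc_between, 4), "\n")
  invisible(x)
}

#' Mean genetic similarity of a population to an environment's residents
#'
#' Mean of the pairwise similarity between `focal` and each population that
#' evolved under treatment `env`. For a population native to `env` the focal
#' population itself is excluded (its self-similarity is 1 by definition and
#' carries no information).
#'
#' @param focal Focal population id.
#' @param env Treatment id defining the resident set.
#' @param sim A `similarity_matrix` covering all populations involved.
#' @param design Treatment design `data.frame`.
#' @return Mean similarity (scalar).
#' @export
mean_similarity_to_environment <- function(focal, env, sim, design) {
  residents <- design$population[design$treatment == env]
  residents <- setdiff(residents, focal)
  residents <- intersect(residents, rownames(sim))
  if (length(residents) == 0L) {
    stop("environment ", env, " has no resident population other than ", focal)
  }
  mean(sim[focal, residents], na.rm = TRUE)
}

#' Write a similarity matrix as square CSV and long TSV
#'
#' The long format (pop_i, pop_j, metric, value) is the hand-off point for
#' external ordination/PERMANOVA tools.
#'
#' @param sim A `similarity_matrix`.
#' @param square_path Output CSV path for the square matrix.
#' @param long_path Optional output TSV path for the unordered-pair long form.
#' @return `square_path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, square_path, long_path = NULL) {
  sq <- data.frame(population = rownames(sim), unclass(sim),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(sq, square_path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    px <- .pair_index(nrow(sim))
    long <- data.frame(pop_i = rownames(sim)[px$i], pop_j = rownames(sim)[px$j],
                       metric = attr(sim, "metric"),
                       orientation = attr(sim, "orientation"),
                       value = sim[cbind(px$i, px$j)], stringsAsFactors = FALSE)
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(square_path)
}
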