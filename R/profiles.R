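#' Apply the gene-assignability and frequency inclusion filters
#'
#' Retains mutations whose effect is unambiguously assignable to a single
#' gene: records that are not synonymous, whose context assignment is
#' `within_gene` or `upstream_of_gene`, and whose frequency is at least
#' `min_frequency`. Every input record is accounted for exactly once in the
#' returned report; exclusion reasons are applied in the fixed order
#' frequency, synonymous, multi-gene, ambiguous-upstream, distal-intergenic.
#'
#' @param records Mutation record `data.frame` carrying the context columns
#'   added by [assign_gene_contexts()].
#' @param min_frequency Minimum retained mutation frequency (default 0.05,
#'   the polymorphism-calling detection floor; 0.10 for the sensitivity
#'   re-run).
#' @return A list with `records` (the retained rows) and `report`
#'   (a `filter_report` with the exclusion accounting).
#' @export
filter_mutations <- function(records, min_frequency = 0.05) {
  if (!"assignment" %in% names(records)) {
    stop("records lack gene context; run assign_gene_contexts() first")
  }
  no_ctx <- which(is.na(records$assignment) | records$assignment == "")
  if (length(no_ctx)) {
    stop("record(s) without a context assignment at row(s): ",
         paste(utils::head(no_ctx, 10L), collapse = ", "))
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  is_multi <- records$assignment == "multi_gene" | records$coding_class == "multi_gene"
  reason[is.na(reason) & records$frequency < min_frequency] <- "below_frequency"
  reason[is.na(reason) & records$coding_class == "synonymous"] <- "synonymous"
  reason[is.na(reason) & is_multi] <- "multi_gene"
  reason[is.na(reason) & records$assignment == "ambiguous"] <- "ambiguous"
  reason[is.na(reason) & records$assignment == "distal_intergenic"] <- "distal_intergenic"
  retained <- is.na(reason)
  report <- structure(list(
    n_input = n,
    n_below_frequency_excluded = sum(reason == "below_frequency", na.rm = TRUE),
    n_synonymous_excluded = sum(reason == "synonymous", na.rm = TRUE),
    n_multi_gene_excluded = sum(reason == "multi_gene", na.rm = TRUE),
    n_ambiguous_excluded = sum(reason == "ambiguous", na.rm = TRUE),
    n_distal_intergenic_excluded = sum(reason == "distal_intergenic", na.rm = TRUE),
    n_retained = sum(retained),
    min_frequency = min_frequency
  ), class = "filter_report")
  out <- records[retained, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Mutation inclusion filter (min frequency ", x$min_frequency, ")\n", sep = "")
  cat("  input:              ", x$n_input, "\n")
  cat("  below frequency:    ", x$n_below_frequency_excluded, "\n")
  cat("  synonymous:         ", x$n_synonymous_excluded, "\n")
  cat("  multi-gene:         ", x$n_multi_gene_excluded, "\n")
  cat("  ambiguous upstream: ", x$n_ambiguous_excluded, "\n")
  cat("  distal intergenic:  ", x$n_distal_intergenic_excluded, "\n")
  cat("  retained:           ", x$n_retained, "\n")
  invisible(x)
}

#' Build the populations x genes mutation-frequency profile matrix
#'
#' Sums the frequencies of all retained mutations assigned to the same gene
#' (coding span plus upstream window) within a population: entry (i, g) is
#' n_ig, the total mutation frequency in gene g in population i. Values can
#' exceed 1 when competing lineages carry different mutations in one gene.
#'
#' @param records Retained mutation records with a `gene` assignment column.
#' @param populations Optional character vector fixing the row set and order;
#'   populations with no retained mutations become all-zero rows. Defaults to
#'   the populations present in `records`, sorted.
#' @return Numeric matrix (class `profile_matrix`) with populations as rows
#'   and genes as columns (lexicographic), attribute `level = "gene"`.
#' @export
build_profiles <- function(records, populations = NULL) {
  if (is.null(populations)) populations <- sort(unique(records$population))
  genes <- sort(unique(records$gene[!is.na(records$gene)]))
  mat <- matrix(0, nrow = length(populations), ncol = length(genes),
                dimnames = list(populations, genes))
  if (nrow(records) > 0L && length(genes) > 0L) {
    keep <- !is.na(records$gene) & records$population %in% populations
    r <- records[keep, , drop = FALSE]
    if (nrow(r)) {
      agg <- tapply(r$frequency, list(r$population, r$gene), sum)
      mat[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
    }
  }
  structure(mat, level = "gene", class = c("profile_matrix", "matrix", "array"))
}

#' Collapse a gene-level profile matrix to operon level
#'
#' Columns whose genes share an `operon_id` are summed into one column
#' labelled by the operon; genes without an operon keep their own column.
#' The total matrix sum is conserved.
#'
#' @param matrix A gene-level `profile_matrix`.
#' @param genes Annotation `data.frame` with `locus_tag` and `operon_id`.
#' @return An operon-level `profile_matrix`.
#' @export
collapse_operons <- function(matrix, genes) {
  if (identical(attr(matrix, "level"), "operon")) {
    stop("profile matrix is already at operon level")
  }
  ids <- colnames(matrix)
  op <- genes$operon_id[match(ids, genes$locus_tag)]
  group <- ifelse(is.na(op) | op == "", ids, op)
  collapsed <- t(rowsum(t(unclass(matrix)), group = group))
  collapsed <- collapsed[, order(colnames(collapsed)), drop = FALSE]
  structure(collapsed, level = "operon",
            class = c("profile_matrix", "matrix", "array"))
}

#' Count fixed versus intermediate-frequency mutations
#'
#' @param records Retained mutation records.
#' @param fixation_threshold Frequency at or above which a mutation counts as
#'   fixed (default 1.0, the consensus-call convention).
#' @return Named integer vector `c(n_fixed, n_intermediate)`.
#' @export
count_fixed <- function(records, fixation_threshold = 1.0) {
  if (!is.numeric(fixation_threshold) || length(fixation_threshold) != 1L ||
      fixation_threshold <= 0 || fixation_threshold > 1) {
    stop("fixation_threshold must lie in (0, 1]")
  }
  n_fixed <- sum(records$frequency >= fixation_threshold)
  c(n_fixed = n_fixed, n_intermediate = nrow(records) - n_fixed)
}

#' Write a profile matrix as wide and long TSV
#'
#' @param matrix A `profile_matrix`.
#' @param wide_path Output path for the populations x genes wide table.
#' @param long_path Optional output path for the long (population, gene,
#'   frequency) table; zero cells are omitted.
#' @return `wide_path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, wide_path, long_path = NULL) {
  wide <- data.frame(population = rownames(matrix), unclass(matrix),
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.table(wide, wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    idx <- which(unclass(matrix) > 0, arr.ind = TRUE)
    long <- data.frame(population = rownames(matrix)[idx[, 1L]],
                       gene = colnames(matrix)[idx[, 2L]],
                       frequency = matrix[idx], stringsAsFactors = FALSE)
    long <- long[order(long$population, long$gene), , drop = FALSE]
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(wide_path)
}

#' Read a wide profile matrix written by [write_profile_matrix()]
#'
#' @param path Wide TSV path.
#' @return A `profile_matrix`.
#' @export
read_profile_matrix <- function(path) {
  wide <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(mat) <- wide$population
  structure(mat, level = "gene", class = c("profile_matrix", "matrix", "array"))
}
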