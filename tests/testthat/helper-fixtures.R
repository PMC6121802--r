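# Shared fixture builders and independent brute-force oracles.

toy_genes <- function(locus_tag, start, end, strand = "+", replicon = "chr1",
                      operon_id = NA_character_) {
  data.frame(locus_tag = locus_tag, replicon = replicon, start = start,
             end = end, strand = strand, operon_id = operon_id,
             product = NA_character_, stringsAsFactors = FALSE)
}

toy_records <- function(population = "p1", replicon = "chr1", position = 100L,
                        mutation_type = "snp", coding_class = "nonsynonymous",
                        locus_tag = "g1", frequency = 0.5,
                        assignment = NULL, gene = NULL,
                        upstream_distance = NA_integer_) {
  n <- min(length(population), length(position), length(frequency))
  if (n == 0L) {
    out <- data.frame(population = character(0), replicon = character(0),
                      position = integer(0), mutation_type = character(0),
                      coding_class = character(0), locus_tag = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(assignment)) {
      out$assignment <- character(0)
      out$gene <- character(0)
      out$upstream_distance <- integer(0)
    }
    return(out)
  }
  out <- data.frame(population = population, replicon = replicon,
                    position = as.integer(position),
                    mutation_type = mutation_type, coding_class = coding_class,
                    locus_tag = locus_tag, frequency = frequency,
                    stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    out$assignment <- assignment
    out$gene <- if (is.null(gene)) locus_tag else gene
    out$upstream_distance <- upstream_distance
  }
  out
}

toy_design <- function(population, treatment,
                       carbon = "high", mode = "biofilm", bead = "large") {
  data.frame(population = population, treatment = treatment, carbon = carbon,
             mode = mode, bead = bead, stringsAsFactors = FALSE)
}

# elementwise oracles, written independently of the package internals
oracle_bray_curtis <- function(x, y) {
  num <- 0
  den <- 0
  for (g in seq_along(x)) {
    num <- num + abs(x[g] - y[g])
    den <- den + x[g] + y[g]
  }
  if (den == 0) NA_real_ else 1 - num / den
}

oracle_jaccard <- function(x, y) {
  inter <- 0
  uni <- 0
  for (g in seq_along(x)) {
    if (x[g] > 0 && y[g] > 0) inter <- inter + 1
    if (x[g] > 0 || y[g] > 0) uni <- uni + 1
  }
  if (uni == 0) NA_real_ else inter / uni
}

oracle_euclidean <- function(x, y) {
  s <- 0
  for (g in seq_along(x)) s <- s + (x[g] - y[g])^2
  sqrt(s)
}

# O(n^2) pair-counting Kendall tau-b with tie correction
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      conc <- conc + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  conc / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# brute-force within-vs-between statistic straight from the definition
oracle_wb_stat <- function(S, labels) {
  w <- c()
  b <- c()
  n <- length(labels)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (labels[i] == labels[j]) w <- c(w, S[i, j]) else b <- c(b, S[i, j])
    }
  }
  mean(w, na.rm = TRUE) - mean(b, na.rm = TRUE)
}
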