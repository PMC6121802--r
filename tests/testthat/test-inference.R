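# perfectly separated 2-treatment toy: within-pairs similarity 1, cross 0
separated_toy <- function() {
  pops <- c("a1", "a2", "b1", "b2")
  S <- matrix(0, 4, 4, dimnames = list(pops, pops))
  S["a1", "a2"] <- S["a2", "a1"] <- 1
  S["b1", "b2"] <- S["b2", "b1"] <- 1
  diag(S) <- 1
  list(S = S, design = toy_design(pops, c("A", "A", "B", "B")))
}

test_that("exhaustive enumeration on the 4-population toy gives p = 1/3", {
  toy <- separated_toy()
  res <- test_within_vs_between(toy$S, toy$design, n_permutations = 100)
  expect_true(res$exhaustive)
  expect_equal(res$observed, 1.0)
  expect_equal(res$n_permutations, 6L)
  expect_equal(res$p_value, 1 / 3)
  # independent oracle: enumerate the 6 labelled assignments by brute force
  perms <- list(c("A","A","B","B"), c("A","B","A","B"), c("A","B","B","A"),
                c("B","A","A","B"), c("B","A","B","A"), c("B","B","A","A"))
  null <- vapply(perms, function(l) oracle_wb_stat(toy$S, l), numeric(1))
  expect_equal(res$p_value, mean(null >= res$observed - 1e-12))
  expect_equal(sort(res$null_values), sort(null))
})

test_that("the observed statistic is a member of the exhaustive null multiset", {
  set.seed(71)
  pops <- paste0("P", 1:6)
  S <- matrix(runif(36), 6, 6, dimnames = list(pops, pops))
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  des <- toy_design(pops, rep(c("A", "B"), each = 3))
  res <- test_within_vs_between(S, des, n_permutations = 50)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 20L)
  expect_true(any(abs(res$null_values - res$observed) < 1e-12))
})

test_that("an exchangeable similarity matrix gives observed 0 and p = 1", {
  pops <- paste0("P", 1:6)
  S <- matrix(0.3, 6, 6, dimnames = list(pops, pops))
  diag(S) <- 1
  des <- toy_design(pops, rep(c("A", "B"), each = 3))
  res <- test_within_vs_between(S, des, n_permutations = 99)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  # sampled path too
  res_s <- test_within_vs_between(S, des, n_permutations = 10, seed = 4)
  expect_equal(res_s$p_value, 1)
})

test_that("sampled p-values are reproducible given a seed and degenerate designs error", {
  set.seed(83)
  pops <- paste0("P", 1:12)
  S <- matrix(runif(144), 12, 12, dimnames = list(pops, pops))
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  des <- toy_design(pops, rep(c("A", "B", "C"), each = 4))
  r1 <- test_within_vs_between(S, des, n_permutations = 200, seed = 9)
  r2 <- test_within_vs_between(S, des, n_permutations = 200, seed = 9)
  expect_false(r1$exhaustive)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(test_within_vs_between(S, toy_design(pops, rep("A", 12))),
               "two treatments")
})

test_that("treatment-pair tests restrict to the two treatments", {
  toy <- separated_toy()
  res <- test_treatment_pair(toy$S, toy$design, "A", "B", n_permutations = 100)
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 1 / 3)
  # identical profiles across both treatments: no signal
  pops <- c("a1", "a2", "b1", "b2")
  S1 <- matrix(1, 4, 4, dimnames = list(pops, pops))
  res1 <- test_treatment_pair(S1, toy$design, "A", "B", n_permutations = 100)
  expect_equal(res1$observed, 0)
  expect_equal(res1$p_value, 1)
  expect_error(test_treatment_pair(toy$S, toy$design, "A", "C"),
               ">= 2 populations")
})

test_that("pairwise test battery feeds Holm decisions in input order", {
  set.seed(19)
  cfg <- synthetic_config(replicates = 3, gene_count = 80, seed = 19,
                          drop_population = FALSE, divergence = 1,
                          factor_share = 0)
  ex <- generate_experiment(cfg)
  prof <- build_profiles(filter_mutations(ex$records)$records,
                         populations = ex$usable_design$population)
  S <- suppressWarnings(pairwise_matrix(prof))
  tab <- test_all_treatment_pairs(S, ex$usable_design, n_permutations = 60,
                                  seed = 5)
  expect_equal(nrow(tab), choose(5, 2))
  expect_true(all(tab$adjusted_p >= tab$p_value - 1e-12))
  # Holm never rejects more than unadjusted alpha-level testing
  expect_lte(sum(tab$reject), sum(tab$p_value <= 0.05))
})

shared_trait_design <- function(reps = 2) {
  grid <- expand.grid(carbon = c("high", "low"), mode = c("biofilm", "planktonic"),
                      stringsAsFactors = FALSE)
  grid$treatment <- paste(grid$carbon, grid$mode, sep = "_")
  des <- grid[rep(1:4, each = reps), ]
  des$population <- paste0(des$treatment, "_r", rep(seq_len(reps), times = 4))
  des$bead <- ifelse(des$mode == "biofilm", "large", "none")
  validate_design(des[c("population", "treatment", "carbon", "mode", "bead")])
}

# block similarity matrix with fixed values per treatment pair
shared_trait_matrix <- function(des, edge, diagonal, within = 0.8) {
  pops <- des$population
  n <- length(pops)
  S <- matrix(NA_real_, n, n, dimnames = list(pops, pops))
  cell <- paste(des$carbon, des$mode, sep = ":")
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { S[i, j] <- 1; next }
    shared <- (des$carbon[i] == des$carbon[j]) + (des$mode[i] == des$mode[j])
    S[i, j] <- if (shared == 2) within else if (shared == 1) edge else diagonal
  }
  S
}

test_that("shared-trait statistic separates edge from diagonal pairs", {
  des <- shared_trait_design()
  S <- shared_trait_matrix(des, edge = 0.5, diagonal = 0)
  res <- test_shared_trait(S, des, n_permutations = 500, seed = 3)
  expect_equal(res$observed, 0.5)
  expect_lt(res$p_value, 0.05)
  # fully exchangeable matrix: observed 0, p 1 under population permutation
  S0 <- shared_trait_matrix(des, edge = 0.2, diagonal = 0.2, within = 0.2)
  res0 <- test_shared_trait(S0, des, n_permutations = 200, seed = 3)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_value, 1)
  # constant cross-pair means: p 1 under the intact-group (treatment) null
  S1 <- shared_trait_matrix(des, edge = 0.2, diagonal = 0.2)
  res1 <- test_shared_trait(S1, des, unit = "treatment")
  expect_equal(res1$observed, 0)
  expect_equal(res1$p_value, 1)
})

test_that("treatment-unit shared-trait null enumerates all 24 cell assignments", {
  des <- shared_trait_design()
  S <- shared_trait_matrix(des, edge = 0.5, diagonal = 0)
  res <- test_shared_trait(S, des, unit = "treatment")
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 24L)
  expect_equal(res$observed, 0.5)
  # brute-force oracle over all 24 permutations of the cell labels
  cells <- sort(unique(paste(des$carbon, des$mode, sep = ":")))
  carbon <- sub(":.*", "", cells)
  mode <- sub(".*:", "", cells)
  base <- match(paste(des$carbon, des$mode, sep = ":"), cells)
  all_perms <- do.call(rbind, lapply(1:4, function(a)
    do.call(rbind, lapply(setdiff(1:4, a), function(b)
      do.call(rbind, lapply(setdiff(1:4, c(a, b)), function(cc)
        c(a, b, cc, setdiff(1:4, c(a, b, cc)))))))))
  stat <- function(lab) {
    em <- c()
    dm <- c()
    for (a in 1:3) for (b in (a + 1):4) {
      sel <- outer(lab, lab, function(u, v) pmin(u, v) == a & pmax(u, v) == b) &
        upper.tri(S)
      if (!any(sel)) next
      shared <- (carbon[a] == carbon[b]) + (mode[a] == mode[b])
      if (shared == 1) em <- c(em, mean(S[sel])) else dm <- c(dm, mean(S[sel]))
    }
    mean(em) - mean(dm)
  }
  null <- apply(all_perms, 1, function(pm) stat(pm[base]))
  expect_equal(sort(res$null_values), sort(null))
  expect_equal(res$p_value, mean(null >= res$observed - 1e-12))
  # the edge/diagonal split has only 3 distinct forms, so p is at least 1/3
  expect_equal(res$p_value, 1 / 3)
})

test_that("shared-trait test drops the bead-size control and demands full factorial", {
  cfg <- synthetic_config(replicates = 2, gene_count = 80, seed = 31,
                          drop_population = FALSE)
  ex <- generate_experiment(cfg)
  prof <- build_profiles(filter_mutations(ex$records)$records,
                         populations = ex$usable_design$population)
  S <- suppressWarnings(pairwise_matrix(prof))
  res <- test_shared_trait(S, ex$usable_design, n_permutations = 50, seed = 1)
  expect_s3_class(res, "randomization_test")
  # excluding a required cell's treatment leaves a hole
  expect_error(test_shared_trait(S, ex$usable_design, exclude = c(
    "hc_biofilm_sm", "lc_plank")), "low:planktonic")
})

test_that("Holm step-down matches hand-computed thresholds", {
  r <- holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_true(all(r$decisions))
  r2 <- holm_bonferroni(c(0.04, 0.04, 0.04), alpha = 0.05)
  expect_false(any(r2$decisions))
  r3 <- holm_bonferroni(numeric(0))
  expect_length(r3$decisions, 0L)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  # decisions map back to input order; 0.04 > 0.05/2 stops the step-down
  r4 <- holm_bonferroni(c(0.04, 0.001, 0.9), alpha = 0.05)
  expect_equal(r4$decisions, c(FALSE, TRUE, FALSE))
  r5 <- holm_bonferroni(c(0.02, 0.001, 0.9), alpha = 0.05)
  expect_equal(r5$decisions, c(TRUE, TRUE, FALSE))
})

test_that("gene parallelism summary lists genes hit in multiple populations", {
  m <- rbind(P1 = c(gA = 0.5, gB = 0.2), P2 = c(gA = 1.0, gB = 0),
             P3 = c(gA = 0.3, gB = 0))
  g <- gene_parallelism_summary(m)
  expect_equal(g$gene, "gA")
  expect_equal(g$n_populations, 3L)
  expect_equal(g$P2, 1.0)
  expect_equal(nrow(gene_parallelism_summary(m, min_populations = 4)), 0L)
})

test_that("nucleotide parallelism summary groups shared sites", {
  rec <- rbind(
    toy_records(population = "P1", position = 500L),
    toy_records(population = "P2", position = 500L),
    toy_records(population = "P3", position = 500L),
    toy_records(population = "P1", position = 900L))
  s <- nucleotide_parallelism_summary(rec)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 500L)
  expect_equal(s$n_populations, 3L)
  expect_equal(s$populations, "P1,P2,P3")
  distinct <- toy_records(population = c("P1", "P2"), position = c(1L, 2L))
  expect_equal(nrow(nucleotide_parallelism_summary(distinct)), 0L)
})
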