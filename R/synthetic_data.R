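# Synthetic evolution experiments with the statistical structure of a
# five-treatment (2x2 factorial + bead-size control), six-replicate design:
# ~15 mutation calls per population, ~15% fixed, uniform intermediate
# frequencies above the 0.05 detection floor, synonymous and distal-intergenic
# decoy calls to exercise the filters, and adaptive gene pools shared between
# treatments according to which environmental factors they have in common.

.treatment_grid <- function() {
  data.frame(
    treatment = c("hc_biofilm_lg", "hc_biofilm_sm", "hc_plank",
                  "lc_biofilm", "lc_plank"),
    carbon = c("high", "high", "high", "low", "low"),
    mode = c("biofilm", "biofilm", "planktonic", "biofilm", "planktonic"),
    bead = c("large", "small", "none", "large", "none"),
    stringsAsFactors = FALSE)
}

#' Configuration for a synthetic evolution experiment
#'
#' Defaults encode the study conditions being emulated: 5 treatments x 6
#' replicates, a Poisson mean of 15 mutation calls per population, a 0.15
#' fixation probability, intermediate frequencies uniform on
#' \[0.05, 0.95\], 13% synonymous and 6% distal-intergenic decoy calls, and
#' adaptive gene pools whose sharing follows the factorial structure
#' (a small globally beneficial pool, one pool per factor level, and one
#' private pool per factorial cell; the bead-size control shares the
#' high-carbon biofilm cell pool). `divergence` is the weight moved away from
#' the global pool; `factor_share` splits that weight between factor-level
#' and cell-private pools. The `low_carbon_tradeoff` switch makes low-carbon
#' populations skip the shared low-carbon pool (drawing factor-level genes
#' from their growth-mode pool only), which reproduces the near-zero
#' similarity between the two low-carbon environments.
#'
#' @param replicates Populations per treatment (default 6).
#' @param gene_count,gene_length,gene_gap Synthetic genome layout (bp).
#' @param operon_fraction Fraction of genes starting a 2-4 gene operon.
#' @param global_pool,factor_pool,treatment_pool Adaptive pool sizes (genes).
#' @param divergence Weight in \[0, 1\] shifted from the global pool toward
#'   factor and cell pools; 0 means a single shared pool.
#' @param factor_share Fraction of the shifted weight on factor-level pools
#'   (the rest is cell-private).
#' @param low_carbon_tradeoff See Description.
#' @param mutation_mean Poisson mean of calls per population.
#' @param fixation_prob Probability a call is fixed (frequency 1).
#' @param freq_range Range of the uniform intermediate-frequency law.
#' @param synonymous_fraction,distal_fraction Decoy call fractions.
#' @param upstream_prob Probability an adaptive call lands in the upstream
#'   window rather than the coding span.
#' @param upstream_window Upstream promoter window (bp).
#' @param upstream_hotspot Probability an upstream call hits the recurrent
#'   -61 site instead of a uniform distance (nucleotide-level parallelism).
#' @param fitness_base,fitness_slope,fitness_noise_sd True selection rate of
#'   a population in an environment is `base + slope * adaptive content` plus
#'   Gaussian noise, where content is the population's summed mutation
#'   frequency over genes adaptive in that environment.
#' @param assay_replicates Competition assays per population x environment.
#' @param ancestral_d0,ancestral_growth,assay_duration Ancestral competitor
#'   trajectory (CFU/mL, Malthusian rate per day, days).
#' @param count_noise Poisson colony-counting noise on observed densities.
#' @param target_colonies Colony count the simulated dilutions aim for.
#' @param drop_population Drop one high-carbon large-bead replicate from the
#'   usable set (emulating the excluded cross-contaminated replicate, 29
#'   usable populations).
#' @param seed Master seed for [generate_experiment()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(replicates = 6L,
                             gene_count = 500L,
                             gene_length = 900L,
                             gene_gap = 400L,
                             operon_fraction = 0.25,
                             global_pool = 3L,
                             factor_pool = 4L,
                             treatment_pool = 5L,
                             divergence = 0.9,
                             factor_share = 0.65,
                             low_carbon_tradeoff = TRUE,
                             mutation_mean = 15,
                             fixation_prob = 0.15,
                             freq_range = c(0.05, 0.95),
                             synonymous_fraction = 0.13,
                             distal_fraction = 0.06,
                             upstream_prob = 0.2,
                             upstream_window = 150L,
                             upstream_hotspot = 0.5,
                             fitness_base = 0.3,
                             fitness_slope = 0.35,
                             fitness_noise_sd = 0.15,
                             assay_replicates = 3L,
                             ancestral_d0 = 1e5,
                             ancestral_growth = 2.3,
                             assay_duration = 2,
                             count_noise = TRUE,
                             target_colonies = 200,
                             drop_population = TRUE,
                             seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(replicates >= 0, gene_count >= 1, gene_length >= 1, gene_gap >= 0,
              operon_fraction >= 0, operon_fraction <= 1,
              global_pool >= 0, factor_pool >= 0, treatment_pool >= 0,
              divergence >= 0, divergence <= 1,
              factor_share >= 0, factor_share <= 1,
              mutation_mean > 0, fixation_prob >= 0, fixation_prob <= 1,
              length(freq_range) == 2L, freq_range[1L] > 0,
              freq_range[2L] < 1, freq_range[1L] <= freq_range[2L],
              synonymous_fraction >= 0, distal_fraction >= 0,
              synonymous_fraction + distal_fraction < 1,
              upstream_prob >= 0, upstream_prob <= 1, upstream_window >= 0,
              upstream_hotspot >= 0, upstream_hotspot <= 1,
              assay_replicates >= 1, ancestral_d0 > 0, assay_duration > 0,
              target_colonies > 0)
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate the treatment design table
#'
#' Deterministic: the factorial grid is fixed and populations are named
#' `treatment_rN`.
#'
#' @param config A `synthetic_config`.
#' @return Design `data.frame` (population, treatment, carbon, mode, bead);
#'   5 treatments x `replicates` rows.
#' @export
generate_design <- function(config) {
  if (config$replicates < 1L) stop("replicates must be >= 1")
  if (config$replicates == 1L) {
    warning("replicates = 1: design unusable for within-treatment statistics")
  }
  grid <- .treatment_grid()
  des <- grid[rep(seq_len(nrow(grid)), each = config$replicates), , drop = FALSE]
  des$population <- paste0(des$treatment, "_r",
                           rep(seq_len(config$replicates), times = nrow(grid)))
  rownames(des) <- NULL
  validate_design(des[c("population", "treatment", "carbon", "mode", "bead")])
}

#' Generate a synthetic genome annotation
#'
#' Equally spaced genes on one replicon with random strands, consecutive-gene
#' operons, and gaps wide enough that upstream windows never collide.
#'
#' @param config A `synthetic_config`.
#' @param seed Optional seed (leave `NULL` when called from
#'   [generate_experiment()], which manages the RNG stream).
#' @return Annotation `data.frame` as from [read_gene_annotation()].
#' @export
synthetic_genome <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$gene_count
  step <- config$gene_length + config$gene_gap
  start <- 1000L + step * (seq_len(n) - 1L)
  genes <- data.frame(
    locus_tag = sprintf("g%04d", seq_len(n)),
    replicon = "chr1",
    start = start,
    end = start + config$gene_length - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    operon_id = NA_character_,
    product = "hypothetical protein",
    stringsAsFactors = FALSE)
  i <- 1L
  op <- 0L
  while (i <= n) {
    if (stats::runif(1) < config$operon_fraction) {
      size <- sample(2:4, 1L)
      idx <- i:min(i + size - 1L, n)
      op <- op + 1L
      genes$operon_id[idx] <- sprintf("op%03d", op)
      genes$strand[idx] <- genes$strand[i]
      i <- i + length(idx)
    } else {
      i <- i + 1L
    }
  }
  genes
}

# draw disjoint adaptive gene pools from the genome
.assign_pools <- function(config, genes) {
  cells <- unique(.treatment_grid()[c("carbon", "mode")])
  cell_ids <- paste(cells$carbon, cells$mode, sep = ":")
  pool_names <- c("global", "carbon:high", "carbon:low",
                  "mode:biofilm", "mode:planktonic",
                  paste0("cell:", cell_ids))
  sizes <- c(config$global_pool, rep(config$factor_pool, 4L),
             rep(config$treatment_pool, 4L))
  need <- sum(sizes)
  if (need > nrow(genes)) {
    stop("gene_count (", nrow(genes), ") too small for the requested pools (",
         need, " genes)")
  }
  picked <- sample(genes$locus_tag, need)
  split(picked, rep(pool_names, times = sizes))[pool_names[sizes > 0]]
}

# genes adaptive in the environment of a (carbon, mode) cell
.target_genes <- function(config, pools, carbon, mode) {
  out <- pools[["global"]]
  if (!(config$low_carbon_tradeoff && carbon == "low")) {
    out <- c(out, pools[[paste0("carbon:", carbon)]])
  }
  out <- c(out, pools[[paste0("mode:", mode)]])
  c(out, pools[[paste0("cell:", carbon, ":", mode)]])
}

.draw_frequency <- function(n, config) {
  fixed <- stats::runif(n) < config$fixation_prob
  f <- stats::runif(n, config$freq_range[1L], config$freq_range[2L])
  f[fixed] <- 1.0
  f
}

#' Generate a synthetic mutation table with ground truth
#'
#' Per population, the number of calls is Poisson(`mutation_mean`); each call
#' is a synonymous decoy, a distal-intergenic decoy, or an adaptive mutation
#' in a gene drawn from the global / factor-level / cell-private pool mixture
#' governed by `divergence` and `factor_share`. Adaptive calls land in the
#' coding span or, with probability `upstream_prob`, in the strand-aware
#' upstream window (with a recurrent -61 hotspot). Records carry their true
#' context columns (`assignment`, `gene`, `upstream_distance`), which
#' [assign_gene_contexts()] reproduces from the annotation.
#'
#' @param config A `synthetic_config`.
#' @param design Design `data.frame` (rows define the populations simulated).
#' @param genes Synthetic annotation from [synthetic_genome()].
#' @param seed Optional seed (see [synthetic_genome()]).
#' @return List with `records` (mutation table with truth columns) and
#'   `truth` (`pools`, per-population x environment `content`, and
#'   `true_rates`).
#' @export
generate_mutation_table <- function(config, design, genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- .assign_pools(config, genes)
  w_global <- 1 - config$divergence
  w_factor <- config$divergence * config$factor_share
  w_cell <- config$divergence * (1 - config$factor_share)
  if (w_global > 0 && config$global_pool == 0L) {
    stop("global pool is empty but carries positive draw weight")
  }
  if (w_factor > 0 && config$factor_pool == 0L) {
    stop("factor pools are empty but carry positive draw weight")
  }
  if (w_cell > 0 && config$treatment_pool == 0L) {
    stop("cell pools are empty but carry positive draw weight")
  }
  gidx <- stats::setNames(seq_len(nrow(genes)), genes$locus_tag)
  plus_far <- genes$locus_tag[genes$strand == "+" & genes$start > 300L]
  if (length(plus_far) == 0L) stop("no plus-strand gene far enough from the origin for distal decoys")
  rows <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    pop <- design$population[k]
    carbon <- design$carbon[k]
    mode <- design$mode[k]
    mix_genes <- list(
      global = pools[["global"]],
      factor = if (config$low_carbon_tradeoff && carbon == "low") {
        pools[[paste0("mode:", mode)]]
      } else {
        c(pools[[paste0("carbon:", carbon)]], pools[[paste0("mode:", mode)]])
      },
      cell = pools[[paste0("cell:", carbon, ":", mode)]])
    n <- stats::rpois(1L, config$mutation_mean)
    if (n == 0L) next
    cat_p <- c(synonymous = config$synonymous_fraction,
               distal = config$distal_fraction,
               adaptive = 1 - config$synonymous_fraction - config$distal_fraction)
    category <- sample(names(cat_p), n, replace = TRUE, prob = cat_p)
    gene <- character(n)
    position <- integer(n)
    coding_class <- character(n)
    locus_tag <- character(n)
    assignment <- character(n)
    updist <- rep(NA_integer_, n)
    for (m in seq_len(n)) {
      if (category[m] == "adaptive") {
        src <- sample(c("global", "factor", "cell"), 1L,
                      prob = c(w_global, w_factor, w_cell))
        g <- if (length(mix_genes[[src]]) == 1L) mix_genes[[src]] else sample(mix_genes[[src]], 1L)
        gi <- gidx[[g]]
        if (stats::runif(1) < config$upstream_prob && config$upstream_window > 0L) {
          d <- if (stats::runif(1) < config$upstream_hotspot && config$upstream_window >= 61L) {
            61L
          } else {
            sample.int(config$upstream_window, 1L)
          }
          position[m] <- if (genes$strand[gi] == "+") genes$start[gi] - d else genes$end[gi] + d
          coding_class[m] <- "intergenic"
          assignment[m] <- "upstream_of_gene"
          updist[m] <- d
        } else {
          position[m] <- sample(genes$start[gi]:genes$end[gi], 1L)
          coding_class[m] <- sample(c("nonsynonymous", "nonsense", "noncoding_in_gene"),
                                    1L, prob = c(0.85, 0.05, 0.10))
          assignment[m] <- "within_gene"
        }
        gene[m] <- g
        locus_tag[m] <- g
      } else if (category[m] == "synonymous") {
        g <- sample(genes$locus_tag, 1L)
        gi <- gidx[[g]]
        position[m] <- sample(genes$start[gi]:genes$end[gi], 1L)
        coding_class[m] <- "synonymous"
        assignment[m] <- "within_gene"
        gene[m] <- g
        locus_tag[m] <- g
      } else { # distal intergenic decoy, outside every upstream window
        g <- if (length(plus_far) == 1L) plus_far else sample(plus_far, 1L)
        gi <- gidx[[g]]
        position[m] <- genes$start[gi] - sample(160:240, 1L)
        coding_class[m] <- "intergenic"
        assignment[m] <- "distal_intergenic"
        gene[m] <- NA_character_
        locus_tag[m] <- ""
      }
    }
    rows[[k]] <- data.frame(
      population = pop, replicon = "chr1", position = position,
      mutation_type = sample(c("snp", "insertion", "deletion"), n,
                             replace = TRUE, prob = c(0.8, 0.1, 0.1)),
      coding_class = coding_class, locus_tag = locus_tag,
      frequency = .draw_frequency(n, config),
      assignment = assignment, gene = gene, upstream_distance = updist,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  if (is.null(records)) {
    records <- data.frame(population = character(0), replicon = character(0),
                          position = integer(0), mutation_type = character(0),
                          coding_class = character(0), locus_tag = character(0),
                          frequency = numeric(0), assignment = character(0),
                          gene = character(0), upstream_distance = integer(0),
                          stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  truth <- list(pools = pools)
  # adaptive content of every population in every environment, and the true
  # selection rates the competition assays are built around
  grid <- .treatment_grid()
  adaptive <- records[records$assignment %in% c("within_gene", "upstream_of_gene") &
                        records$coding_class != "synonymous", , drop = FALSE]
  content <- matrix(0, nrow = nrow(design), ncol = nrow(grid),
                    dimnames = list(design$population, grid$treatment))
  for (e in seq_len(nrow(grid))) {
    target <- .target_genes(config, pools, grid$carbon[e], grid$mode[e])
    hit <- adaptive$gene %in% target
    if (any(hit)) {
      s <- tapply(adaptive$frequency[hit], adaptive$population[hit], sum)
      content[names(s), e] <- s
    }
  }
  truth$content <- content
  rates <- expand.grid(population = design$population,
                       environment = grid$treatment,
                       stringsAsFactors = FALSE)
  rates$true_rate <- config$fitness_base +
    config$fitness_slope * content[cbind(rates$population, rates$environment)] +
    stats::rnorm(nrow(rates), sd = config$fitness_noise_sd)
  truth$true_rates <- rates
  list(records = records, truth = truth)
}

.noisy_density <- function(d, target_colonies) {
  dil <- 10^max(0, floor(log10(d / target_colonies)))
  obs <- stats::rpois(1L, d / dil) * dil
  tries <- 0L
  while (obs <= 0 && tries < 100L) {
    obs <- stats::rpois(1L, d / dil) * dil
    tries <- tries + 1L
  }
  if (obs <= 0) {
    warning("zero colony count persisted; substituting one colony")
    obs <- dil
  }
  obs
}

#' Generate competition-assay colony counts
#'
#' The ancestral competitor follows a fixed trajectory per environment; the
#' evolved competitor's final density is set so that the realised selection
#' rate equals the true rate exactly, then (optionally) all four observed
#' densities receive Poisson colony-counting noise at the simulated dilution.
#'
#' @param config A `synthetic_config`.
#' @param design Design `data.frame` (populations to assay).
#' @param truth Truth list from [generate_mutation_table()] (uses
#'   `true_rates`).
#' @param seed Optional seed (see [synthetic_genome()]).
#' @return Assay `data.frame` in the layout of [read_competition_table()],
#'   with the `true_rate` carried along for recovery checks.
#' @export
generate_competition_counts <- function(config, design, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- truth$true_rates
  tr <- tr[tr$population %in% design$population, , drop = FALSE]
  n <- nrow(tr)
  out <- tr[rep(seq_len(n), each = config$assay_replicates), , drop = FALSE]
  out$replicate <- rep(seq_len(config$assay_replicates), times = n)
  dur <- config$assay_duration
  a0 <- config$ancestral_d0
  a2 <- a0 * exp(config$ancestral_growth * dur)
  e0 <- a0
  e2 <- e0 * exp((config$ancestral_growth + out$true_rate) * dur)
  if (config$count_noise) {
    out$evolved_d0 <- vapply(rep(e0, n * config$assay_replicates),
                             .noisy_density, numeric(1), config$target_colonies)
    out$evolved_d2 <- vapply(e2, .noisy_density, numeric(1), config$target_colonies)
    out$ancestral_d0 <- vapply(rep(a0, n * config$assay_replicates),
                               .noisy_density, numeric(1), config$target_colonies)
    out$ancestral_d2 <- vapply(rep(a2, n * config$assay_replicates),
                               .noisy_density, numeric(1), config$target_colonies)
  } else {
    out$evolved_d0 <- e0
    out$evolved_d2 <- e2
    out$ancestral_d0 <- a0
    out$ancestral_d2 <- a2
  }
  out$duration <- dur
  rownames(out) <- NULL
  out[c("population", "environment", "replicate", "evolved_d0", "evolved_d2",
        "ancestral_d0", "ancestral_d2", "duration", "true_rate")]
}

#' Generate a complete synthetic experiment
#'
#' Seeds the RNG once from `config$seed` and draws the genome, design,
#' mutation table, truth, and competition counts in a fixed order, so equal
#' seeds give identical experiments. When `config$drop_population` is set,
#' the last high-carbon large-bead replicate is removed from the usable set
#' (emulating an excluded cross-contaminated replicate), leaving 29 usable
#' populations under the default design.
#'
#' @param config A `synthetic_config` (default: `synthetic_config()`).
#' @return List of class `synthetic_experiment` with `config`, `genes`,
#'   `design` (full), `usable_design`, `records`, `truth`, `assays`.
#' @export
generate_experiment <- function(config = synthetic_config()) {
  set.seed(config$seed)
  genes <- synthetic_genome(config)
  design <- generate_design(config)
  usable <- design
  if (isTRUE(config$drop_population)) {
    drop_pop <- utils::tail(usable$population[usable$treatment == "hc_biofilm_lg"], 1L)
    usable <- usable[usable$population != drop_pop, , drop = FALSE]
  }
  sim <- generate_mutation_table(config, usable, genes)
  assays <- generate_competition_counts(config, usable, sim$truth)
  structure(list(config = config, genes = genes, design = design,
                 usable_design = usable, records = sim$records,
                 truth = sim$truth, assays = assays),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to disk
#'
#' Emits exactly the file formats the readers consume: `mutations.tsv`
#' (canonical mutation columns only), `design.tsv`, `counts.tsv` (long
#' format), `genes.gff3`, `operons.tsv`, and `truth.json`.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mutation_table(experiment$records, file.path(dir, "mutations.tsv"))
  write.table(experiment$usable_design, file.path(dir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_annotation(experiment$genes, file.path(dir, "genes.gff3"))
  ops <- experiment$genes[!is.na(experiment$genes$operon_id),
                          c("locus_tag", "operon_id")]
  write.table(ops, file.path(dir, "operons.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  a <- experiment$assays
  long <- rbind(
    data.frame(population = a$population, environment = a$environment,
               competitor = "evolved", day = 0, cfu_per_ml = a$evolved_d0,
               replicate = a$replicate, stringsAsFactors = FALSE),
    data.frame(population = a$population, environment = a$environment,
               competitor = "evolved", day = a$duration, cfu_per_ml = a$evolved_d2,
               replicate = a$replicate, stringsAsFactors = FALSE),
    data.frame(population = a$population, environment = a$environment,
               competitor = "ancestral", day = 0, cfu_per_ml = a$ancestral_d0,
               replicate = a$replicate, stringsAsFactors = FALSE),
    data.frame(population = a$population, environment = a$environment,
               competitor = "ancestral", day = a$duration, cfu_per_ml = a$ancestral_d2,
               replicate = a$replicate, stringsAsFactors = FALSE))
  write.table(long, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- experiment$truth
  truth$content <- as.data.frame(truth$content)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Deterministic filter-accounting benchmark table
#'
#' Builds, without randomness, a mutation table with the printed class
#' composition of the emulated experiment: `n_total` calls spread
#' round-robin over `n_populations` populations, of which `n_synonymous` are
#' synonymous decoys, `n_distal` are intergenic calls 160-240 bp upstream of
#' a gene (outside the 150 bp promoter window), and the remainder are
#' unambiguously assignable, with `n_fixed` of those at frequency 1.0 and
#' the rest at intermediate frequencies in \[0.05, 0.95\].
#'
#' @param n_total,n_synonymous,n_distal,n_fixed,n_populations Class
#'   composition (defaults 432 / 55 / 25 / 51 / 29).
#' @return List with `records` and the matching `genes` annotation.
#' @export
benchmark_mutation_table <- function(n_total = 432L, n_synonymous = 55L,
                                     n_distal = 25L, n_fixed = 51L,
                                     n_populations = 29L) {
  n_assignable <- n_total - n_synonymous - n_distal
  stopifnot(n_assignable >= n_fixed, n_populations >= 1L)
  n_genes <- 60L
  start <- 1000L + 2000L * (seq_len(n_genes) - 1L)
  genes <- data.frame(locus_tag = sprintf("g%04d", seq_len(n_genes)),
                      replicon = "chr1", start = start, end = start + 899L,
                      strand = "+", operon_id = NA_character_,
                      product = NA_character_, stringsAsFactors = FALSE)
  k <- seq_len(n_total)
  pop <- sprintf("p%02d", (k - 1L) %% n_populations + 1L)
  gi <- (k - 1L) %% n_genes + 1L
  class_of <- rep("assignable", n_total)
  class_of[seq_len(n_synonymous)] <- "synonymous"
  class_of[n_synonymous + seq_len(n_distal)] <- "distal"
  assignable_idx <- which(class_of == "assignable")
  upstream <- rep(FALSE, n_total)
  upstream[assignable_idx[seq_along(assignable_idx) %% 5L == 0L]] <- TRUE
  position <- integer(n_total)
  coding_class <- character(n_total)
  locus_tag <- genes$locus_tag[gi]
  position <- genes$start[gi] + 10L + (k %% 800L)          # in-gene default
  coding_class[class_of == "assignable"] <- "nonsynonymous"
  coding_class[class_of == "synonymous"] <- "synonymous"
  position[class_of == "distal"] <- genes$start[gi[class_of == "distal"]] - 200L
  coding_class[class_of == "distal"] <- "intergenic"
  locus_tag[class_of == "distal"] <- ""
  position[upstream] <- genes$start[gi[upstream]] - 61L
  coding_class[upstream] <- "intergenic"
  frequency <- 0.05 + ((k * 37L) %% 91L) / 100
  frequency[class_of == "assignable"][seq_len(n_fixed)] <- 1.0
  records <- data.frame(population = pop, replicon = "chr1",
                        position = position, mutation_type = "snp",
                        coding_class = coding_class, locus_tag = locus_tag,
                        frequency = frequency, stringsAsFactors = FALSE)
  list(records = records, genes = genes)
}
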