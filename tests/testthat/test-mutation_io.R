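test_that("mutation tables round-trip through write/read, TSV and CSV", {
  rec <- rbind(
    toy_records(population = "p1", position = 120L, mutation_type = "snp",
                frequency = 0.5),
    toy_records(population = "p2", position = 999L, mutation_type = "deletion",
                coding_class = "intergenic", locus_tag = "", frequency = 1.0))
  for (ext in c("tsv", "csv")) {
    path <- file.path(withr::local_tempdir(), paste0("m.", ext))
    write_mutation_table(rec, path)
    back <- read_mutation_table(path)
    expect_equal(back, rec)
  }
})

test_that("column-name schema mapping and schema errors work", {
  path <- file.path(withr::local_tempdir(), "renamed.tsv")
  writeLines(c("pop\trep\tpos\ttype\tclass\tgene\tfreq",
               "p1\tchr1\t42\tsnp\tnonsynonymous\tg1\t0.25"), path)
  rec <- read_mutation_table(path, schema = c(
    population = "pop", replicon = "rep", position = "pos",
    mutation_type = "type", coding_class = "class", locus_tag = "gene",
    frequency = "freq"))
  expect_equal(rec$position, 42L)
  expect_equal(rec$frequency, 0.25)
  expect_error(read_mutation_table(path), "required column")
  expect_error(read_mutation_table(path, schema = c(population = "nope")),
               "nope")
})

test_that("header-only input gives an empty record list", {
  path <- file.path(withr::local_tempdir(), "empty.tsv")
  writeLines(paste(c("population", "replicon", "position", "mutation_type",
                     "coding_class", "locus_tag", "frequency"),
                   collapse = "\t"), path)
  rec <- read_mutation_table(path)
  expect_equal(nrow(rec), 0L)
  expect_type(rec$frequency, "double")
})

test_that("out-of-range frequencies are rejected with the row index", {
  dir <- withr::local_tempdir()
  bad <- toy_records(population = c("p1", "p2"), position = c(10L, 20L))
  bad$frequency <- c(0.5, 1.3)
  path <- file.path(dir, "bad.tsv")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "row\\(s\\) 2")
  bad$frequency <- c(0.5, "x")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "row\\(s\\) 2")
})

test_that("GFF3 annotation round-trips with strands and coordinates intact", {
  genes <- toy_genes(c("g1", "g2"), start = c(100L, 1000L),
                     end = c(400L, 1800L), strand = c("+", "-"))
  path <- file.path(withr::local_tempdir(), "genes.gff3")
  write_gene_annotation(genes, path)
  back <- read_gene_annotation(path)
  expect_equal(back[c("locus_tag", "replicon", "start", "end", "strand")],
               genes[c("locus_tag", "replicon", "start", "end", "strand")])
})

test_that("directive-only GFF3 yields an empty annotation", {
  path <- file.path(withr::local_tempdir(), "empty.gff3")
  writeLines("##gff-version 3", path)
  expect_equal(nrow(read_gene_annotation(path)), 0L)
})

test_that("features without locus_tag are skipped with a warning", {
  path <- file.path(withr::local_tempdir(), "untagged.gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t100\t400\t.\t+\t.\tID=a;locus_tag=g1",
               "chr1\t.\tgene\t600\t900\t.\t+\t.\tID=b"), path)
  expect_warning(ann <- read_gene_annotation(path), "locus_tag")
  expect_equal(ann$locus_tag, "g1")
})

test_that("operon sidecar table populates operon_id", {
  genes <- toy_genes(c("g1", "g2"), start = c(100L, 1000L),
                     end = c(400L, 1800L))
  path <- file.path(withr::local_tempdir(), "genes.gff3")
  write_gene_annotation(genes, path)
  ops <- data.frame(locus_tag = "g2", operon_id = "op1",
                    stringsAsFactors = FALSE)
  ann <- read_gene_annotation(path, operon_table = ops)
  expect_equal(ann$operon_id, c(NA, "op1"))
})

test_that("consecutive equal-frequency single-base indels consolidate", {
  runs <- toy_records(position = c(10L, 11L, 12L), mutation_type = "deletion",
                      frequency = 0.40)
  out <- consolidate_indels(runs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$position, 10L)
  expect_equal(out$frequency, 0.40)

  gap <- toy_records(position = c(10L, 12L), mutation_type = "deletion",
                     frequency = 0.40)
  expect_equal(nrow(consolidate_indels(gap)), 2L)

  diff_freq <- toy_records(position = c(10L, 11L), mutation_type = "deletion",
                           frequency = c(0.40, 0.60))
  expect_equal(nrow(consolidate_indels(diff_freq)), 2L)

  cross_pop <- rbind(
    toy_records(population = "p1", position = 10L, mutation_type = "insertion"),
    toy_records(population = "p2", position = 11L, mutation_type = "insertion"))
  expect_equal(nrow(consolidate_indels(cross_pop)), 2L)

  empty <- toy_records()[0, ]
  expect_equal(nrow(consolidate_indels(empty)), 0L)
})

test_that("indel consolidation is idempotent and never grows the table", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    rec <- toy_records(
      population = sample(c("p1", "p2"), n, replace = TRUE),
      position = sample(1:30, n, replace = TRUE),
      mutation_type = sample(c("snp", "insertion", "deletion"), n, TRUE),
      frequency = round(runif(n, 0.05, 1), 2))
    once <- consolidate_indels(rec)
    twice <- consolidate_indels(once)
    expect_lte(nrow(once), nrow(rec))
    expect_equal(twice, once)
  }
})

test_that("gene context assignment follows containment and strand-aware windows", {
  genes <- rbind(
    toy_genes("g1", 100L, 400L, "+"),
    toy_genes("g2", 1000L, 1900L, "-"),
    toy_genes("g3", 3000L, 4000L, "+"))
  ctx <- assign_gene_context(250L, "chr1", genes)
  expect_equal(ctx$assignment, "within_gene")
  expect_equal(ctx$gene, "g1")

  # minus-strand upstream window sits to the right of the gene
  ctx <- assign_gene_context(1950L, "chr1", genes)
  expect_equal(ctx$assignment, "upstream_of_gene")
  expect_equal(ctx$gene, "g2")
  expect_equal(ctx$upstream_distance, 50L)

  # plus-strand boundary arithmetic: 140 bp upstream in, 160 bp out
  expect_equal(assign_gene_context(2860L, "chr1", genes)$upstream_distance, 140L)
  expect_equal(assign_gene_context(2840L, "chr1", genes)$assignment,
               "distal_intergenic")
})

test_that("upstream window boundary is inclusive at window and exclusive beyond, both strands", {
  genes <- rbind(toy_genes("plus", 1000L, 1900L, "+"),
                 toy_genes("minus", 5000L, 5900L, "-"))
  expect_equal(assign_gene_context(850L, "chr1", genes, window = 150L)$assignment,
               "upstream_of_gene")
  expect_equal(assign_gene_context(849L, "chr1", genes, window = 150L)$assignment,
               "distal_intergenic")
  expect_equal(assign_gene_context(6050L, "chr1", genes, window = 150L)$assignment,
               "upstream_of_gene")
  expect_equal(assign_gene_context(6051L, "chr1", genes, window = 150L)$assignment,
               "distal_intergenic")
})

test_that("overlapping genes and overlapping windows are flagged, in-gene wins over windows", {
  genes <- rbind(
    toy_genes("a", 100L, 500L, "+"),
    toy_genes("b", 400L, 900L, "+"),      # overlaps a
    toy_genes("c", 2000L, 2500L, "-"),    # window 2501..2650
    toy_genes("d", 2700L, 3200L, "+"))    # window 2550..2699
  expect_equal(assign_gene_context(450L, "chr1", genes)$assignment, "multi_gene")
  expect_equal(assign_gene_context(2600L, "chr1", genes)$assignment, "ambiguous")
  # inside gene d but also within c's window region? containment has priority
  genes2 <- rbind(
    toy_genes("c", 2000L, 2500L, "-"),
    toy_genes("d", 2520L, 3200L, "+"))
  ctx <- assign_gene_context(2550L, "chr1", genes2)
  expect_equal(ctx$assignment, "within_gene")
  expect_equal(ctx$gene, "d")
})

test_that("every record gets exactly one assignment and unknown replicons error", {
  genes <- toy_genes("g1", 100L, 400L)
  set.seed(7)
  rec <- toy_records(position = sample(1:1200, 50, replace = TRUE))
  out <- assign_gene_contexts(rec, genes)
  expect_true(all(out$assignment %in%
    c("within_gene", "upstream_of_gene", "ambiguous", "distal_intergenic",
      "multi_gene")))
  expect_false(anyNA(out$assignment))
  bad <- toy_records(replicon = "plasmid9")
  expect_error(assign_gene_contexts(bad, genes), "plasmid9")
  expect_error(assign_gene_context(10L, "plasmid9", genes), "plasmid9")
})

test_that("design tables validate populations and factor levels", {
  des <- toy_design(c("p1", "p2"), c("t1", "t2"))
  path <- file.path(withr::local_tempdir(), "design.tsv")
  write.table(des, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_design_table(path), des)
  expect_error(validate_design(toy_design(c("p1", "p1"), c("t1", "t2"))),
               "more than one treatment")
  bad <- toy_design("p1", "t1")
  bad$carbon <- "medium"
  expect_error(validate_design(bad), "carbon")
})

test_that("competition counts reshape to one row per assay", {
  long <- expand.grid(population = c("p1", "p2"), environment = "e1",
                      competitor = c("evolved", "ancestral"), day = c(0, 2),
                      stringsAsFactors = FALSE)
  long$cfu_per_ml <- seq(1e5, by = 1e5, length.out = nrow(long))
  path <- file.path(withr::local_tempdir(), "counts.tsv")
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  assays <- read_competition_table(path)
  expect_equal(nrow(assays), 2L)
  expect_equal(assays$duration, c(2, 2))
  p1 <- assays[assays$population == "p1", ]
  expect_equal(p1$evolved_d0,
               long$cfu_per_ml[long$population == "p1" &
                                 long$competitor == "evolved" & long$day == 0])
})
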