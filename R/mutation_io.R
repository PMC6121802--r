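#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

# canonical column set for curated mutation tables
.mutation_columns <- c("population", "replicon", "position", "mutation_type",
                       "coding_class", "locus_tag", "frequency")

.mutation_types <- c("snp", "insertion", "deletion", "mobile_element", "other")

.coding_classes <- c("nonsynonymous", "synonymous", "nonsense",
                     "noncoding_in_gene", "intergenic", "multi_gene")

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a curated mutation table
#'
#' Reads a per-population mutation call table (TSV or CSV, one row per curated
#' mutation) as produced downstream of polymorphism-mode variant calling.
#' Columns can be renamed in the file and mapped back via `schema`.
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column names
#'   (`population`, `replicon`, `position`, `mutation_type`, `coding_class`,
#'   `locus_tag`, `frequency`) to the column names used in the file, e.g.
#'   `c(population = "pop", frequency = "freq")`. Unmapped canonical names are
#'   assumed to appear verbatim.
#' @return A `data.frame` with the canonical columns; `position` integer,
#'   `frequency` numeric in (0, 1].
#' @details Rows with a frequency that does not parse, or that falls outside
#'   (0, 1], abort with an error reporting the offending data row numbers: a
#'   curated table should never contain them, so they indicate an upstream
#'   curation fault rather than data to be silently dropped.
#' @export
read_mutation_table <- function(path, schema = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("mutation table not found: ", path)
  raw <- read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  wanted <- setNames(.mutation_columns, .mutation_columns)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), .mutation_columns)
    if (length(bad)) stop("unknown canonical column(s) in schema: ",
                          paste(bad, collapse = ", "))
    wanted[names(schema)] <- unname(schema)
  }
  missing <- wanted[!wanted %in% names(raw)]
  if (length(missing)) {
    stop("mutation table ", path, " lacks required column(s): ",
         paste(sprintf("'%s' (for %s)", missing, names(missing)), collapse = ", "))
  }
  rec <- setNames(raw[unname(wanted)], names(wanted))
  if (nrow(rec) == 0L) {
    rec$position <- integer(0)
    rec$frequency <- numeric(0)
    return(rec)
  }
  pos <- suppressWarnings(as.integer(rec$position))
  bad_pos <- which(is.na(pos) | pos < 1L)
  if (length(bad_pos)) {
    stop("unparseable or non-positive position in mutation table row(s) ",
         paste(head(bad_pos, 10L), collapse = ", "),
         " (data rows, header excluded)")
  }
  freq <- suppressWarnings(as.numeric(rec$frequency))
  bad_freq <- which(is.na(freq) | freq <= 0 | freq > 1)
  if (length(bad_freq)) {
    stop("frequency outside (0, 1] or unparseable in mutation table row(s) ",
         paste(head(bad_freq, 10L), collapse = ", "),
         " (data rows, header excluded); offending values: ",
         paste(head(rec$frequency[bad_freq], 10L), collapse = ", "))
  }
  rec$position <- pos
  rec$frequency <- freq
  unknown_type <- setdiff(unique(rec$mutation_type), .mutation_types)
  if (length(unknown_type)) {
    warning("unrecognised mutation_type value(s) kept as-is: ",
            paste(unknown_type, collapse = ", "))
  }
  unknown_class <- setdiff(unique(rec$coding_class), .coding_classes)
  if (length(unknown_class)) {
    warning("unrecognised coding_class value(s) kept as-is: ",
            paste(unknown_class, collapse = ", "))
  }
  rownames(rec) <- NULL
  rec
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]; writes the canonical columns as TSV
#' (or CSV if the path ends in `.csv`).
#'
#' @param records Mutation record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  write.table(records[.mutation_columns], path, sep = .delim_for(path),
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Imports gene (or, failing that, CDS) features carrying a `locus_tag`
#' attribute and returns a flat annotation table. Coordinates are kept exactly
#' as in the file (1-based, inclusive). Operon membership, which GFF3 does not
#' carry, can be supplied as a two-column sidecar table.
#'
#' @param path GFF3 file.
#' @param operon_table Optional path to a TSV with columns `locus_tag` and
#'   `operon_id`, or a `data.frame` with those columns.
#' @return `data.frame` with columns `locus_tag`, `replicon`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `operon_id` (`NA` when unknown), `product`.
#' @export
read_gene_annotation <- function(path, operon_table = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df)) {
    keep_type <- if (any(df$type == "gene")) "gene" else "CDS"
    df <- df[df$type == keep_type, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(data.frame(locus_tag = character(0), replicon = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), operon_id = character(0),
                      product = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(df$locus_tag)) df$locus_tag <- NA_character_
  n_missing <- sum(is.na(df$locus_tag) | df$locus_tag == "")
  if (n_missing > 0L) {
    warning(n_missing, " feature(s) lacking a locus_tag attribute were skipped")
    df <- df[!(is.na(df$locus_tag) | df$locus_tag == ""), , drop = FALSE]
  }
  if (anyDuplicated(df$locus_tag)) {
    stop("duplicated locus_tag in annotation: ",
         paste(unique(df$locus_tag[duplicated(df$locus_tag)]), collapse = ", "))
  }
  ann <- data.frame(locus_tag = as.character(df$locus_tag),
                    replicon = as.character(df$seqnames),
                    start = as.integer(df$start),
                    end = as.integer(df$end),
                    strand = as.character(df$strand),
                    operon_id = NA_character_,
                    product = if (is.null(df$product)) NA_character_ else as.character(df$product),
                    stringsAsFactors = FALSE)
  if (any(!ann$strand %in% c("+", "-"))) {
    stop("gene feature(s) with unstranded coordinates: ",
         paste(ann$locus_tag[!ann$strand %in% c("+", "-")], collapse = ", "))
  }
  if (!is.null(operon_table)) {
    op <- if (is.character(operon_table)) {
      read.delim(operon_table, stringsAsFactors = FALSE)
    } else {
      operon_table
    }
    stopifnot(all(c("locus_tag", "operon_id") %in% names(op)))
    idx <- match(ann$locus_tag, op$locus_tag)
    ann$operon_id <- as.character(op$operon_id[idx])
  }
  rownames(ann) <- NULL
  ann
}

#' Write gene annotation as GFF3
#'
#' @param genes Annotation `data.frame` as returned by [read_gene_annotation()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$locus_tag
  gr$locus_tag <- genes$locus_tag
  if (!is.null(genes$product)) gr$product <- genes$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a treatment design table
#'
#' @param path TSV with columns `population`, `treatment`, `carbon`
#'   (`high`/`low`), `mode` (`biofilm`/`planktonic`), `bead`
#'   (`large`/`small`/`none`).
#' @return A validated `data.frame` with those columns.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop("design table not found: ", path)
  des <- read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  validate_design(des)
}

#' Validate a treatment design
#'
#' Checks the population-to-treatment mapping and factor levels used by the
#' similarity and randomization machinery.
#'
#' @param design Design `data.frame`.
#' @return `design`, invisibly usable (returned after validation).
#' @export
validate_design <- function(design) {
  need <- c("population", "treatment", "carbon", "mode", "bead")
  missing <- setdiff(need, names(design))
  if (length(missing)) stop("design lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(design$population)) {
    stop("population(s) mapped to more than one treatment: ",
         paste(unique(design$population[duplicated(design$population)]), collapse = ", "))
  }
  chk <- function(col, levels) {
    bad <- setdiff(unique(design[[col]]), levels)
    if (length(bad)) stop("invalid ", col, " level(s): ", paste(bad, collapse = ", "))
  }
  chk("carbon", c("high", "low"))
  chk("mode", c("biofilm", "planktonic"))
  chk("bead", c("large", "small", "none"))
  per_trt <- unique(design[c("treatment", "carbon", "mode", "bead")])
  if (anyDuplicated(per_trt$treatment)) {
    stop("treatment(s) with inconsistent factor levels: ",
         paste(unique(per_trt$treatment[duplicated(per_trt$treatment)]), collapse = ", "))
  }
  design
}

#' Read competition-assay colony counts
#'
#' Reads a long-format colony-count table and reshapes it into one row per
#' assay (population x environment x replicate) with the four densities the
#' selection-rate formula needs.
#'
#' @param path TSV with columns `population`, `environment`, `competitor`
#'   (`evolved`/`ancestral`), `day` (0 or the final day), `cfu_per_ml`,
#'   and optionally `replicate`.
#' @return `data.frame` with columns `population`, `environment`, `replicate`,
#'   `evolved_d0`, `evolved_d2`, `ancestral_d0`, `ancestral_d2`, `duration`.
#' @export
read_competition_table <- function(path) {
  if (!file.exists(path)) stop("competition count table not found: ", path)
  cc <- read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  need <- c("population", "environment", "competitor", "day", "cfu_per_ml")
  missing <- setdiff(need, names(cc))
  if (length(missing)) stop("competition table lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (is.null(cc$replicate)) cc$replicate <- 1L
  bad <- setdiff(unique(cc$competitor), c("evolved", "ancestral"))
  if (length(bad)) stop("invalid competitor value(s): ", paste(bad, collapse = ", "))
  days <- sort(unique(cc$day))
  if (length(days) != 2L) stop("competition table must contain exactly two sampling days, got: ",
                               paste(days, collapse = ", "))
  duration <- diff(days)
  key <- interaction(cc$population, cc$environment, cc$replicate, drop = TRUE)
  out <- do.call(rbind, lapply(split(cc, key), function(a) {
    pick <- function(who, day) {
      v <- a$cfu_per_ml[a$competitor == who & a$day == day]
      if (length(v) != 1L) {
        stop("assay (", a$population[1L], ", ", a$environment[1L], ", replicate ",
             a$replicate[1L], ") needs exactly one ", who, " count at day ", day)
      }
      v
    }
    data.frame(population = a$population[1L], environment = a$environment[1L],
               replicate = a$replicate[1L],
               evolved_d0 = pick("evolved", days[1L]),
               evolved_d2 = pick("evolved", days[2L]),
               ancestral_d0 = pick("ancestral", days[1L]),
               ancestral_d2 = pick("ancestral", days[2L]),
               duration = duration, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Consolidate runs of single-base indels
#'
#' Sequencing pipelines report a multi-base insertion or deletion as a run of
#' single-base calls at consecutive positions. Runs of same-population,
#' same-replicon, same-type insertion or deletion calls at consecutive
#' positions whose frequencies agree within `tol` are merged into a single
#' record at the first position of the run, with the run's mean frequency.
#'
#' @param records Mutation record `data.frame`.
#' @param tol Frequency agreement tolerance between adjacent calls
#'   (default 0.01; pooled-sequencing frequencies are noisy at the third
#'   decimal).
#' @return `data.frame` with merged indel runs; all non-indel records are
#'   untouched. Idempotent.
#' @export
consolidate_indels <- function(records, tol = 0.01) {
  if (nrow(records) == 0L) return(records)
  is_indel <- records$mutation_type %in% c("insertion", "deletion")
  if (!any(is_indel)) return(records)
  ind <- records[is_indel, , drop = FALSE]
  rest <- records[!is_indel, , drop = FALSE]
  o <- order(ind$population, ind$replicon, ind$mutation_type, ind$position)
  ind <- ind[o, , drop = FALSE]
  n <- nrow(ind)
  same_run <- c(FALSE, ind$population[-1L] == ind$population[-n] &
                  ind$replicon[-1L] == ind$replicon[-n] &
                  ind$mutation_type[-1L] == ind$mutation_type[-n] &
                  ind$position[-1L] == ind$position[-n] + 1L &
                  abs(ind$frequency[-1L] - ind$frequency[-n]) <= tol)
  run_id <- cumsum(!same_run)
  merged <- do.call(rbind, lapply(split(ind, run_id), function(run) {
    out <- run[1L, , drop = FALSE]
    out$frequency <- mean(run$frequency)
    out
  }))
  out <- rbind(rest, merged)
  out <- out[order(out$population, out$replicon, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# context assignment internals ------------------------------------------------

.context_one <- function(position, genes, window) {
  inside <- which(position >= genes$start & position <= genes$end)
  if (length(inside) == 1L) {
    return(list(assignment = "within_gene", gene = genes$locus_tag[inside],
                upstream_distance = NA_integer_))
  }
  if (length(inside) >= 2L) {
    return(list(assignment = "multi_gene", gene = NA_character_,
                upstream_distance = NA_integer_))
  }
  up_plus <- genes$strand == "+" &
    position >= genes$start - window & position <= genes$start - 1L
  up_minus <- genes$strand == "-" &
    position >= genes$end + 1L & position <= genes$end + window
  hits <- which(up_plus | up_minus)
  if (length(hits) == 1L) {
    d <- if (genes$strand[hits] == "+") genes$start[hits] - position else position - genes$end[hits]
    return(list(assignment = "upstream_of_gene", gene = genes$locus_tag[hits],
                upstream_distance = as.integer(d)))
  }
  if (length(hits) >= 2L) {
    return(list(assignment = "ambiguous", gene = NA_character_,
                upstream_distance = NA_integer_))
  }
  list(assignment = "distal_intergenic", gene = NA_character_,
       upstream_distance = NA_integer_)
}

#' Assign a gene context to a single genomic position
#'
#' Implements the unambiguous-assignment rule: a position inside exactly one
#' gene is `within_gene`; inside two or more overlapping genes, `multi_gene`;
#' intergenic but inside the strand-aware upstream window (`[start - window,
#' start - 1]` for `+` genes, `[end + 1, end + window]` for `-` genes) of
#' exactly one gene, `upstream_of_gene` with its distance; in the windows of
#' two or more genes, `ambiguous`; otherwise `distal_intergenic`. Containment
#' takes priority over any upstream window.
#'
#' @param position 1-based reference position.
#' @param replicon Replicon (chromosome/plasmid) identifier.
#' @param genes Annotation `data.frame` (see [read_gene_annotation()]).
#' @param window Upstream promoter window in bp (default 150).
#' @return One-row `data.frame` with `assignment`, `gene`, `upstream_distance`.
#' @export
assign_gene_context <- function(position, replicon, genes, window = 150L) {
  stopifnot(length(position) == 1L, window >= 0)
  g <- genes[genes$replicon == replicon, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown replicon: ", replicon)
  ctx <- .context_one(position, g, window)
  data.frame(assignment = ctx$assignment, gene = ctx$gene,
             upstream_distance = ctx$upstream_distance,
             stringsAsFactors = FALSE)
}

#' Assign gene contexts to a whole mutation table
#'
#' Vectorised wrapper around [assign_gene_context()]; appends `assignment`,
#' `gene`, and `upstream_distance` columns to the record table. Every record
#' receives exactly one assignment.
#'
#' @param records Mutation record `data.frame`.
#' @param genes Annotation `data.frame`.
#' @param window Upstream window in bp (default 150).
#' @return `records` with the three context columns appended.
#' @export
assign_gene_contexts <- function(records, genes, window = 150L) {
  n <- nrow(records)
  records$assignment <- character(n)
  records$gene <- NA_character_
  records$upstream_distance <- NA_integer_
  if (n == 0L) return(records)
  unknown <- setdiff(unique(records$replicon), unique(genes$replicon))
  if (length(unknown)) stop("unknown replicon(s): ", paste(unknown, collapse = ", "))
  for (rep_id in unique(records$replicon)) {
    g <- genes[genes$replicon == rep_id, , drop = FALSE]
    idx <- which(records$replicon == rep_id)
    for (i in idx) {
      ctx <- .context_one(records$position[i], g, window)
      records$assignment[i] <- ctx$assignment
      records$gene[i] <- ctx$gene
      records$upstream_distance[i] <- ctx$upstream_distance
    }
  }
  records
}
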