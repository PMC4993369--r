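#' Simulate a complete synthetic dataset
#'
#' Runs the whole generator under one master seed: genome annotation with
#' ground truth, raw coverage tracks for every supported mark in both
#' strains, RNA-seq counts for a two-strain two-condition design with the
#' given replication, and an observed peptide-form table.
#'
#' @param config a [sim_config()].
#' @param n_reps replicates per strain x condition group.
#' @param marks which marks to simulate coverage for.
#' @param noise_concentration Dirichlet concentration for the peptide table.
#' @return list with `config`, `annotation`, `truth`, `tracks` (nested list
#'   `tracks[[mark]][[strain]]`), `design`, `counts`, `peptides`.
#' @export
simulate_dataset <- function(config = sim_config(), n_reps = 3L,
                             marks = SUPPORTED_MARKS,
                             noise_concentration = 200) {
  g <- gen_genome(config)
  design <- expand.grid(rep = seq_len(n_reps), strain = c("WT", "mutant"),
                        condition = c("PM", "SM48"), stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d", design$strain, design$condition, design$rep)
  design <- design[, c("sample_id", "strain", "condition")]
  counts <- gen_counts(g$annotation, g$truth, design, config)
  tracks <- lapply(stats::setNames(marks, marks), function(mk)
    lapply(stats::setNames(c("WT", "mutant"), c("WT", "mutant")), function(st)
      gen_coverage(g$annotation, g$truth, mk, st, config)))
  peptides <- gen_peptide_table(g$truth$peptides, noise_concentration,
                                seed = child_seed(config$seed, "peptide-table"))
  list(config = config, annotation = g$annotation, truth = g$truth,
       tracks = tracks, design = design, counts = counts, peptides = peptides)
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Writes the annotation as GFF3 and BED6, every coverage track as bedGraph
#' (with a sidecar of total mapped reads in the manifest), counts, design,
#' categories, peptide abundances and the per-gene/per-cluster ground truth
#' as TSV, and a manifest listing every file with its MD5 checksum.
#'
#' @param sim result of [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame (file, md5, total_mapped_reads where
#'   applicable), invisibly; also written as `manifest.tsv`.
#' @export
write_fixtures <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); totals <- numeric(0)
  put <- function(name, total = NA_real_) {
    files <<- c(files, name); totals <<- c(totals, total)
    file.path(out_dir, name)
  }
  write_gff3(sim$annotation, put("annotation.gff3"))
  write_bed6(sim$annotation, put("annotation.bed"))
  for (mk in names(sim$tracks)) for (st in names(sim$tracks[[mk]])) {
    tr <- sim$tracks[[mk]][[st]]
    write_bedgraph(tr, put(sprintf("coverage_%s_%s.bedgraph", mk, st),
                           total = tr$total_mapped_reads))
  }
  wtsv <- function(df, name) utils::write.table(
    df, put(name), sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- sim$counts
  wtsv(data.frame(gene_id = rownames(cm$counts), cm$counts,
                  check.names = FALSE), "counts.tsv")
  wtsv(sim$design, "design.tsv")
  wtsv(data.frame(gene_id = sim$annotation$gene_id,
                  category = sim$annotation$category,
                  cluster_id = ifelse(is.na(sim$annotation$cluster_id), ".",
                                      sim$annotation$cluster_id)),
       "categories.tsv")
  wtsv(sim$peptides, "peptides.tsv")
  wtsv(sim$truth$genes, "truth_genes.tsv")
  if (!is.null(sim$truth$clusters)) wtsv(sim$truth$clusters, "truth_clusters.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    total_mapped_reads = totals, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a genome annotation as GFF3 (1-based, inclusive)
#' @param annotation a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- sprintf("ID=%s;category=%s%s", annotation$gene_id, annotation$category,
                   ifelse(is.na(annotation$cluster_id), "",
                          paste0(";cluster_id=", annotation$cluster_id)))
  writeLines(sprintf("%s\tchromexpr\tgene\t%d\t%d\t.\t%s\t.\t%s",
                     annotation$chrom, annotation$start + 1L, annotation$end,
                     annotation$strand, attrs), con)
  invisible(path)
}

#' Write a genome annotation as BED6 (0-based, half-open)
#' @param annotation a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(annotation, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", annotation$chrom,
                     annotation$start, annotation$end, annotation$gene_id,
                     annotation$strand), path)
  invisible(path)
}

#' Read a GFF3 gene annotation written by [write_gff3()]
#'
#' Coordinates are converted to the package's internal 0-based half-open
#' convention on read.
#'
#' @param path GFF3 file with `gene` features carrying `ID` (and optionally
#'   `category`, `cluster_id`) attributes.
#' @return a `genome_annotation` data.frame.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, integer(1)) != 9L)
  if (length(bad)) stop("GFF3 line ", bad[1], ": expected 9 tab-separated fields")
  f <- do.call(rbind, f)
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
  }
  ann <- data.frame(
    gene_id = attr_get(f[, 9], "ID"),
    chrom = f[, 1],
    start = as.integer(f[, 4]) - 1L,
    end = as.integer(f[, 5]),
    strand = f[, 7],
    stringsAsFactors = FALSE)
  ann$orf_length <- ann$end - ann$start
  ann$category <- attr_get(f[, 9], "category")
  ann$cluster_id <- attr_get(f[, 9], "cluster_id")
  if (anyNA(ann$gene_id)) stop("GFF3 gene feature without an ID attribute")
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene IDs in GFF3")
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}
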