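#' Pipeline configuration
#'
#' Collects every stage's parameters for an end-to-end run on a simulated
#' dataset.  Validation happens before any computation: parameter ranges
#' are checked here and missing inputs fail fast.
#'
#' @param sim a [sim_config()] for the synthetic dataset.
#' @param n_reps replicates per strain x condition group.
#' @param condition which condition the integrate stages analyse
#'   (`"SM48"`, the nutrient-limited phase, by default).
#' @param de_profile threshold profile name from [de_profiles()].
#' @param k4_threshold log2 threshold splitting low/high H3K4me3.
#' @param window_step metagene bin width, bp.
#' @param smooth_window,smooth_step sliding-window smoothing parameters, bp.
#' @param k9_min_len,k9_merge_gap,k9_max_gap domain-calling and flanking
#'   parameters, bp.
#' @param out_dir output directory for the report bundle.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_reps = 3L,
                            condition = "SM48", de_profile = "fdr05",
                            k4_threshold = 5, window_step = 10L,
                            smooth_window = 100L, smooth_step = 10L,
                            k9_min_len = 2000L, k9_merge_gap = 500L,
                            k9_max_gap = 5000L, out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (!condition %in% c("PM", "SM48")) stop("condition must be PM or SM48")
  if (!de_profile %in% names(de_profiles()))
    stop("unknown DE profile '", de_profile, "'")
  if (smooth_window < smooth_step) stop("smooth_window must be >= smooth_step")
  if (n_reps < 2) stop("need >= 2 replicates per group")
  structure(list(sim = sim, n_reps = as.integer(n_reps), condition = condition,
                 de_profile = de_profile, k4_threshold = k4_threshold,
                 window_step = as.integer(window_step),
                 smooth_window = as.integer(smooth_window),
                 smooth_step = as.integer(smooth_step),
                 k9_min_len = as.integer(k9_min_len),
                 k9_merge_gap = as.integer(k9_merge_gap),
                 k9_max_gap = as.integer(k9_max_gap),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full chromatin-transcriptome integration pipeline
#'
#' Simulates a dataset, then runs every analysis stage in the canonical
#' order: CPM normalization and smoothing of the coverage tracks; metagene
#' profiles per mark and strain; per-gene H3K4me3 quantification; TMM +
#' moderated-t differential expression (mutant vs WT in the configured
#' condition); low/high mark split and G-group assignment; SM-category
#' enrichment among the genes requiring the regulator; per-category
#' deregulation percentages and mark-level summaries; H3K9me3 domain
#' calling and SM-cluster flanking; and the peptide stoichiometry summary.
#' Deterministic given the configuration (including its seed).  If
#' `config$out_dir` is set, every result table is written as TSV together
#' with a log of parameters and input checksums.
#'
#' @param config a [pipeline_config()].
#' @return a named list of stage results (class `pipeline_report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- stage("simulate", simulate_dataset(config$sim, n_reps = config$n_reps))

  # tracks: CPM + smoothing
  norm <- stage("tracks", lapply(sim$tracks, function(by_strain)
    lapply(by_strain, cpm_normalize)))
  smoothed <- stage("tracks", lapply(norm, function(by_strain)
    lapply(by_strain, smooth_and_bin,
           window = config$smooth_window, step = config$smooth_step)))

  # metagene profiles (ATG window for 5' marks, STOP window for H3K36me3)
  spec_of <- function(mark) if (mark == "H3K36me3")
    window_spec("STOP", upstream = 1500, downstream = 500)
  else window_spec("ATG", upstream = 500, downstream = 1500)
  profiles <- stage("metagene", {
    out <- list()
    for (mk in names(norm)) for (st in names(norm[[mk]])) {
      gwm <- gene_windows(norm[[mk]][[st]], sim$annotation, spec_of(mk),
                          step = config$window_step)
      out[[paste(mk, st, sep = ".")]] <- metagene_profile(gwm)
    }
    out
  })

  # per-gene H3K4me3 quantification (WT)
  quant <- stage("metagene", quantify_gene_mark(
    sim$tracks$H3K4me3$WT, sim$annotation, spec_of("H3K4me3"),
    step = config$window_step, read_length = config$sim$read_length))

  # differential expression, mutant vs WT in the configured condition
  contrast <- paste(c("mutant", "WT"), config$condition, sep = ".")
  de <- stage("diffexpr", de_test(sim$counts, contrast))
  de <- classify_de(de, profile = config$de_profile)
  de_calls <- stats::setNames(de$call, de$gene_id)

  # mark tiers and G groups
  tiers <- stage("integrate", split_by_mark(quant, threshold = config$k4_threshold))
  groups <- stage("integrate", assign_groups(
    tiers$tiers, de_calls, offset = if (config$condition == "SM48") 4L else 0L))

  # category analyses
  categories <- stats::setNames(sim$annotation$category, sim$annotation$gene_id)
  down_genes <- de$gene_id[de$call == "up_in_WT"]
  enrichment <- stage("integrate", category_enrichment(
    down_genes, categories, "SM"))
  dereg <- stage("integrate", deregulation_fractions(de_calls, categories))
  lev <- stats::setNames(quant$log2_window_cpm, quant$gene_id)
  mark_summary <- stage("integrate", category_mark_summary(lev, categories))

  # H3K9me3 domains and cluster flanking
  k9 <- smoothed$H3K9me3$WT
  domains <- stage("integrate", call_k9_domains(
    k9, min_len = config$k9_min_len, merge_gap = config$k9_merge_gap))
  flanking <- stage("integrate", cluster_flanking(
    domains, sim$annotation, max_gap = config$k9_max_gap))

  stoich <- stage("stoichiometry", stoichiometry_summary(sim$peptides))

  report <- structure(list(
    config = config, sim = sim, profiles = profiles, quant = quant,
    de = de, tiers = tiers, groups = groups, enrichment = enrichment,
    deregulation = dereg, mark_summary = mark_summary, domains = domains,
    flanking = flanking, stoichiometry = stoich),
    class = "pipeline_report")
  if (!is.null(config$out_dir))
    write_report(report, config$out_dir, elapsed = Sys.time() - t0)
  report
}

#' Write a pipeline report bundle as TSV files
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @param elapsed optional run duration for the log.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, elapsed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$profiles))
    wtsv(report$profiles[[nm]], sprintf("metagene_%s.tsv", nm))
  wtsv(report$quant, "mark_quant_H3K4me3_WT.tsv")
  wtsv(report$de, "de_results.tsv")
  wtsv(report$groups, "gene_groups.tsv")
  wtsv(data.frame(group = names(attr(report$groups, "counts")),
                  n = as.integer(attr(report$groups, "counts"))),
       "group_counts.tsv")
  e <- report$enrichment
  wtsv(data.frame(set = "down_in_mutant", category = "SM", k = e$k, K = e$K,
                  n = e$n, N = e$N, odds_ratio = e$odds_ratio, p = e$p),
       "enrichment.tsv")
  wtsv(report$deregulation, "deregulation_fractions.tsv")
  wtsv(report$mark_summary$summary, "category_mark_summary.tsv")
  if (!is.null(report$mark_summary$tests))
    wtsv(report$mark_summary$tests, "category_mark_tests.tsv")
  wtsv(report$domains, "k9_domains.tsv")
  write_domains_bed(report$domains, file.path(out_dir, "k9_domains.bed"))
  wtsv(report$flanking, "cluster_flanking.tsv")
  wtsv(report$stoichiometry$fractions, "stoich_fractions.tsv")
  wtsv(report$stoichiometry$aggregates, "stoich_aggregates.tsv")
  wtsv(report$stoichiometry$comparison, "stoich_comparison.tsv")
  cfg <- report$config
  log_lines <- c(
    sprintf("seed\t%d", cfg$sim$seed),
    sprintf("condition\t%s", cfg$condition),
    sprintf("de_profile\t%s", cfg$de_profile),
    sprintf("k4_threshold\t%g", cfg$k4_threshold),
    sprintf("smooth_window\t%d", cfg$smooth_window),
    sprintf("smooth_step\t%d", cfg$smooth_step),
    sprintf("k9_min_len\t%d", cfg$k9_min_len),
    sprintf("k9_merge_gap\t%d", cfg$k9_merge_gap),
    sprintf("k9_max_gap\t%d", cfg$k9_max_gap),
    if (!is.null(elapsed)) sprintf("elapsed_sec\t%.1f", as.numeric(elapsed, units = "secs")))
  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}

#' One-call demonstration run
#'
#' Simulates the default study conditions under the given seed, runs the
#' full pipeline, and (optionally) writes the report bundle.
#'
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param ... overrides passed to [sim_config()].
#' @return the `pipeline_report`.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, ...) {
  run_pipeline(pipeline_config(sim = sim_config(seed = seed, ...),
                               out_dir = out_dir))
}
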