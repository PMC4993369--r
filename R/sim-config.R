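#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults are
#' chosen as the package's fixed study conditions: a compact, gene-dense
#' haploid genome in which a small set of physically contiguous
#' secondary-metabolite (SM) gene clusters sits inside a much larger
#' background of "cell structure and function" (CSF) genes; active-mark
#' coverage shaped around start codons; negative-binomial expression counts
#' with planted 4-fold (log2 fold-change 2) strain effects; and Dirichlet
#' noise on histone peptide-form fractions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome, bp.
#' @param n_genes total number of genes across the genome.
#' @param gene_length_range min/max ORF length, bp.
#' @param n_sm_clusters number of SM clusters.
#' @param sm_cluster_size genes per SM cluster.
#' @param frac_k9_flanked_clusters fraction of SM clusters flanked on both
#'   sides by planted H3K9me3 blocks.
#' @param mark_shape_params list of kernel parameters: `k4_center`,
#'   `k4_sigma` (Gaussian peak for H3K4me3, bp from ATG), `hac_center`,
#'   `hac_sigma` (H3Ac promoter/first-nucleosome peak), `k9_block_len`
#'   (length of planted H3K9me3 rectangles, bp), `background` (uniform
#'   per-bp Poisson background), `amplitude` (kernel peak height for a
#'   mid-tier gene, per-bp expected coverage).
#' @param nb_mean_logsd log-normal spread of baseline expression means.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param planted_lfc magnitude of planted log2 fold-changes.
#' @param frac_de fraction of CSF genes planted differentially expressed in
#'   each direction under the nutrient-limited condition.
#' @param sm_frac_down,sm_frac_up fractions of SM-cluster genes planted
#'   down- resp. up-regulated in the mutant under the nutrient-limited
#'   condition (SM clusters depend heavily on the regulator).
#' @param depth expected total counts per RNA-seq sample.
#' @param read_length nominal read length, bp, used to convert simulated
#'   coverage into mapped-read totals.
#' @param seed master seed; together with the other fields it fully
#'   determines every simulated output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 600000L,
                       n_genes = 400L,
                       gene_length_range = c(900L, 2400L),
                       n_sm_clusters = 4L,
                       sm_cluster_size = 8L,
                       frac_k9_flanked_clusters = 0.5,
                       mark_shape_params = list(
                         k4_center = 250, k4_sigma = 150,
                         hac_center = 75, hac_sigma = 75,
                         k9_block_len = 5000, background = 1,
                         amplitude = 20),
                       nb_mean_logsd = 1,
                       nb_dispersion = 0.05,
                       planted_lfc = 2,
                       frac_de = 0.05,
                       sm_frac_down = 0.65,
                       sm_frac_up = 0.15,
                       depth = 2e6,
                       read_length = 50L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_sm_clusters = as.integer(n_sm_clusters),
    sm_cluster_size = as.integer(sm_cluster_size),
    frac_k9_flanked_clusters = frac_k9_flanked_clusters,
    mark_shape_params = mark_shape_params,
    nb_mean_logsd = nb_mean_logsd,
    nb_dispersion = nb_dispersion,
    planted_lfc = planted_lfc,
    frac_de = frac_de,
    sm_frac_down = sm_frac_down,
    sm_frac_up = sm_frac_up,
    depth = depth,
    read_length = as.integer(read_length),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!frac_ok(cfg$frac_k9_flanked_clusters))
    stop("frac_k9_flanked_clusters must lie in [0, 1]")
  if (!frac_ok(cfg$frac_de) || !frac_ok(cfg$sm_frac_down) || !frac_ok(cfg$sm_frac_up))
    stop("frac_de, sm_frac_down and sm_frac_up must lie in [0, 1]")
  if (cfg$sm_frac_down + cfg$sm_frac_up > 1)
    stop("sm_frac_down + sm_frac_up must not exceed 1")
  if (cfg$n_chromosomes < 1 || cfg$chrom_length < 1 || cfg$n_genes < 1)
    stop("n_chromosomes, chrom_length and n_genes must be positive")
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2] ||
      cfg$gene_length_range[1] < 1)
    stop("gene_length_range must be an increasing positive pair")
  if (cfg$n_sm_clusters * cfg$sm_cluster_size > cfg$n_genes)
    stop("configuration error: n_sm_clusters * sm_cluster_size (",
         cfg$n_sm_clusters * cfg$sm_cluster_size,
         ") exceeds n_genes (", cfg$n_genes, ")")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x", x$chrom_length, "bp;",
      x$n_genes, "genes;", x$n_sm_clusters, "SM clusters of",
      x$sm_cluster_size, "; seed", x$seed, "\n")
  invisible(x)
}
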