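#' Simulate a gene-by-sample RNA-seq count matrix with planted effects
#'
#' Counts are negative binomial: gene g in sample s has mean
#' `libsize_s / depth * baseline_g * 2^lfc(g, s)` with the configured
#' dispersion, where `baseline_g` is a log-normal draw around the gene's
#' expression-tier mean and `lfc(g, s)` is the planted log2 fold-change for
#' mutant samples of genes flagged differentially expressed in the sample's
#' condition (0 otherwise).  The planted calls live in `truth$genes`
#' (`de_PM`/`de_SM48` with signed `lfc_*`).
#'
#' @param annotation a `genome_annotation`.
#' @param truth matching ground truth from [gen_genome()].
#' @param design data.frame with columns `sample_id`, `strain`
#'   (`WT`/`mutant`) and `condition` (`PM`/`SM48`); at least two replicates
#'   per strain-condition group.
#' @param config the [sim_config()].
#' @return a [count_matrix()] whose `groups` are `strain.condition`.
#' @export
gen_counts <- function(annotation, truth, design, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("sample_id", "strain", "condition") %in% names(design)))
  grp <- interaction(design$strain, design$condition, drop = TRUE)
  if (any(table(grp) < 2))
    stop("each strain x condition group needs >= 2 replicates for DE testing")
  tg <- truth$genes[match(annotation$gene_id, truth$genes$gene_id), ]
  n <- nrow(annotation)

  with_seed(config$seed, "counts", {
    tier_mean <- c(50, 400, 2000)[tg$tier]
    baseline <- exp(stats::rnorm(n, log(tier_mean), config$nb_mean_logsd))
    libsize <- round(config$depth * stats::runif(nrow(design), 0.8, 1.2))
    counts <- matrix(0L, n, nrow(design),
                     dimnames = list(annotation$gene_id, design$sample_id))
    for (s in seq_len(nrow(design))) {
      lfc <- if (design$strain[s] == "WT") 0 else
        switch(design$condition[s], PM = tg$lfc_PM, SM48 = tg$lfc_SM48,
               stop("unknown condition '", design$condition[s], "'"))
      mu <- libsize[s] / config$depth * baseline * 2^lfc
      counts[, s] <- stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }
    count_matrix(counts, groups = as.character(grp),
                 lengths = stats::setNames(annotation$orf_length, annotation$gene_id))
  })
}

#' Simulate an observed peptide-form table around true stoichiometries
#'
#' For every site and strain the observed form fractions are one Dirichlet
#' draw centered on the true fractions with the given concentration
#' (precision) parameter: the expected value equals the truth, and the
#' spread shrinks as `noise_concentration` grows.
#'
#' @param true_fractions data.frame (site, form, strain, fraction); fractions
#'   must sum to 1 per site and strain within 1e-9.
#' @param noise_concentration Dirichlet concentration (> 0); larger is less
#'   noisy.
#' @param seed integer seed.
#' @return data.frame (site, form, strain, abundance) with unit sums.
#' @export
gen_peptide_table <- function(true_fractions, noise_concentration = 200, seed = 1L) {
  stopifnot(is.data.frame(true_fractions),
            all(c("site", "form", "strain", "fraction") %in% names(true_fractions)))
  if (noise_concentration <= 0) stop("noise_concentration must be positive")
  if (any(true_fractions$fraction < 0)) stop("true fractions must be nonnegative")
  sums <- tapply(true_fractions$fraction,
                 interaction(true_fractions$site, true_fractions$strain, drop = TRUE),
                 sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("true fractions must sum to 1 per site and strain (found ",
         paste(format(sums[abs(sums - 1) > 1e-9]), collapse = ", "), ")")
  out <- true_fractions
  names(out)[names(out) == "fraction"] <- "abundance"
  with_seed(seed, "peptides", {
    for (key in unique(paste(out$site, out$strain))) {
      idx <- paste(out$site, out$strain) == key
      a <- noise_concentration * true_fractions$fraction[idx]
      g <- stats::rgamma(length(a), shape = a)
      if (sum(g) == 0) g <- true_fractions$fraction[idx]  # degenerate guard
      out$abundance[idx] <- g / sum(g)
    }
  })
  out
}
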