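#' Generate a synthetic genome annotation with planted ground truth
#'
#' Places non-overlapping genes on both strands of a multi-chromosome
#' genome, groups a subset into physically contiguous secondary-metabolite
#' (SM) clusters, and assigns every gene a functional category (`SM` inside
#' clusters, `CSF` — cell structure and function — outside), an expression
#' tier, true per-mark signal levels, and planted differential-expression
#' calls for the active-growth (`PM`) and nutrient-limited (`SM48`)
#' conditions.  Chromosome ends are kept gene-free so that planted
#' subtelomeric H3K9me3 blocks never overlap genes, and extra clearance is
#' left around SM clusters for their flanking heterochromatin blocks.
#'
#' @param config a [sim_config()].
#' @return a list with elements `annotation` (a `genome_annotation`
#'   data.frame: gene_id, chrom, start, end in 0-based half-open
#'   coordinates, strand, orf_length, category, cluster_id) and `truth`
#'   (per-gene tiers, mark levels and DE calls; per-cluster flanking flags
#'   with true domain coordinates; true peptide-form fractions).
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  msp <- cfg$mark_shape_params
  block <- as.integer(msp$k9_block_len %||% 5000)
  reserve <- block + 1000L       # gene-free zone at each chromosome end
  margin <- 700L                 # minimum inter-gene gap (room for windows)

  with_seed(cfg$seed, "genome", {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    # distribute genes and clusters across chromosomes
    n_per <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
    extra <- cfg$n_genes %% cfg$n_chromosomes
    if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
    clusters_per <- rep(0L, cfg$n_chromosomes)
    if (cfg$n_sm_clusters > 0)
      for (i in seq_len(cfg$n_sm_clusters))
        clusters_per[(i - 1L) %% cfg$n_chromosomes + 1L] <-
          clusters_per[(i - 1L) %% cfg$n_chromosomes + 1L] + 1L

    ann <- list(); clus <- list(); cluster_no <- 0L; gene_no <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      n_c <- n_per[ci]
      if (n_c == 0L) next
      lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                     n_c, replace = TRUE)
      # choose non-overlapping cluster runs of consecutive gene indices
      k <- clusters_per[ci]
      cluster_of <- rep(NA_integer_, n_c)
      if (k > 0) {
        if (k * cfg$sm_cluster_size > n_c)
          stop("configuration error: chromosome ", chroms[ci], " holds ", n_c,
               " genes but needs ", k * cfg$sm_cluster_size, " for its SM clusters")
        # pick k starts with spacing >= sm_cluster_size
        slots <- n_c - k * cfg$sm_cluster_size
        gaps <- as.vector(stats::rmultinom(1, slots, rep(1, k + 1)))
        pos <- 0L
        for (j in seq_len(k)) {
          pos <- pos + gaps[j]
          cluster_no <- cluster_no + 1L
          cluster_of[(pos + 1L):(pos + cfg$sm_cluster_size)] <- cluster_no
          pos <- pos + cfg$sm_cluster_size
        }
      }
      # gap budget: margin everywhere, plus cluster clearance
      gapmin <- rep(margin, n_c + 1L)
      if (k > 0) {
        firsts <- which(!is.na(cluster_of) &
                          c(TRUE, is.na(cluster_of[-n_c]) | cluster_of[-n_c] != cluster_of[-1]))
        lasts <- which(!is.na(cluster_of) &
                         c(is.na(cluster_of[-1]) | cluster_of[-n_c] != cluster_of[-1], TRUE))
        gapmin[firsts] <- gapmin[firsts] + block + 500L
        gapmin[lasts + 1L] <- gapmin[lasts + 1L] + block + 500L
      }
      need <- sum(lens) + sum(gapmin) + 2L * reserve
      if (need > cfg$chrom_length)
        stop("configuration error: chromosome length ", cfg$chrom_length,
             " bp cannot hold ", n_c, " genes (required ", need, " bp: ",
             sum(lens), " gene bp + ", sum(gapmin), " gap bp + ",
             2L * reserve, " bp terminal reserve)")
      slack <- cfg$chrom_length - need
      gaps <- gapmin + as.vector(stats::rmultinom(1, slack, rep(1, n_c + 1L)))
      starts <- reserve + cumsum(gaps[seq_len(n_c)]) + c(0L, cumsum(lens))[seq_len(n_c)]
      ends <- starts + lens
      strand <- sample(c("+", "-"), n_c, replace = TRUE)
      ann[[ci]] <- data.frame(
        chrom = chroms[ci], start = as.integer(starts), end = as.integer(ends),
        strand = strand, orf_length = as.integer(lens),
        cluster_idx = cluster_of, stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, ann)
    ann$gene_id <- sprintf("gene_%04d", seq_len(nrow(ann)))
    ann$category <- ifelse(is.na(ann$cluster_idx), "CSF", "SM")
    ann$cluster_id <- ifelse(is.na(ann$cluster_idx), NA_character_,
                             sprintf("SMC%02d", ann$cluster_idx))
    ann$cluster_idx <- NULL
    ann <- ann[, c("gene_id", "chrom", "start", "end", "strand",
                   "orf_length", "category", "cluster_id")]
    class(ann) <- c("genome_annotation", "data.frame")

    # per-gene truth: tiers, mark levels, planted DE
    n <- nrow(ann)
    tier <- ifelse(ann$category == "SM", 1L,
                   sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25)))
    tier_mult <- c(0.15, 1, 4)
    de_draw <- function(p_down, p_up) {
      u <- stats::runif(n)
      ifelse(u < p_down, "down", ifelse(u < p_down + p_up, "up", "ns"))
    }
    is_sm <- ann$category == "SM"
    de_sm48 <- ifelse(is_sm,
                      de_draw(cfg$sm_frac_down, cfg$sm_frac_up),
                      de_draw(cfg$frac_de, cfg$frac_de))
    de_pm <- ifelse(is_sm, de_draw(0.07, 0), de_draw(cfg$frac_de / 2, cfg$frac_de / 2))
    genes_truth <- data.frame(
      gene_id = ann$gene_id, category = ann$category,
      cluster_id = ann$cluster_id, tier = tier,
      k4_level = tier_mult[tier], hac_level = tier_mult[tier],
      k36_level = tier_mult[tier], k9_level = 0,
      de_PM = de_pm, lfc_PM = ifelse(de_pm == "ns", 0,
                                     ifelse(de_pm == "up", cfg$planted_lfc, -cfg$planted_lfc)),
      de_SM48 = de_sm48, lfc_SM48 = ifelse(de_sm48 == "ns", 0,
                                           ifelse(de_sm48 == "up", cfg$planted_lfc, -cfg$planted_lfc)),
      stringsAsFactors = FALSE)

    # per-cluster truth: outer coordinates and K9 flanking domains
    clusters_truth <- NULL
    if (cluster_no > 0L) {
      ids <- sprintf("SMC%02d", seq_len(cluster_no))
      flanked <- rep(FALSE, cluster_no)
      n_fl <- round(cfg$frac_k9_flanked_clusters * cluster_no)
      if (n_fl > 0) flanked[sample(cluster_no, n_fl)] <- TRUE
      rows <- lapply(seq_len(cluster_no), function(i) {
        g <- ann[!is.na(ann$cluster_id) & ann$cluster_id == ids[i], ]
        data.frame(cluster_id = ids[i], chrom = g$chrom[1],
                   start = min(g$start), end = max(g$end),
                   flanked_by_k9 = flanked[i],
                   left_domain_start = if (flanked[i]) min(g$start) - block else NA_integer_,
                   left_domain_end = if (flanked[i]) min(g$start) else NA_integer_,
                   right_domain_start = if (flanked[i]) max(g$end) else NA_integer_,
                   right_domain_end = if (flanked[i]) max(g$end) + block else NA_integer_,
                   stringsAsFactors = FALSE)
      })
      clusters_truth <- do.call(rbind, rows)
    }

    truth <- list(genes = genes_truth, clusters = clusters_truth,
                  peptides = default_peptide_truth(),
                  k9_block_len = block)
    list(annotation = ann, truth = truth)
  })
}

#' True peptide-form fractions used by the simulator
#'
#' Two histone H3 peptide sites are modeled: the K4 peptide with methylation
#' forms me0--me3, and the K9/K14 peptide with joint acetyl/methyl forms.
#' Wild-type fractions follow typical LC-MS/MS stoichiometries for an
#' H3K4me3-demethylase deletion background: the mutant gains H3K4me3 at the
#' expense of the lower methylation states, gains K9/K14 acetylation at the
#' expense of unmodified peptide, and loses most of its H3K9me3.
#'
#' @return data.frame (site, form, strain, fraction); fractions sum to 1 per
#'   site and strain.
#' @export
default_peptide_truth <- function() {
  k4_wt <- c(me0 = 0.287, me1 = 0.103, me2 = 0.135, me3 = 0.475)
  k4_mut <- c(me0 = 0.235, me1 = 0.084, me2 = 0.111, me3 = 0.570)
  k4_mut["me0"] <- k4_mut["me0"] + (1 - sum(k4_mut))  # exact unit sum
  k9_wt <- c(unmod = 0.2200, ac1 = 0.4000, ac2 = 0.2447, me2K9 = 0.1200,
             me3K9 = 0.0153)
  k9_mut <- c(unmod = 0.0600, ac1 = 0.4600, ac2 = 0.3120, me2K9 = 0.1660,
              me3K9 = 0.0020)
  rbind(
    data.frame(site = "H3K4", form = names(k4_wt), strain = "WT",
               fraction = unname(k4_wt)),
    data.frame(site = "H3K4", form = names(k4_mut), strain = "mutant",
               fraction = unname(k4_mut)),
    data.frame(site = "H3K9K14", form = names(k9_wt), strain = "WT",
               fraction = unname(k9_wt)),
    data.frame(site = "H3K9K14", form = names(k9_mut), strain = "mutant",
               fraction = unname(k9_mut)))
}

# Anchor coordinate of a gene: the first transcribed base of the ORF for
# anchor "ATG", the last for anchor "STOP", in 0-based coordinates.
anchor_coord <- function(annotation, anchor = c("ATG", "STOP")) {
  anchor <- match.arg(anchor)
  plus <- annotation$strand == "+"
  if (anchor == "ATG") ifelse(plus, annotation$start, annotation$end - 1L)
  else ifelse(plus, annotation$end - 1L, annotation$start)
}
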