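#' Marks supported by the coverage simulator
#' @export
SUPPORTED_MARKS <- c("H3K4me3", "H3Ac", "H3K36me3", "H3K9me3")

# Expected per-bp coverage (the Poisson mean surface) for one mark/strain.
coverage_mean_surface <- function(annotation, truth, mark, strain, config) {
  msp <- config$mark_shape_params
  bg <- msp$background %||% 1
  amp <- msp$amplitude %||% 20
  lens <- vapply(sprintf("chr%d", seq_len(config$n_chromosomes)),
                 function(ch) config$chrom_length, integer(1))
  mu <- lapply(lens, function(L) rep(as.numeric(bg), L))

  tg <- truth$genes[match(annotation$gene_id, truth$genes$gene_id), ]
  level <- switch(mark,
                  H3K4me3 = tg$k4_level, H3Ac = tg$hac_level,
                  H3K36me3 = tg$k36_level, H3K9me3 = rep(0, nrow(annotation)))
  # strain effect on active marks: genes losing expression in the mutant
  # also lose H3K4me3/H3Ac there, genes gaining expression gain the marks
  strain_mult <- rep(1, nrow(annotation))
  if (strain != "WT" && mark %in% c("H3K4me3", "H3Ac"))
    strain_mult <- ifelse(tg$de_SM48 == "down", 0.4,
                          ifelse(tg$de_SM48 == "up", 1.6, 1))

  if (mark != "H3K9me3") {
    for (i in seq_len(nrow(annotation))) {
      A <- amp * level[i] * strain_mult[i]
      if (A <= 0) next
      g <- annotation[i, ]
      L <- length(mu[[g$chrom]])
      if (mark %in% c("H3K4me3", "H3Ac")) {
        center <- if (mark == "H3K4me3") msp$k4_center %||% 250 else msp$hac_center %||% 75
        sigma <- if (mark == "H3K4me3") msp$k4_sigma %||% 150 else msp$hac_sigma %||% 75
        d <- seq.int(-300L, min(1500L, g$orf_length))  # offsets from ATG, gene frame
        kern <- A * exp(-((d - center)^2) / (2 * sigma^2))
      } else {                                          # H3K36me3: 5'->3' ramp
        d <- seq.int(0L, g$orf_length - 1L)
        kern <- A * d / g$orf_length
      }
      if (g$strand == "+") pos <- g$start + d else pos <- (g$end - 1L) - d
      keep <- pos >= 0L & pos < L
      idx <- pos[keep] + 1L
      mu[[g$chrom]][idx] <- mu[[g$chrom]][idx] + kern[keep]
    }
  } else {
    block <- as.integer(msp$k9_block_len %||% 5000)
    A <- amp * 0.5   # heterochromatin blocks: flat rectangles
    for (ch in names(mu)) {
      L <- length(mu[[ch]])
      b <- min(block, L)
      mu[[ch]][seq_len(b)] <- mu[[ch]][seq_len(b)] + A
      mu[[ch]][(L - b + 1L):L] <- mu[[ch]][(L - b + 1L):L] + A
    }
    if (!is.null(truth$clusters)) {
      fl <- truth$clusters[truth$clusters$flanked_by_k9, , drop = FALSE]
      for (i in seq_len(nrow(fl))) {
        ch <- fl$chrom[i]; L <- length(mu[[ch]])
        for (side in c("left", "right")) {
          s <- fl[[paste0(side, "_domain_start")]][i]
          e <- fl[[paste0(side, "_domain_end")]][i]
          s <- max(s, 0L); e <- min(e, L)
          if (e > s) mu[[ch]][(s + 1L):e] <- mu[[ch]][(s + 1L):e] + A
        }
      }
    }
  }
  mu
}

#' Simulate a ChIP-seq coverage track for one mark and strain
#'
#' Per-bp coverage is drawn as Poisson counts around a deterministic mean
#' surface: a uniform background plus per-gene kernels in gene orientation —
#' a Gaussian peak ~250 bp downstream of the ATG for H3K4me3 (the
#' first-nucleosomes peak), a narrow promoter-proximal Gaussian at ~75 bp
#' for H3Ac, a linear 5'→3' ramp over the ORF for H3K36me3 — and, for
#' H3K9me3, rectangular heterochromatin blocks at both chromosome ends and
#' abutting the boundaries of the SM clusters flagged as flanked in the
#' ground truth.  The mutant strain loses active-mark signal over genes that
#' are planted down-regulated and gains it over up-regulated ones.  The
#' total mapped reads recorded on the track is the coverage integral
#' divided by the nominal read length.
#'
#' @param annotation a `genome_annotation` from [gen_genome()].
#' @param truth the matching ground-truth list.
#' @param mark one of `r paste(SUPPORTED_MARKS, collapse=", ")`.
#' @param strain `"WT"` or `"mutant"`.
#' @param config the [sim_config()].
#' @return a raw (non-normalized) [coverage_track()].
#' @export
gen_coverage <- function(annotation, truth, mark, strain = "WT", config) {
  stopifnot(inherits(config, "sim_config"))
  if (!mark %in% SUPPORTED_MARKS)
    stop("unknown mark '", mark, "'; supported marks: ",
         paste(SUPPORTED_MARKS, collapse = ", "))
  mu <- coverage_mean_surface(annotation, truth, mark, strain, config)
  with_seed(config$seed, paste("coverage", mark, strain), {
    signal <- lapply(mu, function(m) as.numeric(stats::rpois(length(m), m)))
  })
  total <- max(1, round(sum(vapply(signal, sum, numeric(1))) / config$read_length))
  coverage_track(signal, total_mapped_reads = total, normalized = FALSE)
}
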