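#' Anchored gene-window specification
#'
#' Defines the window used for metagene profiling and per-gene mark
#' quantification, in gene orientation: `upstream` bp 5' of the anchor and
#' `downstream` bp 3' of it.  The conventional windows are 500 bp upstream +
#' 1500 bp downstream of the ATG for promoter/5' marks (H3Ac, H3K4me3) and
#' 1500 bp upstream + 500 bp downstream of the stop codon for the 3'-biased
#' H3K36me3.
#'
#' @param anchor `"ATG"` (start codon) or `"STOP"` (stop codon).
#' @param upstream bp 5' of the anchor (>= 0).
#' @param downstream bp 3' of the anchor (>= 0).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(anchor = c("ATG", "STOP"), upstream = 500L,
                        downstream = 1500L) {
  anchor <- match.arg(anchor)
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 0 || downstream < 0 || upstream + downstream <= 0)
    stop("need upstream >= 0, downstream >= 0, upstream + downstream > 0")
  structure(list(anchor = anchor, upstream = upstream, downstream = downstream),
            class = "window_spec")
}

#' Build a strand-aware anchored gene-window matrix
#'
#' Every gene contributes one row: its signal in a fixed window around the
#' anchor, rebinned at `step` bp in gene orientation, so position 0 is
#' always the gene's own anchor base and positive positions run 3' of it
#' regardless of strand (minus-strand windows are reflected).  A window bin
#' covers gene-frame offsets `[off, off + step)`; bins that extend past
#' either chromosome end are masked and excluded from downstream averages.
#'
#' @param x a [coverage_track()] (per-bp values, typically CPM-normalized)
#'   or a `binned_track` from [smooth_and_bin()].
#' @param annotation a `genome_annotation`.
#' @param spec a [window_spec()].
#' @param step bin width in gene-frame bp; must divide both window arms.
#' @return object of class `gene_window_matrix`: `gene_ids`, `positions`
#'   (gene-frame bin start offsets), `values` (genes x positions), `mask`
#'   (TRUE where the bin lies on-chromosome).
#' @export
gene_windows <- function(x, annotation, spec = window_spec(), step = 10L) {
  stopifnot(inherits(spec, "window_spec"))
  step <- as.integer(step)
  if (spec$upstream %% step != 0 || spec$downstream %% step != 0)
    stop("step must divide both the upstream and downstream window arms")
  glen <- if (inherits(x, "coverage_track") || inherits(x, "binned_track"))
    x$genome_lengths else stop("x must be a coverage_track or binned_track")
  unknown <- setdiff(unique(annotation$chrom), names(glen))
  if (length(unknown)) {
    g1 <- annotation$gene_id[annotation$chrom == unknown[1]][1]
    stop("gene ", g1, " lies on unknown chromosome '", unknown[1], "'")
  }
  offs <- seq.int(-spec$upstream, spec$downstream - step, by = step)
  npos <- length(offs)
  anchors <- anchor_coord(annotation, spec$anchor)
  n <- nrow(annotation)
  values <- matrix(NA_real_, n, npos,
                   dimnames = list(annotation$gene_id, offs))
  mask <- matrix(FALSE, n, npos, dimnames = dimnames(values))

  # per-chromosome cumulative sums, computed once
  cs_cache <- new.env(parent = emptyenv())
  get_cs <- function(ch) {
    if (is.null(cs_cache[[ch]]))
      cs_cache[[ch]] <- c(0, cumsum(per_bp_signal(x, ch)))
    cs_cache[[ch]]
  }
  for (i in seq_len(n)) {
    ch <- annotation$chrom[i]
    cs <- get_cs(ch)
    L <- length(cs) - 1L
    a <- anchors[i]
    starts <- if (annotation$strand[i] == "+") a + offs
    # gene-frame bin [off, off+step) covers genomic [a-off-step+1, a-off+1)
    else a - offs - step + 1L
    ok <- starts >= 0L & starts + step <= L
    if (any(ok)) {
      s <- starts[ok]
      values[i, ok] <- (cs[s + step + 1L] - cs[s + 1L]) / step
    }
    mask[i, ] <- ok
  }
  structure(list(gene_ids = annotation$gene_id, positions = offs,
                 values = values, mask = mask, step = step, spec = spec),
            class = "gene_window_matrix")
}

#' Average a gene-window matrix into a metagene profile
#'
#' Position-wise arithmetic mean over the unmasked entries of the selected
#' genes, with the number of contributing genes reported per position.
#'
#' @param matrix a `gene_window_matrix`.
#' @param gene_set character vector of gene ids (default: all genes).
#' @return data.frame (position, mean, n) of class `metagene_profile`.
#' @export
metagene_profile <- function(matrix, gene_set = NULL) {
  stopifnot(inherits(matrix, "gene_window_matrix"))
  if (is.null(gene_set)) gene_set <- matrix$gene_ids
  if (length(gene_set) == 0) stop("empty gene set")
  missing <- setdiff(gene_set, matrix$gene_ids)
  if (length(missing)) stop("gene(s) not in matrix: ", missing[1])
  rows <- matrix$gene_ids %in% gene_set
  v <- matrix$values[rows, , drop = FALSE]
  m <- matrix$mask[rows, , drop = FALSE]
  n <- colSums(m)
  mean <- ifelse(n > 0, colSums(ifelse(m, v, 0)) / n, NA_real_)
  structure(data.frame(position = matrix$positions, mean = mean, n = n),
            class = c("metagene_profile", "data.frame"))
}

#' Quantify a histone mark per gene
#'
#' Two quantities per gene: the mean CPM over the anchored window (the
#' "average CPM from -500 to +1500" convention) and an RPKM-style estimate —
#' reads overlapping the ORF x 1e9 / (total mapped reads x ORF length bp) —
#' where the read count is reconstructed from raw coverage as coverage
#' integral / read length.  log2 values use a pseudocount of 0.01 x the
#' genome-wide nonzero median of the respective quantity.  Genes with more
#' than `max_masked_frac` of their window masked are flagged so that
#' threshold classification can exclude them explicitly rather than treat
#' truncated windows as low signal.
#'
#' @param track a [coverage_track()]; if CPM-normalized, raw coverage is
#'   recovered via the recorded total mapped reads.
#' @param annotation a `genome_annotation`.
#' @param spec a [window_spec()] for the window-mean quantity.
#' @param step window bin size, bp.
#' @param read_length nominal read length used to convert coverage to reads.
#' @param max_masked_frac window-masking fraction above which a gene is
#'   flagged `masked`.
#' @return data.frame of class `mark_quant`: gene_id, window_mean_cpm,
#'   log2_window_cpm, orf_reads, orf_rpkm, log2_orf_rpkm, masked_frac,
#'   masked.  Pseudocounts are stored as attributes `pc_window`/`pc_rpkm`.
#' @export
quantify_gene_mark <- function(track, annotation, spec = window_spec(),
                               step = 10L, read_length = 50L,
                               max_masked_frac = 0.5) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.finite(track$total_mapped_reads) || track$total_mapped_reads <= 0)
    stop("track must carry a positive total_mapped_reads")
  cpm_track <- if (track$normalized) track else cpm_normalize(track)
  gwm <- gene_windows(cpm_track, annotation, spec, step = step)
  masked_frac <- 1 - rowMeans(gwm$mask)
  wmean <- vapply(seq_len(nrow(annotation)), function(i) {
    m <- gwm$mask[i, ]
    if (!any(m)) NA_real_ else mean(gwm$values[i, m])
  }, numeric(1))

  # ORF read counts from raw coverage (fractional reads allowed)
  scale_back <- if (track$normalized) track$total_mapped_reads / 1e6 else 1
  orf_reads <- vapply(seq_len(nrow(annotation)), function(i) {
    sig <- track$signal[[annotation$chrom[i]]]
    s <- max(annotation$start[i], 0L); e <- min(annotation$end[i], length(sig))
    if (e <= s) return(NA_real_)
    sum(sig[(s + 1L):e]) * scale_back / read_length
  }, numeric(1))
  orf_rpkm <- orf_reads * 1e9 /
    (track$total_mapped_reads * annotation$orf_length)

  lw <- log2_pseudo(wmean)
  lr <- log2_pseudo(orf_rpkm)
  out <- data.frame(
    gene_id = annotation$gene_id,
    window_mean_cpm = wmean, log2_window_cpm = lw$value,
    orf_reads = orf_reads, orf_rpkm = orf_rpkm, log2_orf_rpkm = lr$value,
    masked_frac = masked_frac, masked = masked_frac > max_masked_frac,
    stringsAsFactors = FALSE)
  attr(out, "pc_window") <- lw$pseudocount
  attr(out, "pc_rpkm") <- lr$pseudocount
  class(out) <- c("mark_quant", "data.frame")
  out
}
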