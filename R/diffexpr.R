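#' Construct a gene-by-sample count matrix
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param groups character vector of group labels, one per sample.
#' @param lengths named vector of per-gene exon/ORF lengths, bp (optional;
#'   required for RPKM).
#' @param library_sizes per-sample library sizes; defaults to column sums.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, lengths = NULL, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample dimnames")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0))
      stop("every gene needs a positive length")
  }
  structure(list(counts = counts, groups = as.character(groups),
                 lengths = lengths,
                 library_sizes = stats::setNames(as.numeric(library_sizes),
                                                 colnames(counts))),
            class = "count_matrix")
}

#' Read a counts TSV (genes x samples, first column gene ids)
#' @param path counts file.
#' @param design data.frame with `sample_id` and group columns; groups are
#'   taken as `strain.condition` if both present, else the `group` column.
#' @param lengths optional named gene-length vector.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, design, lengths = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  counts <- counts[, design$sample_id, drop = FALSE]
  groups <- if (all(c("strain", "condition") %in% names(design)))
    paste(design$strain, design$condition, sep = ".") else design$group
  count_matrix(counts, groups = groups, lengths = lengths)
}

#' Expression as (log2) RPKM
#'
#' RPKM = count x 1e9 / (library size x length bp): reads per kilobase of
#' exon/ORF per million library reads.  With `log = TRUE`, 0.5 is added to
#' the counts before scaling so zeros stay finite.
#'
#' @param cm a [count_matrix()] with gene lengths.
#' @param log return log2 values?
#' @return numeric matrix, genes x samples.
#' @export
rpkm <- function(cm, log = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$lengths)) stop("count matrix has no gene lengths")
  y <- if (log) cm$counts + 0.5 else cm$counts
  r <- sweep(y * 1e9, 2, cm$library_sizes, "/") / cm$lengths
  if (log) log2(r) else r
}

# 75th percentile of the library-scaled counts, used to pick the TMM
# reference sample.
upper_quartile <- function(cm) {
  apply(sweep(cm$counts, 2, cm$library_sizes, "/"), 2,
        stats::quantile, probs = 0.75)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For each sample a scaling factor is computed against a reference sample
#' (the one whose upper-quartile of library-scaled counts is closest to the
#' mean): per-gene log-ratios M and average log-abundances A are formed over
#' genes expressed in both samples, the extreme `trim_m` fraction of M and
#' `trim_a` fraction of A are trimmed on each side, and the factor is 2 to
#' the inverse-variance-weighted mean of the surviving M values.  Factors
#' are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()] with >= 2 samples.
#' @param trim_m two-sided trim fraction on M (log-ratio).
#' @param trim_a two-sided trim fraction on A (abundance).
#' @param ref reference sample id (default: upper-quartile rule).
#' @return list of class `tmm_factors`: `factors` (named, geometric mean 1)
#'   and `ref`.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2) stop("TMM needs at least two samples")
  samples <- colnames(cm$counts)
  if (is.null(ref)) {
    uq <- upper_quartile(cm)
    ref <- samples[which.min(abs(uq - mean(uq)))]
  }
  r <- cm$counts[, ref]; Nr <- cm$library_sizes[ref]
  f <- vapply(samples, function(s) {
    y <- cm$counts[, s]; N <- cm$library_sizes[s]
    keep <- y > 0 & r > 0
    if (!any(keep)) stop("no genes expressed in both '", s, "' and reference")
    yk <- y[keep]; rk <- r[keep]
    M <- log2((yk / N) / (rk / Nr))
    A <- 0.5 * log2((yk / N) * (rk / Nr))
    v <- (N - yk) / (N * yk) + (Nr - rk) / (Nr * rk)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(use)) return(1)
    2^(sum(M[use] / v[use]) / sum(1 / v[use]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, ref = ref), class = "tmm_factors")
}

# log2 counts per million on TMM-effective library sizes, pseudocount on
# the counts.
log2_cpm <- function(cm, tmm = NULL, prior_count = 0.5) {
  eff <- cm$library_sizes * if (is.null(tmm)) 1 else tmm$factors[colnames(cm$counts)]
  log2(sweep((cm$counts + prior_count) * 1e6, 2, eff + 2 * prior_count, "/"))
}

#' Two-group moderated-t differential expression test
#'
#' A self-contained count-based test on TMM-adjusted log2-CPM: per-gene
#' log2 fold-change is the difference of group means; the pooled per-gene
#' variance is shrunk toward an abundance-dependent trend by empirical
#' Bayes (the trend is a lowess fit of the log residual variances against
#' mean log2-CPM; the prior degrees of freedom come from a moments fit of
#' the log-variance spread, so the squeezed variance is an F-weighted
#' compromise between the gene's own variance and the trend); p-values are
#' two-sided t on the augmented degrees of freedom and are BH-adjusted.
#' Genes with zero counts throughout both groups are reported `ns` with
#' log2FC 0 and p 1.
#'
#' @param cm a [count_matrix()].
#' @param contrast character pair `c(test_group, reference_group)`; the
#'   reported log2FC is test minus reference (e.g. mutant vs WT).
#' @param trim_m,trim_a TMM trims.
#' @param prior_count pseudocount on counts before log2-CPM.
#' @param lowess_f lowess span of the variance trend.
#' @return data.frame of class `de_result`: gene_id, log2FC, AveExpr, t, p,
#'   fdr, mean log2-CPM per group, call (filled by [classify_de()], default
#'   thresholds).
#' @export
de_test <- function(cm, contrast, trim_m = 0.30, trim_a = 0.05,
                    prior_count = 0.5, lowess_f = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  sel <- cm$groups %in% contrast
  if (!all(contrast %in% cm$groups)) stop("contrast groups not found")
  sub <- count_matrix(cm$counts[, sel, drop = FALSE], cm$groups[sel],
                      lengths = cm$lengths,
                      library_sizes = cm$library_sizes[sel])
  n1 <- sum(sub$groups == contrast[1]); n2 <- sum(sub$groups == contrast[2])
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per group")
  tmm <- tmm_factors(sub, trim_m = trim_m, trim_a = trim_a)
  lc <- log2_cpm(sub, tmm, prior_count = prior_count)
  i1 <- sub$groups == contrast[1]; i2 <- sub$groups == contrast[2]
  m1 <- rowMeans(lc[, i1, drop = FALSE]); m2 <- rowMeans(lc[, i2, drop = FALSE])
  lfc <- m1 - m2
  df <- n1 + n2 - 2
  s2 <- (rowSums((lc[, i1, drop = FALSE] - m1)^2) +
           rowSums((lc[, i2, drop = FALSE] - m2)^2)) / df
  amean <- rowMeans(lc)
  allzero <- rowSums(sub$counts) == 0

  # empirical-Bayes squeeze toward a mean-variance trend
  ok <- !allzero & s2 > 1e-10
  if (sum(ok) >= 10) {
    z <- log(pmax(s2, 1e-10))
    ez <- z - digamma(df / 2) + log(df / 2)   # unbiased log-variance
    lo <- stats::lowess(amean[ok], ez[ok], f = lowess_f)
    trend <- stats::approx(lo$x, lo$y, xout = amean, rule = 2)$y
    resid_var <- stats::var(ez[ok] - trend[ok])
    excess <- resid_var - trigamma(df / 2)
    if (is.finite(excess) && excess > 1e-8) {
      d0 <- 2 * trigamma_inverse(excess)
      s20 <- exp(trend + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s20 <- exp(trend)
    }
  } else {
    # too few informative genes for a trend (e.g. degenerate copies):
    # fall back to the raw variances with a small floor
    d0 <- Inf
    s20 <- pmax(s2, 1e-8)
  }
  s2post <- pmax(if (is.finite(d0)) (d0 * s20 + df * s2) / (d0 + df) else s20,
                 1e-10)
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  tt <- lfc / se
  dft <- df + if (is.finite(d0)) d0 else 1e6
  p <- 2 * stats::pt(-abs(tt), df = dft)
  lfc[allzero] <- 0; tt[allzero] <- 0; p[allzero] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = rownames(sub$counts), log2FC = lfc, AveExpr = amean, t = tt,
    p = p, fdr = fdr, mean_g1 = m1, mean_g2 = m2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "prior_df") <- d0
  out$call <- classify_de(out)$call
  class(out) <- c("de_result", "data.frame")
  out
}

#' Named differential-expression threshold profiles
#'
#' All profiles require at least a 4-fold change (|log2FC| >= 2) and differ
#' in the adjusted-p cut-off: `fdr01` (FDR < 0.01, the default reporting
#' threshold), `fdr005` (FDR < 0.005, used for the mark-by-expression group
#' split), `fdr05` (FDR < 0.05, used for category deregulation counts).
#'
#' @return named list of lists with `lfc_cut` and `fdr_cut`.
#' @export
de_profiles <- function() {
  list(fdr01 = list(lfc_cut = 2, fdr_cut = 0.01),
       fdr005 = list(lfc_cut = 2, fdr_cut = 0.005),
       fdr05 = list(lfc_cut = 2, fdr_cut = 0.05))
}

#' Classify genes from a differential-expression result
#'
#' `up_in_mutant` iff log2FC >= `lfc_cut` and FDR < `fdr_cut`;
#' `up_in_WT` iff log2FC <= -`lfc_cut` and FDR < `fdr_cut`; otherwise `ns`.
#' (The test group of the contrast is conventionally the mutant.)
#'
#' @param result a `de_result` (or data.frame with log2FC and fdr).
#' @param lfc_cut minimum |log2FC| (default 2, i.e. 4-fold).
#' @param fdr_cut FDR threshold (strict inequality).
#' @param profile optional name from [de_profiles()], overriding the cuts.
#' @return `result` with an updated `call` column.
#' @export
classify_de <- function(result, lfc_cut = 2, fdr_cut = 0.01, profile = NULL) {
  if (!is.null(profile)) {
    pr <- de_profiles()[[profile]]
    if (is.null(pr)) stop("unknown profile '", profile, "'")
    lfc_cut <- pr$lfc_cut; fdr_cut <- pr$fdr_cut
  }
  call <- ifelse(result$log2FC >= lfc_cut & result$fdr < fdr_cut, "up_in_mutant",
                 ifelse(result$log2FC <= -lfc_cut & result$fdr < fdr_cut,
                        "up_in_WT", "ns"))
  result$call <- call
  result
}
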