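#' Split genes into low/high tiers by mark level
#'
#' Applies the conventional threshold on the log2 mark level: genes at or
#' below the threshold are `low`, strictly above are `high` (the boundary
#' value goes to `low`).  Genes flagged `masked` in the quantification are
#' excluded and returned in a skipped-gene list instead of being classified
#' as low.  The canonical thresholds are log2 level 5 for H3K4me3 and 2 for
#' H3K36me3.
#'
#' @param quant a `mark_quant` from [quantify_gene_mark()], or a data.frame
#'   with `gene_id` and the chosen value column.
#' @param threshold log2 threshold (boundary inclusive into `low`).
#' @param value_col which log2 column to threshold.
#' @return list with `tiers` (named character vector `low`/`high`) and
#'   `skipped` (gene ids excluded as masked).
#' @export
split_by_mark <- function(quant, threshold = 5,
                          value_col = c("log2_window_cpm", "log2_orf_rpkm")) {
  value_col <- match.arg(value_col)
  skipped <- if ("masked" %in% names(quant))
    quant$gene_id[quant$masked] else character(0)
  keep <- !(quant$gene_id %in% skipped) & is.finite(quant[[value_col]])
  lev <- quant[[value_col]][keep]
  tiers <- stats::setNames(ifelse(lev <= threshold, "low", "high"),
                           quant$gene_id[keep])
  list(tiers = tiers, skipped = skipped,
       threshold = threshold, value_col = value_col)
}

#' Assign mark-by-expression groups
#'
#' Crosses a low/high mark tier with the differential-expression call into
#' the four canonical groups: G1 = low mark, up in WT (the regulator is
#' required for expression); G2 = low mark, up in mutant; G3 = high mark,
#' up in WT; G4 = high mark, up in mutant.  With `offset = 4` the same
#' cross is labelled G5--G8 (the nutrient-limited condition's convention).
#' Genes with call `ns`, without a tier, or absent from either input get no
#' group.
#'
#' @param tiers named `low`/`high` vector (from [split_by_mark()]`$tiers`).
#' @param de_calls named vector of calls
#'   (`up_in_WT`/`up_in_mutant`/`ns`).
#' @param offset 0 for G1--G4, 4 for G5--G8.
#' @return data.frame (gene_id, tier, call, group) of class
#'   `gene_group_assignment`; `group` is NA where undefined.  Group counts
#'   are attached as attribute `counts`.
#' @export
assign_groups <- function(tiers, de_calls, offset = 0L) {
  genes <- union(names(tiers), names(de_calls))
  tier <- tiers[genes]; call <- de_calls[genes]
  idx <- ifelse(is.na(tier) | is.na(call) | call == "ns", NA_integer_,
                ifelse(tier == "low",
                       ifelse(call == "up_in_WT", 1L, 2L),
                       ifelse(call == "up_in_WT", 3L, 4L)))
  group <- unname(ifelse(is.na(idx), NA_character_, sprintf("G%d", idx + offset)))
  out <- data.frame(gene_id = genes, tier = unname(tier), call = unname(call),
                    group = group, stringsAsFactors = FALSE, row.names = NULL)
  lab <- sprintf("G%d", (1:4) + offset)
  attr(out, "counts") <- stats::setNames(
    as.integer(table(factor(group, levels = lab))), lab)
  class(out) <- c("gene_group_assignment", "data.frame")
  out
}

#' Functional-category enrichment of a gene set
#'
#' One-sided hypergeometric (Fisher exact upper-tail) test of whether the
#' target category is over-represented in the gene set relative to the
#' universe: with N universe genes of which K are in the category and a set
#' of size n overlapping it in k genes, p = P(X >= k) for X hypergeometric.
#' Exact at any size used here.
#'
#' @param gene_set character vector of gene ids (must lie in the universe).
#' @param categories named character vector gene id -> category.
#' @param target_category the category tested for enrichment.
#' @param universe gene universe (default: all categorized genes).
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#'   (Fisher exact).
#' @return list of class `enrichment_result`: `table` (2x2), `k`, `K`, `n`,
#'   `N`, `odds_ratio`, `p`.
#' @export
category_enrichment <- function(gene_set, categories, target_category,
                                universe = names(categories),
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!target_category %in% categories) stop("empty category '", target_category, "'")
  bad <- setdiff(gene_set, universe)
  if (length(bad)) stop("gene set contains genes outside the universe: ", bad[1])
  gene_set <- unique(gene_set)
  in_cat <- names(categories)[categories == target_category]
  in_cat <- intersect(in_cat, universe)
  N <- length(universe); K <- length(in_cat); n <- length(gene_set)
  k <- length(intersect(gene_set, in_cat))
  tab <- matrix(c(k, K - k, n - k, (N - K) - (n - k)), 2, 2,
                dimnames = list(category = c("in", "out"),
                                set = c("in", "out")))
  p <- if (n == 0) 1
  else if (alternative == "greater")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  structure(list(table = tab, k = k, K = K, n = n, N = N,
                 odds_ratio = or, p = p, alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: k=%d of n=%d in category (K=%d of N=%d); OR=%.3g; p=%.3g (%s)\n",
              x$k, x$n, x$K, x$N, x$odds_ratio, x$p, x$alternative))
  invisible(x)
}

#' Per-category deregulation fractions
#'
#' For every functional category, the percentage of its genes called up, down
#' and deregulated in either direction, with the category size as the
#' denominator.
#'
#' @param de_calls named vector of calls (`up_in_mutant` = up,
#'   `up_in_WT` = down in the mutant).
#' @param categories named character vector gene id -> category.
#' @return data.frame (category, n, n_up, n_down, pct_up, pct_down,
#'   pct_deregulated).
#' @export
deregulation_fractions <- function(de_calls, categories) {
  cats <- sort(unique(categories))
  rows <- lapply(cats, function(cc) {
    g <- names(categories)[categories == cc]
    call <- de_calls[g]
    n_up <- sum(call == "up_in_mutant", na.rm = TRUE)
    n_down <- sum(call == "up_in_WT", na.rm = TRUE)
    data.frame(category = cc, n = length(g), n_up = n_up, n_down = n_down,
               pct_up = 100 * n_up / length(g),
               pct_down = 100 * n_down / length(g),
               pct_deregulated = 100 * (n_up + n_down) / length(g))
  })
  do.call(rbind, rows)
}

#' Per-category mark-level summaries
#'
#' Median, quartiles and n of the log2 mark level per category, plus a
#' two-sided Mann-Whitney (rank-sum) p-value for each pair of categories.
#'
#' @param levels named numeric vector of per-gene log2 mark levels.
#' @param categories named character vector gene id -> category.
#' @return list with `summary` (data.frame category, n, q1, median, q3) and
#'   `tests` (data.frame category_a, category_b, p).
#' @export
category_mark_summary <- function(levels, categories) {
  genes <- intersect(names(levels), names(categories))
  lev <- levels[genes]; cat_of <- categories[genes]
  cats <- sort(unique(cat_of))
  summary <- do.call(rbind, lapply(cats, function(cc) {
    x <- lev[cat_of == cc]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(category = cc, n = length(x), q1 = q[1], median = q[2], q3 = q[3])
  }))
  tests <- NULL
  if (length(cats) >= 2) {
    pairs <- utils::combn(cats, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- lev[cat_of == pairs[1, j]]; b <- lev[cat_of == pairs[2, j]]
      p <- if (length(a) && length(b))
        stats::wilcox.test(a, b, exact = FALSE)$p.value else NA_real_
      data.frame(category_a = pairs[1, j], category_b = pairs[2, j], p = p)
    }))
  }
  list(summary = summary, tests = tests)
}

#' Call broad H3K9me3 domains from a binned track
#'
#' Maximal runs of bins at or above the threshold are merged across gaps of
#' at most `merge_gap` bp and kept if at least `min_len` bp long.  The
#' default threshold is 4x the genome-wide median of the nonzero bin
#' values, which separates planted heterochromatin rectangles from the
#' euchromatic background.
#'
#' @param binned a `binned_track` (typically H3K9me3 CPM).
#' @param threshold_cpm bin-level threshold; `NULL` for the median rule.
#' @param min_len minimum domain length, bp.
#' @param merge_gap maximal gap bridged when merging runs, bp.
#' @return data.frame (chrom, start, end, mean_cpm), 0-based half-open;
#'   non-overlapping and sorted.
#' @export
call_k9_domains <- function(binned, threshold_cpm = NULL, min_len = 2000L,
                            merge_gap = 500L) {
  stopifnot(inherits(binned, "binned_track"))
  step <- binned$step
  if (is.null(threshold_cpm)) {
    allv <- unlist(binned$bins, use.names = FALSE)
    nz <- allv[allv > 0]
    if (!length(nz)) return(empty_domains())
    threshold_cpm <- 4 * stats::median(nz)
  }
  out <- list()
  for (ch in names(binned$bins)) {
    v <- binned$bins[[ch]]
    above <- v >= threshold_cpm
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    runs <- data.frame(start = starts[r$values] * step,
                       end = pmin(ends[r$values] * step,
                                  binned$genome_lengths[[ch]]))
    # merge across small gaps
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    merged <- merged[merged$end - merged$start >= min_len, , drop = FALSE]
    if (!nrow(merged)) next
    merged$chrom <- ch
    merged$mean_cpm <- vapply(seq_len(nrow(merged)), function(i) {
      b0 <- merged$start[i] %/% step + 1L
      b1 <- min((merged$end[i] - 1L) %/% step + 1L, length(v))
      mean(v[b0:b1])
    }, numeric(1))
    out[[ch]] <- merged[, c("chrom", "start", "end", "mean_cpm")]
  }
  if (!length(out)) return(empty_domains())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_domains <- function() data.frame(
  chrom = character(0), start = integer(0), end = integer(0),
  mean_cpm = numeric(0))

#' Write domains as BED3+score
#' @param domains output of [call_k9_domains()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.6g", domains$chrom,
                     as.integer(domains$start), as.integer(domains$end),
                     domains$mean_cpm), path)
  invisible(path)
}

#' Heterochromatin flanking of secondary-metabolite clusters
#'
#' For every annotated SM cluster, the distance from its outermost gene
#' coordinates to the nearest domain edge on each side (0 when a domain
#' overlaps or abuts the cluster), flags at `max_gap`, and a classification
#' into `both`, `one` or `none` flanked sides.
#'
#' @param domains data.frame (chrom, start, end) of called domains.
#' @param annotation a `genome_annotation` with `cluster_id`.
#' @param max_gap maximal cluster-to-domain gap called flanked, bp.
#' @return data.frame (cluster_id, chrom, start, end, dist_left, dist_right,
#'   flanked_left, flanked_right, classification).
#' @export
cluster_flanking <- function(domains, annotation, max_gap = 5000L) {
  ids <- sort(unique(annotation$cluster_id[!is.na(annotation$cluster_id)]))
  rows <- lapply(ids, function(id) {
    g <- annotation[!is.na(annotation$cluster_id) & annotation$cluster_id == id, ]
    ch <- g$chrom[1]
    cs <- min(g$start); ce <- max(g$end)
    d <- domains[domains$chrom == ch, , drop = FALSE]
    # left: domains not starting right of the cluster start
    dl <- d[d$start < cs, , drop = FALSE]
    dist_left <- if (nrow(dl)) max(0, cs - max(dl$end)) else Inf
    dr <- d[d$end > ce, , drop = FALSE]
    dist_right <- if (nrow(dr)) max(0, min(dr$start) - ce) else Inf
    fl <- dist_left <= max_gap; fr <- dist_right <= max_gap
    data.frame(cluster_id = id, chrom = ch, start = cs, end = ce,
               dist_left = dist_left, dist_right = dist_right,
               flanked_left = fl, flanked_right = fr,
               classification = if (fl && fr) "both"
               else if (fl || fr) "one" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
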