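test_that("mark split puts the boundary in the low tier and skips masked genes", {
  q <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  log2_window_cpm = c(5.0, 5.01, 1.2, 9),
                  masked = c(FALSE, FALSE, FALSE, TRUE))
  s <- split_by_mark(q, threshold = 5)
  expect_equal(unname(s$tiers[c("g1", "g2", "g3")]), c("low", "high", "low"))
  expect_false("g4" %in% names(s$tiers))
  expect_equal(s$skipped, "g4")
})

test_that("group assignment crosses tier with DE call per the G1-G4 table", {
  tiers <- c(g1 = "low", g2 = "low", g3 = "high", g4 = "high", g5 = "low")
  calls <- c(g1 = "up_in_WT", g2 = "up_in_mutant", g3 = "up_in_WT",
             g4 = "up_in_mutant", g5 = "ns", g6 = "up_in_WT")
  ga <- assign_groups(tiers, calls)
  got <- setNames(ga$group, ga$gene_id)
  expect_equal(unname(got[c("g1", "g2", "g3", "g4")]),
               c("G1", "G2", "G3", "G4"))
  expect_true(is.na(got["g5"]))  # ns -> no group
  expect_true(is.na(got["g6"]))  # no tier -> no group
  expect_equal(unname(attr(ga, "counts")), c(1L, 1L, 1L, 1L))

  # 48-h labelling: same cross shifted to G5-G8
  ga8 <- assign_groups(tiers, calls, offset = 4L)
  expect_equal(unname(setNames(ga8$group, ga8$gene_id)[c("g1", "g4")]),
               c("G5", "G8"))
})

test_that("group counts partition the DE-called genes with defined tiers", {
  rep <- run_pipeline(pipeline_config(sim = sim_config(seed = 5,
                                                       n_genes = 200L,
                                                       chrom_length = 400000L),
                                      n_reps = 2))
  ga <- rep$groups
  called <- ga$gene_id[!is.na(ga$call) & ga$call != "ns" & !is.na(ga$tier)]
  grouped <- ga$gene_id[!is.na(ga$group)]
  expect_setequal(called, grouped)
  expect_equal(sum(attr(ga, "counts")), length(grouped))
  expect_false(anyDuplicated(grouped) > 0)
})

test_that("hypergeometric enrichment is exact", {
  categories <- setNames(rep(c("SM", "CSF"), c(5, 15)), sprintf("g%d", 1:20))
  # closed form: N=20, K=5, n=4, k=3 -> [C(5,3)C(15,1)+C(5,4)C(15,0)]/C(20,4)
  set <- c("g1", "g2", "g3", "g6")
  e <- category_enrichment(set, categories, "SM")
  expect_equal(e$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(e$k, 3); expect_equal(e$K, 5); expect_equal(e$n, 4)

  # empty set -> p = 1
  e0 <- category_enrichment(character(0), categories, "SM")
  expect_equal(e0$p, 1)

  expect_error(category_enrichment(set, categories, "XXX"), "empty category")
  expect_error(category_enrichment("nope", categories, "SM"), "outside")
})

test_that("hypergeometric tail matches exhaustive enumeration for N <= 25", {
  set.seed(14)
  for (i in 1:30) {
    N <- sample(5:25, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    genes <- sprintf("g%d", 1:N)
    categories <- setNames(rep("other", N), genes)
    categories[sample(N, K)] <- "target"
    set <- sample(genes, n)
    e <- category_enrichment(set, categories, "target")
    expect_equal(e$p, hyper_tail_bruteforce(e$k, K, N, n), tolerance = 1e-12)
  }
})

test_that("deregulation fractions use the category size as denominator", {
  categories <- setNames(rep(c("SM", "CSF"), c(149, 5676)),
                         sprintf("g%05d", 1:5825))
  sm <- names(categories)[categories == "SM"]
  calls <- setNames(rep("ns", 5825), names(categories))
  calls[sm[1:97]] <- "up_in_WT"      # down in the mutant
  calls[sm[98:119]] <- "up_in_mutant"
  d <- deregulation_fractions(calls, categories)
  smrow <- d[d$category == "SM", ]
  expect_equal(smrow$pct_deregulated, 100 * 119 / 149, tolerance = 1e-12)
  expect_gt(smrow$pct_deregulated, 50)
  expect_equal(smrow$n_down, 97)

  # category of 10 with 1 up -> 10% up; none deregulated -> 0
  cat2 <- setNames(rep("A", 10), sprintf("a%d", 1:10))
  calls2 <- setNames(c("up_in_mutant", rep("ns", 9)), names(cat2))
  d2 <- deregulation_fractions(calls2, cat2)
  expect_equal(d2$pct_up, 10)
  d3 <- deregulation_fractions(setNames(rep("ns", 10), names(cat2)), cat2)
  expect_equal(d3$pct_deregulated, 0)
})

test_that("category mark summaries report medians, quartiles and rank-sum p", {
  # single-gene category: quartiles collapse to that gene's value
  lev <- setNames(c(1, 2, 3, 7), sprintf("g%d", 1:4))
  cats <- setNames(c("A", "A", "A", "B"), names(lev))
  cs <- category_mark_summary(lev, cats)
  b <- cs$summary[cs$summary$category == "B", ]
  expect_equal(c(b$q1, b$median, b$q3), c(7, 7, 7))

  # planted separation: SM at 1/8 the CSF level -> lower median, small p
  set.seed(9)
  lev2 <- c(setNames(rnorm(200, 5, 0.5), sprintf("c%d", 1:200)),
            setNames(rnorm(30, 2, 0.5), sprintf("s%d", 1:30)))
  cats2 <- setNames(rep(c("CSF", "SM"), c(200, 30)), names(lev2))
  cs2 <- category_mark_summary(lev2, cats2)
  med <- setNames(cs2$summary$median, cs2$summary$category)
  expect_gt(med["CSF"], med["SM"])
  expect_lt(cs2$tests$p, 0.01)

  # identical distributions: rank-sum p roughly uniform over simulations
  ps <- vapply(1:200, function(i) {
    set.seed(i)
    l <- setNames(rnorm(60), sprintf("g%d", 1:60))
    cc <- setNames(rep(c("A", "B"), 30), names(l))
    category_mark_summary(l, cc)$tests$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(median(ps), 0.3)
})

test_that("domain calling merges across small gaps and filters short runs", {
  mk_binned <- function(v, step = 100L) {
    tr <- coverage_track(list(chr1 = rep(v, each = step)),
                         total_mapped_reads = 1e6, normalized = TRUE)
    smooth_and_bin(tr, window = step, step = step)
  }
  # flat zero -> no domains
  expect_equal(nrow(call_k9_domains(mk_binned(rep(0, 100)), threshold_cpm = 1)), 0)

  # one 5-kb rectangle -> exactly one domain spanning it
  v <- rep(0, 100); v[21:70] <- 10
  d <- call_k9_domains(mk_binned(v), threshold_cpm = 5)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(2000, 7000))

  # two 1.5-kb blocks 300 bp apart merge into one 3.3-kb domain
  v2 <- rep(0, 100); v2[11:25] <- 10; v2[29:43] <- 10
  d2 <- call_k9_domains(mk_binned(v2), threshold_cpm = 5,
                        min_len = 2000, merge_gap = 500)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$end - d2$start, 3300)

  # without merging both blocks fall below min_len
  d3 <- call_k9_domains(mk_binned(v2), threshold_cpm = 5,
                        min_len = 2000, merge_gap = 100)
  expect_equal(nrow(d3), 0)
})

test_that("cluster flanking classifies both/one/none and recovers the truth", {
  ann <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    chrom = "chr1",
    start = c(10000L, 12000L, 40000L, 42000L),
    end = c(11000L, 13000L, 41000L, 43000L),
    strand = "+", orf_length = 1000L, category = "SM",
    cluster_id = c("C1", "C1", "C2", "C2"), stringsAsFactors = FALSE)
  # C1 flanked on both sides (abutting), C2 only on the left, far
  domains <- data.frame(chrom = "chr1",
                        start = c(5000, 13000, 34000),
                        end = c(10000, 18000, 36000))
  fr <- cluster_flanking(domains, ann, max_gap = 5000)
  expect_equal(setNames(fr$classification, fr$cluster_id),
               c(C1 = "both", C2 = "one"))
  expect_equal(fr$dist_left[fr$cluster_id == "C1"], 0)
  expect_equal(fr$dist_left[fr$cluster_id == "C2"], 4000)
  expect_false(fr$flanked_right[fr$cluster_id == "C2"])

  # on simulated data, flagged clusters are recovered exactly
  cfg <- sim_config(seed = 30, frac_k9_flanked_clusters = 0.5)
  sim <- simulate_dataset(cfg, n_reps = 2, marks = "H3K9me3")
  b <- smooth_and_bin(cpm_normalize(sim$tracks$H3K9me3$WT))
  dom <- call_k9_domains(b)
  fl <- cluster_flanking(dom, sim$annotation)
  truth <- sim$truth$clusters
  expect_equal(fl$classification == "both",
               truth$flanked_by_k9[match(fl$cluster_id, truth$cluster_id)])
})

test_that("flanking classification is invariant under genome mirroring", {
  cfg <- sim_config(seed = 31, frac_k9_flanked_clusters = 0.5)
  sim <- simulate_dataset(cfg, n_reps = 2, marks = "H3K9me3")
  tr <- cpm_normalize(sim$tracks$H3K9me3$WT)
  dom <- call_k9_domains(smooth_and_bin(tr))
  fl <- cluster_flanking(dom, sim$annotation)

  L <- tr$genome_lengths
  dom_m <- dom
  dom_m$start <- L[dom$chrom] - dom$end
  dom_m$end <- L[dom$chrom] - dom$start
  ann <- sim$annotation
  ann_m <- ann
  ann_m$start <- L[ann$chrom] - ann$end
  ann_m$end <- L[ann$chrom] - ann$start
  ann_m$strand <- ifelse(ann$strand == "+", "-", "+")
  fl_m <- cluster_flanking(dom_m, ann_m)
  expect_equal(setNames(fl_m$classification, fl_m$cluster_id),
               setNames(fl$classification, fl$cluster_id))
  expect_equal(setNames(fl_m$dist_left, fl_m$cluster_id),
               setNames(fl$dist_right, fl$cluster_id))
})
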