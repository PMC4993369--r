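test_that("generated genomes honor the configured category structure", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 400000L, n_genes = 100L,
                    n_sm_clusters = 2L, sm_cluster_size = 5L, seed = 4)
  g <- gen_genome(cfg)
  ann <- g$annotation
  expect_equal(nrow(ann), 100L)
  expect_equal(sum(ann$category == "SM"), 10L)
  expect_equal(sum(ann$category == "CSF"), 90L)
  expect_equal(length(unique(na.omit(ann$cluster_id))), 2L)
  # SM clusters are contiguous coordinate runs: between the outermost genes
  # of a cluster there is no CSF gene
  for (id in unique(na.omit(ann$cluster_id))) {
    g_cl <- ann[!is.na(ann$cluster_id) & ann$cluster_id == id, ]
    within <- ann$chrom == g_cl$chrom[1] & ann$start >= min(g_cl$start) &
      ann$end <= max(g_cl$end)
    expect_true(all(ann$category[within] == "SM"))
  }
  # genes do not overlap
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  # every gene in exactly one category
  expect_true(all(ann$category %in% c("CSF", "SM")))
})

test_that("the generator is deterministic: same config, same outputs", {
  cfg <- tiny_config(seed = 9)
  s1 <- simulate_dataset(cfg, n_reps = 2)
  s2 <- simulate_dataset(cfg, n_reps = 2)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$tracks$H3K4me3$WT$signal, s2$tracks$H3K4me3$WT$signal)
  expect_identical(s1$peptides, s2$peptides)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixtures(s1, d1); m2 <- write_fixtures(s2, d2)
  expect_identical(m1$md5, m2$md5)  # byte-identical fixture files
})

test_that("infeasible gene packing raises a configuration error", {
  expect_error(
    gen_genome(sim_config(n_chromosomes = 1L, chrom_length = 30000L,
                          n_genes = 50L, gene_length_range = c(2000L, 2400L),
                          n_sm_clusters = 0L, seed = 1)),
    "configuration error")
  expect_error(sim_config(n_genes = 10L, n_sm_clusters = 3L,
                          sm_cluster_size = 5L), "exceeds n_genes")
})

test_that("background-only coverage has genome-wide mean near lambda", {
  cfg <- tiny_config(seed = 2)
  cfg$mark_shape_params$amplitude <- 0
  cfg$mark_shape_params$background <- 1
  g <- gen_genome(cfg)
  tr <- gen_coverage(g$annotation, g$truth, "H3Ac", "WT", cfg)
  m <- mean(tr$signal$chr1)
  expect_lt(abs(m - 1), 4 / sqrt(cfg$chrom_length))  # Poisson SE bound
})

test_that("H3K4me3 kernel mass concentrates downstream of the ATG", {
  # one strong plus-strand gene: >80% of the window signal inside [ATG, ATG+500]
  cfg <- tiny_config(seed = 6)
  cfg$mark_shape_params$amplitude <- 500
  cfg$mark_shape_params$background <- 0.1
  g <- gen_genome(cfg)
  g$truth$genes$k4_level <- 0
  gi <- which(g$annotation$strand == "+")[1]
  g$truth$genes$k4_level[gi] <- 1
  tr <- gen_coverage(g$annotation, g$truth, "H3K4me3", "WT", cfg)
  a <- g$annotation$start[gi]
  sig <- tr$signal[[g$annotation$chrom[gi]]]
  win <- sig[(a - 500 + 1):(a + 1500)]
  inner <- sig[(a + 1):(a + 500)]
  expect_gt(sum(inner) / sum(win), 0.8)
})

test_that("minus-strand coverage is the mirror image of the plus-strand case", {
  cfg <- tiny_config(seed = 6)
  cfg$mark_shape_params$background <- 0
  g <- gen_genome(cfg)
  ann <- g$annotation
  gi <- which(ann$strand == "+")[1]
  g$truth$genes$k4_level <- 0
  g$truth$genes$k4_level[gi] <- 1
  mu_plus <- chromexpr:::coverage_mean_surface(ann, g$truth, "H3K4me3", "WT", cfg)
  ann2 <- ann
  ann2$strand[gi] <- "-"
  mu_minus <- chromexpr:::coverage_mean_surface(ann2, g$truth, "H3K4me3", "WT", cfg)
  # the minus-strand kernel is the reflection of the plus-strand kernel
  # about the gene midpoint
  ch <- ann$chrom[gi]
  s <- ann$start[gi]; e <- ann$end[gi]
  lo <- s - 1500; hi <- e + 1500
  seg_p <- mu_plus[[ch]][(lo + 1):hi]
  seg_m <- mu_minus[[ch]][(lo + 1):hi]
  expect_equal(seg_m, rev(seg_p), tolerance = 1e-12)
})

test_that("unknown marks are rejected with the supported list", {
  cfg <- tiny_config()
  g <- gen_genome(cfg)
  expect_error(gen_coverage(g$annotation, g$truth, "H3K27me3", "WT", cfg),
               "H3K4me3")
})

test_that("planted fold-changes appear in count sample-mean ratios", {
  cfg <- tiny_config(seed = 13)
  g <- gen_genome(cfg)
  # force one high-baseline gene up 4-fold at 48 h
  g$truth$genes$tier <- 3L  # high-tier baselines (mean 2000)
  g$truth$genes$de_SM48 <- "ns"; g$truth$genes$lfc_SM48 <- 0
  g$truth$genes$de_SM48[1] <- "up"; g$truth$genes$lfc_SM48[1] <- 2
  design <- data.frame(
    sample_id = sprintf("s%d", 1:10),
    strain = rep(c("WT", "mutant"), each = 5),
    condition = "SM48")
  cm <- gen_counts(g$annotation, g$truth, design, cfg)
  wt <- rowMeans(cm$counts[1, design$strain == "WT", drop = FALSE])
  mu <- rowMeans(cm$counts[1, design$strain == "mutant", drop = FALSE])
  expect_gt(mu / wt, 3)
  expect_lt(mu / wt, 5.3)
})

test_that("frac_de = 0 plants no differential expression", {
  cfg <- tiny_config(seed = 3, frac_de = 0, sm_frac_down = 0, sm_frac_up = 0)
  cfg$n_sm_clusters <- 0L
  g <- gen_genome(cfg)
  expect_true(all(g$truth$genes$de_SM48 == "ns"))
  expect_true(all(g$truth$genes$lfc_SM48 == 0))
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- tiny_config(seed = 8, nb_dispersion = 1e-8)
  g <- gen_genome(cfg)
  g$truth$genes$de_SM48 <- "ns"; g$truth$genes$lfc_SM48 <- 0
  design <- data.frame(sample_id = sprintf("s%d", 1:40),
                       strain = "WT", condition = "SM48")
  cm <- gen_counts(g$annotation, g$truth, design, cfg)
  # after removing the per-sample depth factor, variance ~ mean across the
  # 40 replicate samples
  sf <- cm$library_sizes / mean(cm$library_sizes)
  scaled <- sweep(cm$counts, 2, sf, "/")
  m <- rowMeans(scaled); v <- apply(scaled, 1, var)
  keep <- m > 50
  ratio <- v[keep] / m[keep]
  expect_lt(abs(median(ratio) - 1), 0.35)
})

test_that("replication below two per group is rejected", {
  cfg <- tiny_config()
  g <- gen_genome(cfg)
  design <- data.frame(sample_id = c("a", "b", "c"),
                       strain = c("WT", "WT", "mutant"), condition = "PM")
  expect_error(gen_counts(g$annotation, g$truth, design, cfg), "2 replicates")
})

test_that("peptide tables are Dirichlet-centered on the truth with unit sums", {
  truth <- default_peptide_truth()
  # concentration -> infinity recovers the truth
  tab <- gen_peptide_table(truth, noise_concentration = 1e9, seed = 2)
  expect_equal(tab$abundance, truth$fraction, tolerance = 1e-3)

  # unit sums per site x strain, always
  tab <- gen_peptide_table(truth, noise_concentration = 50, seed = 2)
  sums <- tapply(tab$abundance, interaction(tab$site, tab$strain, drop = TRUE), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)

  # Dirichlet moments: replicate means within 0.01 of the truth
  k4wt <- truth[truth$site == "H3K4" & truth$strain == "WT", ]
  obs <- sapply(1:1000, function(i)
    gen_peptide_table(k4wt, noise_concentration = 50, seed = i)$abundance)
  expect_true(all(abs(rowMeans(obs) - k4wt$fraction) < 0.01))

  # malformed truth rejected
  bad <- k4wt; bad$fraction[1] <- bad$fraction[1] + 0.01
  expect_error(gen_peptide_table(bad, 50, 1), "sum to 1")
})

test_that("fixtures round-trip through the package readers", {
  cfg <- tiny_config(seed = 21)
  sim <- simulate_dataset(cfg, n_reps = 2, marks = c("H3K4me3", "H3K9me3"))
  d <- withr::local_tempdir()
  manifest <- write_fixtures(sim, d)
  expect_true(all(file.exists(file.path(d, manifest$file))))

  ann <- read_gff3(file.path(d, "annotation.gff3"))
  expect_equal(ann$gene_id, sim$annotation$gene_id)
  expect_equal(ann$start, sim$annotation$start)
  expect_equal(ann$end, sim$annotation$end)
  expect_equal(ann$strand, sim$annotation$strand)
  expect_equal(ann$category, sim$annotation$category)

  bg <- manifest[manifest$file == "coverage_H3K4me3_WT.bedgraph", ]
  tr <- read_bedgraph(file.path(d, bg$file),
                      sim$tracks$H3K4me3$WT$genome_lengths,
                      total_mapped_reads = bg$total_mapped_reads)
  expect_identical(tr$signal, sim$tracks$H3K4me3$WT$signal)
  expect_equal(tr$total_mapped_reads, sim$tracks$H3K4me3$WT$total_mapped_reads)

  cm <- read_counts_tsv(file.path(d, "counts.tsv"), sim$design)
  expect_equal(cm$counts, sim$counts$counts)
})
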