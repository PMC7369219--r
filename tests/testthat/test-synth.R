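small_cfg <- function(...) {
  args <- list(n_chroms = 2, chrom_length = 20000L, n_genes = 20,
               gene_length = c(300, 800), n_peaks = 5, n_de = 8, n_direct = 5)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("the genome generator is byte-deterministic per seed", {
  g1 <- simulate_genome(small_cfg(), seed = 11)
  g2 <- simulate_genome(small_cfg(), seed = 11)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$truth$peaks, g2$truth$peaks)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$genome, f1)
  write_genome_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- simulate_genome(small_cfg(), seed = 12)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("gene models are in bounds, non-overlapping, and round-trip FASTA/GFF3", {
  g <- simulate_genome(small_cfg(), seed = 5)
  genes <- g$genes
  expect_true(all(genes$start >= 0))
  expect_true(all(genes$end <= 20000))
  for (d in split(genes, genes$chrom)) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # planted intervals lie within chromosome bounds
  expect_true(all(g$truth$peaks$start >= 0 & g$truth$peaks$end <= 20000))
  # DE targets are annotated genes; direct targets are bound DE targets
  expect_true(all(g$truth$de_targets$gene %in% genes$gene_id))
  expect_true(all(g$truth$direct_targets %in%
                    intersect(g$truth$de_targets$gene, g$truth$bound_genes)))
  ff <- withr::local_tempfile(fileext = ".fa")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(g$genome, ff)
  expect_identical(read_genome_fasta(ff), g$genome)
  write_gff_genes(genes, gf)
  back <- read_gff_genes(gf)
  expect_equal(back[order(back$gene_id), ], genes[order(genes$gene_id), ])
})

test_that("n_genes = 0 gives an empty feature set over a valid genome", {
  g <- simulate_genome(sim_config(n_genes = 0, n_peaks = 0, n_de = 0,
                                  n_direct = 0), seed = 1)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nchar(g$genome[["chr1"]]), 200000)
  expect_true(all(strsplit(substr(g$genome[["chr1"]], 1, 1000), "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("infeasible gene packing is an explicit error", {
  expect_error(
    simulate_genome(sim_config(n_chroms = 1, chrom_length = 5000L,
                               n_genes = 10, gene_length = c(900, 1000),
                               n_peaks = 0, n_de = 0, n_direct = 0), seed = 1),
    "packing"
  )
})

test_that("planted consensus sites are all recovered by the planting PWM scan", {
  g <- simulate_genome(small_cfg(n_peaks = 5), seed = 31)
  hits <- scan_pwm(g$truth$motif, g$genome, p_threshold = 0.001)
  sites <- g$truth$motif_sites
  expect_equal(nrow(sites), 5)
  for (i in seq_len(nrow(sites))) {
    expect_true(any(hits$chrom == sites$chrom[i] & hits$start == sites$pos[i] &
                      hits$strand == sites$strand[i]))
  }
})

test_that("coverage simulation honors background and enrichment components", {
  g <- simulate_genome(small_cfg(), seed = 41)
  # enrichment 0: tagged and untagged means agree within 3 standard errors
  cfg0 <- small_cfg(enrichment_depth = 0)
  tg <- simulate_chip_coverage(g$truth, cfg0, tagged = TRUE, seed = 52)[[1]]
  un <- simulate_chip_coverage(g$truth, cfg0, tagged = FALSE, seed = 53)[[1]]
  mt <- mean(tg$depth); mu <- mean(un$depth)
  se <- sqrt(var(tg$depth) / nrow(tg) + var(un$depth) / nrow(un))
  expect_lt(abs(mt - mu), 3 * se)
  # background 0, tagged: depth is 0 everywhere outside planted peaks
  cfg1 <- small_cfg(background_depth = 0)
  tg1 <- simulate_chip_coverage(g$truth, cfg1, tagged = TRUE, seed = 53)[[1]]
  inside <- rep(FALSE, nrow(tg1))
  for (i in seq_len(nrow(g$truth$peaks))) {
    pk <- g$truth$peaks[i, ]
    inside[tg1$chrom == pk$chrom & tg1$pos >= pk$start & tg1$pos < pk$end] <- TRUE
  }
  expect_true(all(tg1$depth[!inside] == 0))
  expect_gt(mean(tg1$depth[inside]), 50)
  # untagged never receives enrichment even at background 0
  un1 <- simulate_chip_coverage(g$truth, cfg1, tagged = FALSE, seed = 54)[[1]]
  expect_true(all(un1$depth == 0))
  # replicate count and determinism
  reps <- simulate_chip_coverage(g$truth, small_cfg(), tagged = TRUE, seed = 55)
  expect_length(reps, 2)
  reps2 <- simulate_chip_coverage(g$truth, small_cfg(), tagged = TRUE, seed = 55)
  expect_identical(reps, reps2)
})

test_that("NB counts obey the generative model's moments and design checks", {
  g <- simulate_genome(sim_config(n_genes = 1000, n_peaks = 0, n_de = 0,
                                  n_direct = 0, gene_length = c(100, 150),
                                  chrom_length = 500000L), seed = 61)
  design <- make_design(timepoints = 2, n_batches = 4)
  # phi = 0 limit: per-gene variance tracks the mean (Poisson)
  cfg <- sim_config(nb_dispersion = 0, batch_effect_sd = 0,
                    library_size = c(1e6, 1e6), baseline_sdlog = 0,
                    n_de = 0, n_direct = 0)
  sim <- simulate_counts(design, g$truth, g$genes, cfg, seed = 62)
  m <- as.matrix(sim$counts[, -1])
  ratio <- apply(m, 1, var) / rowMeans(m)
  # dispersion index across 1000 genes: mean ~ 1 under Poisson
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # missing treatment arm is an explicit error
  expect_error(simulate_counts(design[design$treatment == "dex", ],
                               g$truth, g$genes, cfg, seed = 1),
               "treatment arm")
  expect_identical(simulate_counts(design, g$truth, g$genes, cfg, seed = 9),
                   simulate_counts(design, g$truth, g$genes, cfg, seed = 9))
})

test_that("a planted logFC of 2 is recovered without bias at n = 4 pairs", {
  # At mu = 100, phi = 0.05 and 4 pairs the sampling sd of a per-gene logFC
  # estimate is ~0.25, so per-gene estimates scatter around the truth while
  # the cross-gene mean recovers it closely.
  g <- simulate_genome(sim_config(n_genes = 400, chrom_length = 500000L,
                                  n_peaks = 0, n_de = 40, n_direct = 0,
                                  de_logfc = 2, baseline_mean = 100,
                                  baseline_sdlog = 0), seed = 71)
  design <- make_design(timepoints = 2, n_batches = 4)
  sim <- simulate_counts(design, g$truth, g$genes, seed = 72)
  r <- fit_de(sim$counts, sim$meta, 2)
  est <- dplyr::inner_join(r, g$truth$de_targets, by = "gene",
                           suffix = c("", "_true"))
  err <- abs(est$logFC) - 2
  expect_lt(abs(mean(err)), 0.1)
  expect_lt(sd(err), 0.35)
})
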