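mini_meta <- function(n_batches = 4, timepoint = 2, lib_size = 1e6) {
  d <- make_design(timepoints = timepoint, n_batches = n_batches)
  dplyr::mutate(d, lib_size = lib_size)
}

# counts with a known multiplicative treatment effect on the first
# n_effect genes, balanced up/down so TMM stays anchored on the unchanged
# majority without directional bias; no batch effect
mini_counts <- function(n_genes, meta, mu = 200, fc = 1, phi = 0.05, seed = 1,
                        n_effect = if (fc == 1) 0 else round(0.1 * n_genes)) {
  set.seed(seed)
  fc_g <- rep(1, n_genes)
  if (n_effect > 0) {
    half <- n_effect %/% 2
    fc_g[seq_len(n_effect)] <- c(rep(fc, n_effect - half), rep(1 / fc, half))
  }
  m <- sapply(seq_len(nrow(meta)), function(s) {
    mean_s <- mu * fc_g^(meta$treatment[s] == "dex") * meta$lib_size[s] / 1e6
    if (phi == 0) rpois(n_genes, mean_s) else rnbinom(n_genes, mu = mean_s, size = 1 / phi)
  })
  colnames(m) <- meta$sample
  dplyr::bind_cols(tibble::tibble(gene = sprintf("g%04d", seq_len(n_genes))),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

test_that("RPKM follows the unit definition and its scaling laws", {
  counts <- tibble::tibble(gene = c("a", "b"), s1 = c(10, 0))
  lens <- tibble::tibble(gene = c("a", "b"), length = c(1000, 500))
  meta <- tibble::tibble(sample = "s1", lib_size = 1e6)
  r <- rpkm(counts, lens, meta)
  expect_equal(r$s1, c(10, 0))
  # doubling the library size halves RPKM exactly
  meta2 <- tibble::tibble(sample = "s1", lib_size = 2e6)
  expect_equal(rpkm(counts, lens, meta2)$s1, c(5, 0))
  expect_error(rpkm(counts, tibble::tibble(gene = c("a", "b"), length = c(0, 500)),
                    meta), "length")
  expect_error(rpkm(counts, lens, tibble::tibble(sample = "s1", lib_size = 0)),
               "library size")
})

test_that("TMM factors are 1 for identical samples and recover global ratios", {
  counts <- tibble::tibble(gene = sprintf("g%d", 1:100),
                           s1 = rep(50, 100), s2 = rep(50, 100))
  meta <- tibble::tibble(sample = c("s1", "s2"), lib_size = c(1e6, 1e6))
  expect_equal(tmm_factors(counts, meta)$norm_factor, c(1, 1))
  # sample B = 2 x A on every gene at equal recorded library size:
  # effective sizes (factor x libsize) must recover the 2.0 ratio
  counts2 <- tibble::tibble(gene = sprintf("g%d", 1:100),
                            A = rpois(100, 100) + 1)
  counts2$B <- counts2$A * 2
  f <- tmm_factors(counts2, tibble::tibble(sample = c("A", "B"),
                                           lib_size = c(1e6, 1e6)))
  eff <- f$norm_factor * 1e6
  expect_equal(eff[f$sample == "B"] / eff[f$sample == "A"], 2, tolerance = 1e-6)
  # factors multiply to 1 on random matrices
  set.seed(5)
  counts3 <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%d", 1:500)),
    tibble::as_tibble(matrix(rnbinom(500 * 6, mu = 80, size = 5), 500, 6,
                             dimnames = list(NULL, sprintf("s%d", 1:6))),
                      .name_repair = "minimal"))
  meta3 <- tibble::tibble(sample = sprintf("s%d", 1:6),
                          lib_size = colSums(counts3[, -1]))
  f3 <- tmm_factors(counts3, meta3)
  expect_equal(prod(f3$norm_factor), 1, tolerance = 1e-12)
  expect_error(tmm_factors(tibble::tibble(gene = "g", s1 = 0, s2 = 1),
                           tibble::tibble(sample = c("s1", "s2"),
                                          lib_size = c(1, 1))), "all-zero")
})

test_that("TMM agrees with the reference implementation on random data", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  m <- matrix(rnbinom(1000 * 5, mu = exp(runif(1000, 2, 7)), size = 3), 1000, 5)
  colnames(m) <- sprintf("s%d", 1:5)
  counts <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%d", 1:1000)),
                             tibble::as_tibble(m, .name_repair = "minimal"))
  meta <- tibble::tibble(sample = colnames(m), lib_size = colSums(m))
  ours <- tmm_factors(counts, meta)
  ref <- edgeR::calcNormFactors(m, lib.size = colSums(m), method = "TMM")
  expect_equal(ours$norm_factor, unname(ref), tolerance = 0.02)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance and monotonicity
  set.seed(4)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-12))
})

test_that("the NB fit recovers a planted logFC of 1 within 0.15", {
  meta <- mini_meta()
  counts <- mini_counts(400, meta, mu = 200, fc = 2, phi = 0.05, seed = 21)
  r <- fit_de(counts, meta, 2)
  up <- sprintf("g%04d", 1:20)
  down <- sprintf("g%04d", 21:40)
  expect_lt(abs(mean(r$logFC[r$gene %in% up]) - 1), 0.15)
  expect_lt(abs(mean(r$logFC[r$gene %in% down]) + 1), 0.15)
  # non-target genes center on zero
  expect_lt(abs(mean(r$logFC[!r$gene %in% c(up, down)])), 0.05)
})

test_that("a batch-only depth shift does not inflate false positives", {
  meta <- mini_meta()
  set.seed(31)
  n <- 600
  # 2-fold depth shift for two of the four batches, no treatment effect
  depth <- ifelse(meta$batch %in% c("b1", "b2"), 2, 1)
  m <- sapply(seq_len(nrow(meta)), function(s) {
    rnbinom(n, mu = 150 * depth[s], size = 20)
  })
  colnames(m) <- meta$sample
  counts <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%d", 1:n)),
                             tibble::as_tibble(m, .name_repair = "minimal"))
  r <- fit_de(counts, meta, 2)
  expect_lt(mean(r$p_value < 0.05), 0.09)
})

test_that("DE decisions are invariant to joint count/library-size rescaling", {
  meta <- mini_meta()
  counts <- mini_counts(150, meta, mu = 120, fc = 1.6, phi = 0.05, seed = 41)
  r1 <- fit_de(counts, meta, 2, dispersion = 0.05)
  # TMM's precision weights shift slightly when the reference sample is
  # rescaled, so invariance is exact in the offsets and near-exact overall
  # double one sample's counts and its recorded library size
  s <- meta$sample[3]
  counts2 <- counts
  counts2[[s]] <- counts2[[s]] * 2
  meta2 <- dplyr::mutate(meta, lib_size = ifelse(.data$sample == s,
                                                 .data$lib_size * 2,
                                                 .data$lib_size))
  r2 <- fit_de(counts2, meta2, 2, dispersion = 0.05)
  expect_equal(r1$logFC, r2$logFC, tolerance = 0.05)
  expect_equal(r1$p_value, r2$p_value, tolerance = 0.05)
})

test_that("fit_de validates the paired design", {
  meta <- mini_meta()
  counts <- mini_counts(10, meta, seed = 2)
  expect_error(fit_de(counts, meta[meta$treatment == "dex", ], 2),
               "treatment arm")
  expect_error(fit_de(counts, meta[meta$batch == "b1", ], 2), "two batches")
  expect_error(fit_de(counts, meta, 99), "no samples")
})

test_that("summarize_de partitions genes into the documented Venn cells", {
  mk <- function(gene, tp, lfc) {
    tibble::tibble(gene = gene, timepoint = tp, logFC = lfc, p_value = 0.001,
                   q_value = 0.01, significant = TRUE)
  }
  res <- dplyr::bind_rows(
    mk("g1", c(2, 4, 8), 0.5), mk("g2", 4, -0.4), mk("g3", c(4, 8), 0.7)
  )
  s <- summarize_de(res)
  v <- setNames(s$venn$n, s$venn$cell)
  expect_equal(unname(v["2&4&8"]), 1)
  expect_equal(unname(v["4"]), 1)
  expect_equal(unname(v["4&8"]), 1)
  expect_equal(sum(v[c("2", "8", "2&4", "2&8")]), 0)
  expect_equal(s$n_unique, 3)
  # Venn cells partition the unique DE set
  expect_equal(sum(s$venn$n), s$n_unique)
  expect_equal(unname(s$gene_directions), c(2, 1, 0))
  g <- glance(s)
  expect_equal(g$n_unique, 3)
  expect_equal(tidy(s), s$venn)
  # no significant genes -> all cells zero
  res0 <- dplyr::mutate(res, significant = FALSE)
  expect_equal(sum(summarize_de(res0)$venn$n), 0)
})

test_that("conflicting logFC signs across timepoints are reported ambiguous", {
  res <- tibble::tibble(gene = "g1", timepoint = c(2, 8), logFC = c(1, -1),
                        p_value = 0.001, q_value = 0.01, significant = TRUE)
  s <- summarize_de(res)
  expect_equal(unname(s$gene_directions["ambiguous"]), 1)
  expect_equal(unname(s$record_directions), c(1, 1))
})
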