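test_that("nearest-TSS assignment measures from the midpoint and breaks ties by id", {
  genes <- gene_models(tibble::tibble(
    gene_id = c("B_GENE", "A_GENE"), chrom = "chr1",
    start = c(100L, 500L), end = c(400L, 900L), strand = "+"
  ))
  # peak midpoint 300: distances 200 to both TSSs -> lexicographic winner
  pk <- tibble::tibble(peak_id = "p1", chrom = "chr1", start = 290L, end = 310L)
  a <- annotate_peaks(pk, genes)
  expect_equal(a$gene_id, "A_GENE")
  # single gene wins regardless of distance; midpoint on TSS -> distance 0
  one <- genes[1, ]
  far <- tibble::tibble(peak_id = "p2", chrom = "chr1", start = 99000L, end = 99010L)
  expect_equal(annotate_peaks(far, one)$gene_id, "B_GENE")
  on_tss <- tibble::tibble(peak_id = "p3", chrom = "chr1", start = 95L, end = 105L)
  expect_equal(annotate_peaks(on_tss, one)$tss_distance, 0)
  # no genes on chromosome -> unassigned
  other <- tibble::tibble(peak_id = "p4", chrom = "chrX", start = 0L, end = 10L)
  expect_true(is.na(annotate_peaks(other, genes)$gene_id))
})

test_that("positional categories follow the documented geometry and precedence", {
  # gene [100,200) on + strand
  expect_equal(classify_position(40, 60, 100, 200, "+"), "upstream")
  expect_equal(classify_position(120, 150, 100, 200, "+"), "inside")
  expect_equal(classify_position(50, 250, 100, 200, "+"), "encompass")
  expect_equal(classify_position(90, 110, 100, 200, "+"), "overlap_start")
  expect_equal(classify_position(190, 210, 100, 200, "+"), "overlap_end")
  expect_equal(classify_position(250, 300, 100, 200, "+"), "downstream")
  # minus strand: TSS sits at the 200 side
  expect_equal(classify_position(190, 210, 100, 200, "-"), "overlap_start")
  expect_equal(classify_position(90, 110, 100, 200, "-"), "overlap_end")
  expect_equal(classify_position(40, 60, 100, 200, "-"), "downstream")
  expect_equal(classify_position(250, 300, 100, 200, "-"), "upstream")
})

test_that("categories are exhaustive, exclusive, and match the set-based oracle", {
  set.seed(202)
  for (i in 1:300) {
    gs <- sample(50:150, 1); ge <- gs + sample(10:100, 1)
    ps <- sample(1:250, 1); pe <- ps + sample(1:120, 1)
    st <- sample(c("+", "-"), 1)
    got <- classify_position(ps, pe, gs, ge, st)
    expect_equal(got, classify_oracle(ps, pe, gs, ge, st),
                 info = sprintf("peak [%d,%d) gene [%d,%d) %s", ps, pe, gs, ge, st))
  }
})

test_that("categories are invariant under coordinate mirroring with strand flip", {
  set.seed(303)
  L <- 1000
  for (i in 1:100) {
    gs <- sample(100:400, 1); ge <- gs + sample(20:200, 1)
    ps <- sample(1:800, 1); pe <- ps + sample(5:150, 1)
    st <- sample(c("+", "-"), 1)
    mirrored <- classify_position(L - pe, L - ps, L - ge, L - gs,
                                  ifelse(st == "+", "-", "+"))
    expect_equal(classify_position(ps, pe, gs, ge, st), mirrored)
  }
})

test_that("position proportions use largest-remainder rounding and sum to 100", {
  mk <- function(n_by_cat) {
    tibble::tibble(
      peak_id = sprintf("p%d", seq_len(sum(n_by_cat))),
      gene_id = "g",
      tss_distance = 0,
      category = rep(names(n_by_cat), n_by_cat)
    )
  }
  # a 48/18/15/5/13/1 split of 100 peaks reports those percentages exactly
  # (published pies of this shape round each slice independently, which can
  # sum to 101; largest-remainder keeps the total at exactly 100)
  a <- mk(c(upstream = 48, overlap_start = 18, inside = 15,
            overlap_end = 5, downstream = 13, encompass = 1))
  p <- position_proportions(a)
  expect_equal(p$percent[match(c("upstream", "overlap_start", "inside",
                                 "overlap_end", "downstream", "encompass"),
                               p$category)],
               c(48, 18, 15, 5, 13, 1))
  expect_equal(sum(p$percent), 100)
  # the published-style 48/18/15/5/14/1 counts (101 peaks) come back within
  # one point of the independently rounded slices, summing to 100
  a2 <- mk(c(upstream = 48, overlap_start = 18, inside = 15,
             overlap_end = 5, downstream = 14, encompass = 1))
  p2 <- position_proportions(a2)
  expect_equal(sum(p2$percent), 100)
  expect_true(all(abs(p2$percent[match(c("upstream", "overlap_start", "inside",
                                         "overlap_end", "downstream",
                                         "encompass"), p2$category)] -
                        c(48, 18, 15, 5, 14, 1)) <= 1))
  # all upstream -> 100/0; equal categories still sum to exactly 100
  p2 <- position_proportions(mk(c(upstream = 7)))
  expect_equal(p2$percent[p2$category == "upstream"], 100)
  expect_equal(sum(p2$percent), 100)
  p3 <- position_proportions(mk(stats::setNames(rep(1, 6),
                                                levels(p$category))), digits = 2)
  expect_equal(sum(p3$percent), 100)
  expect_true(all(abs(p3$percent - 100 / 6) <= 0.01))
  expect_error(position_proportions(a[0, ]), "no assigned")
})

test_that("random category splits always sum to 100 after rounding", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:500, 6, replace = TRUE)
    expect_equal(sum(largest_remainder_percent(n)), 100)
    expect_equal(sum(largest_remainder_percent(n, digits = 1)), 100)
  }
})

test_that("TSS-distance histogram bins signed distances", {
  a <- tibble::tibble(peak_id = c("p1", "p2", "p3"), gene_id = "g",
                      tss_distance = c(-700, -100, 900),
                      category = "upstream")
  h <- tss_distance_histogram(a, bin_width = 500)
  expect_equal(sum(h$n), 3)
  expect_equal(h$n[h$bin_start == -1000], 1)
  expect_equal(h$n[h$bin_start == -500], 1)
  expect_equal(h$n[h$bin_start == 500], 1)
})

test_that("gene models survive a GFF3 round-trip", {
  genes <- gene_models(tibble::tibble(
    gene_id = c("GENE0001", "GENE0002"), chrom = c("chr1", "chr2"),
    start = c(100L, 40L), end = c(400L, 90L), strand = c("+", "-")
  ))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(genes, f)
  back <- read_gff_genes(f)
  expect_equal(back[order(back$gene_id), names(genes)],
               genes[order(genes$gene_id), ])
})
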