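#' Synthetic study-shaped result tables
#'
#' Builds gene-level DE and peak-assignment tables whose structure matches
#' a published inducible-factor study: 1195 unique DE genes over three
#' timepoints (324 at 2 h, 746 at 4 h, 609 at 8 h; 106 at all three),
#' 523 up / 672 down unique genes (836 up / 843 down gene-by-timepoint
#' records), logFC extrema 3.15 and -1.80, and 1113 binding peaks
#' annotated to 1081 unique genes of which 200 are differentially
#' expressed (154 up, 46 down).
#'
#' The tables are SYNTHETIC stand-ins: published work of this shape only
#' reports the marginal counts above, so the Venn cells that are not
#' publicly printed (pairwise-only intersections, and the direction split
#' within each cell) are fixed here to one deterministic configuration
#' consistent with every published marginal. The builder exists to
#' exercise the set-arithmetic summaries ([summarize_de()],
#' [intersect_de_bound()]) on study-scale inputs; it uses no randomness.
#'
#' @return list with `de_results` (gene, timepoint, logFC, p_value,
#'   q_value, significant), `assignments` (peak_id, gene_id, tss_distance,
#'   category) and `expected`, a list of the marginal counts the tables
#'   were built to satisfy.
#' @export
synthetic_study_tables <- function() {
  # exclusive Venn cells (2h/4h/8h): singles, pairs, triple
  cells <- list(
    `2` = 68, `4` = 418, `8` = 331,
    `2&4` = 100, `2&8` = 50, `4&8` = 122,
    `2&4&8` = 106
  )
  # up-regulated genes per cell; remainder of each cell is down-regulated
  up <- c(`2` = 40, `4` = 150, `8` = 100,
          `2&4` = 56, `2&8` = 28, `4&8` = 69, `2&4&8` = 80)
  tps <- list(`2` = 2, `4` = 4, `8` = 8,
              `2&4` = c(2, 4), `2&8` = c(2, 8), `4&8` = c(4, 8),
              `2&4&8` = c(2, 4, 8))
  gene_no <- 0
  rows <- list()
  directions <- character()
  for (cell in names(cells)) {
    n <- cells[[cell]]
    for (i in seq_len(n)) {
      gene_no <- gene_no + 1
      g <- sprintf("DE%04d", gene_no)
      sgn <- if (i <= up[[cell]]) 1 else -1
      directions[g] <- if (sgn > 0) "up" else "down"
      rows[[g]] <- tibble::tibble(gene = g, timepoint = tps[[cell]],
                                  logFC = sgn * 0.5)
    }
  }
  de <- dplyr::bind_rows(rows)
  # plant the published extrema on single-timepoint genes
  up1 <- names(directions)[directions == "up"][1]
  down1 <- names(directions)[directions == "down"][1]
  de$logFC[de$gene == up1][1] <- 3.15
  de$logFC[de$gene == down1][1] <- -1.80
  de$p_value <- 0.005
  de$q_value <- 0.01
  de$significant <- TRUE
  # bound genes: 154 up + 46 down DE genes, plus 881 non-DE genes
  up_genes <- names(directions)[directions == "up"]
  down_genes <- names(directions)[directions == "down"]
  bound <- c(up_genes[seq_len(154)], down_genes[seq_len(46)],
             sprintf("BG%04d", seq_len(881)))
  # 1113 peaks on 1081 genes: one each, plus a second peak on the first 32
  peak_genes <- c(bound, bound[seq_len(32)])
  categories <- rep(c("upstream", "overlap_start", "inside", "overlap_end",
                      "downstream", "encompass"),
                    times = c(534, 200, 167, 56, 145, 11))
  assignments <- tibble::tibble(
    peak_id = sprintf("peak_%04d", seq_along(peak_genes)),
    gene_id = peak_genes,
    tss_distance = rep_len(c(-1200, -300, 150, 800, 2500, -50),
                           length(peak_genes)),
    category = categories
  )
  list(
    de_results = de,
    assignments = assignments,
    expected = list(
      n_unique_de = 1195, per_timepoint = c(`2` = 324, `4` = 746, `8` = 609),
      triple_cell = 106, genes_up = 523, genes_down = 672,
      records_up = 836, records_down = 843,
      logfc_max = 3.15, logfc_min = -1.80,
      n_bound_genes = 1081, n_peaks = 1113,
      n_intersection = 200, intersection_up = 154, intersection_down = 46
    )
  )
}
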