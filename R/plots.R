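#' Plot helpers
#'
#' Lightweight ggplot2 views of the main result types. Each returns a
#' ggplot object the caller can theme further.
#'
#' @name plots
NULL

#' Coverage or difference track over a region
#'
#' @param track coverage track tibble.
#' @param chrom chromosome to show.
#' @param xlim optional length-2 bp window.
#' @return a ggplot.
#' @export
plot_coverage <- function(track, chrom, xlim = NULL) {
  d <- track[track$chrom == chrom, ]
  if (!is.null(xlim)) d <- d[d$pos >= xlim[1] & d$pos < xlim[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "depth (reads/base)")
}

#' Positional category proportions as a bar chart
#'
#' @param proportions tibble from [position_proportions()].
#' @return a ggplot.
#' @export
plot_peak_positions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "peaks (%)")
}

#' Histogram of signed peak-to-TSS distances
#'
#' @param histogram tibble from [tss_distance_histogram()].
#' @return a ggplot.
#' @export
plot_tss_distances <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey30", width = histogram$bin_end[1] -
                        histogram$bin_start[1]) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "distance to TSS (bp)", y = "peaks")
}

#' Per-timepoint DE counts
#'
#' @param de_summary a `de_summary` from [summarize_de()].
#' @return a ggplot.
#' @export
plot_de_counts <- function(de_summary) {
  d <- de_summary$per_timepoint
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$timepoint), y = .data$n_de)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "timepoint (h)", y = "DE genes")
}

#' Volcano plot of one timepoint's DE results
#'
#' @param de tibble from [run_de()].
#' @param timepoint which timepoint to show (default: first).
#' @return a ggplot.
#' @export
plot_volcano <- function(de, timepoint = de$timepoint[1]) {
  d <- de[de$timepoint == timepoint, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logFC,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (dex/mock)",
                  y = "-log10 p", colour = "significant")
}

#' Jaccard heat map for pairwise gene-set overlaps
#'
#' @param pairwise tibble from [pairwise_overlap()].
#' @return a ggplot.
#' @export
plot_overlap_heatmap <- function(pairwise) {
  full <- dplyr::bind_rows(
    pairwise,
    dplyr::rename(pairwise[pairwise$set_a != pairwise$set_b, ],
                  set_a = "set_b", set_b = "set_a")
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$set_a, y = .data$set_b,
                                     fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$jaccard_rounded), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard")
}
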