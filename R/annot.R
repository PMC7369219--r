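#' Peak-to-gene annotation
#'
#' Each peak is assigned to the gene with the closest transcription start
#' site (TSS) on its chromosome, and its position relative to that gene is
#' classified into one of six mutually exclusive categories:
#' `upstream`, `overlap_start`, `inside`, `overlap_end`, `downstream` and
#' `encompass`. Coordinates are handled internally as 0-based half-open;
#' GFF3 input (1-based inclusive) is converted at the parser boundary.
#'
#' @name annot
NULL

position_categories <- c("upstream", "overlap_start", "inside",
                         "overlap_end", "downstream", "encompass")

#' Read gene models from a GFF3 file
#'
#' Keeps features of type `gene` and converts coordinates to 0-based
#' half-open. The TSS is the start-side base on `+` genes and the end-side
#' base on `-` genes; the TES is the opposite side.
#'
#' @param path GFF3 file.
#' @return tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss`, `tes` (0-based base positions).
#' @export
read_gff_genes <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), tss = integer(), tes = integer()))
  }
  id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
  gene_models(tibble::tibble(
    gene_id = id,
    chrom = as.character(g$seqid),
    start = as.integer(g$start) - 1L,   # to 0-based half-open
    end = as.integer(g$end),
    strand = as.character(g$strand)
  ))
}

#' Derive TSS/TES columns for a gene table
#'
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` in `{+,-}`.
#' @return the same tibble with `tss` and `tes` base positions added.
#' @export
gene_models <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$start >= genes$end)) stop("gene start must be < end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  dplyr::mutate(
    tibble::as_tibble(genes),
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
  )
}

#' Write gene models as GFF3
#'
#' @param genes gene tibble (0-based half-open, as from [gene_models()]).
#' @param path output path.
#' @param source source field for column 2 (default "florabind").
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path, source = "florabind") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id
  )
  GenomicRanges::mcols(gr)$source <- source
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Classify a peak's position relative to a gene
#'
#' Categories follow the precedence encompass > overlap_start > overlap_end
#' > inside > upstream > downstream: `encompass` means the peak contains the
#' whole gene body; `overlap_start`/`overlap_end` mean the peak covers the
#' TSS/TES base; `inside` means the peak lies within the gene body;
#' `upstream`/`downstream` mean the peak lies entirely 5'/3' of the gene in
#' gene orientation.
#'
#' @param peak_start,peak_end 0-based half-open peak interval (vectorized).
#' @param gene_start,gene_end,strand matching gene geometry (0-based
#'   half-open, strand `+`/`-`).
#' @return character vector of categories.
#' @export
classify_position <- function(peak_start, peak_end, gene_start, gene_end, strand) {
  n <- max(length(peak_start), length(gene_start))
  ps <- rep_len(peak_start, n); pe <- rep_len(peak_end, n)
  gs <- rep_len(gene_start, n); ge <- rep_len(gene_end, n)
  st <- rep_len(strand, n)
  if (any(ps >= pe) || any(gs >= ge)) stop("intervals must have start < end", call. = FALSE)
  tss <- ifelse(st == "+", gs, ge - 1L)
  tes <- ifelse(st == "+", ge - 1L, gs)
  covers <- function(base) ps <= base & base < pe
  out <- rep(NA_character_, n)
  encompass <- ps <= gs & pe >= ge
  o_start <- covers(tss)
  o_end <- covers(tes)
  inside <- ps >= gs & pe <= ge
  upstream <- ifelse(st == "+", pe <= gs, ps >= ge)
  downstream <- ifelse(st == "+", ps >= ge, pe <= gs)
  out[downstream] <- "downstream"
  out[upstream] <- "upstream"
  out[inside] <- "inside"
  out[o_end] <- "overlap_end"
  out[o_start] <- "overlap_start"
  out[encompass] <- "encompass"
  if (anyNA(out)) stop("unclassifiable peak/gene geometry", call. = FALSE)
  out
}

#' Assign each peak to the gene with the closest TSS
#'
#' The distance anchor is the peak midpoint `(start + end) / 2`. Ties are
#' broken by the lexicographically smallest gene id. The signed distance is
#' reported in gene orientation: negative means the anchor lies 5' of the
#' TSS. Peaks on chromosomes with no genes are flagged unassigned
#' (`gene_id = NA`).
#'
#' @param peaks peak tibble (`peak_id`, `chrom`, `start`, `end`).
#' @param genes gene tibble from [gene_models()] or [read_gff_genes()].
#' @param anchor `"midpoint"` (default) or `"edge"` (distance from the
#'   nearest peak edge to the TSS).
#' @param max_distance optional cap; assignments farther than this are
#'   flagged unassigned (default `Inf`, every peak gets a gene).
#' @return tibble: `peak_id`, `gene_id`, `tss_distance` (signed bp),
#'   `category`.
#' @export
annotate_peaks <- function(peaks, genes, anchor = c("midpoint", "edge"),
                           max_distance = Inf) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)))
  if (!"tss" %in% names(genes)) genes <- gene_models(genes)
  purrr::pmap_dfr(
    peaks[, c("peak_id", "chrom", "start", "end")],
    function(peak_id, chrom, start, end) {
      g <- genes[genes$chrom == chrom, ]
      if (nrow(g) == 0) {
        return(tibble::tibble(peak_id = peak_id, gene_id = NA_character_,
                              tss_distance = NA_real_, category = NA_character_))
      }
      mid <- (start + end) / 2
      d <- if (anchor == "midpoint") {
        abs(mid - g$tss)
      } else {
        pmax(0, pmax(g$tss - (end - 1L), start - g$tss))
      }
      best <- which(d == min(d))
      if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
      if (d[best] > max_distance) {
        return(tibble::tibble(peak_id = peak_id, gene_id = NA_character_,
                              tss_distance = NA_real_, category = NA_character_))
      }
      signed <- ifelse(g$strand[best] == "+", mid - g$tss[best], g$tss[best] - mid)
      tibble::tibble(
        peak_id = peak_id,
        gene_id = g$gene_id[best],
        tss_distance = signed,
        category = classify_position(start, end, g$start[best], g$end[best],
                                     g$strand[best])
      )
    }
  )
}

#' Positional category proportions
#'
#' Percentages are computed with the largest-remainder method at the given
#' number of decimal places, so they always sum to exactly 100.
#'
#' @param assignments tibble from [annotate_peaks()]; unassigned peaks are
#'   dropped with a message.
#' @param digits decimal places for the reported percentages (default 0).
#' @return tibble: `category`, `n`, `percent`, covering all six categories.
#' @export
position_proportions <- function(assignments, digits = 0) {
  assignments <- drop_unassigned(assignments)
  if (nrow(assignments) == 0) stop("no assigned peaks to summarize", call. = FALSE)
  counts <- table(factor(assignments$category, levels = position_categories))
  n <- as.integer(counts)
  tibble::tibble(
    category = factor(position_categories, levels = position_categories),
    n = n,
    percent = largest_remainder_percent(n, digits = digits)
  )
}

#' Largest-remainder rounding of proportions to percentages
#'
#' @param n non-negative counts.
#' @param digits decimal places.
#' @return numeric vector summing to exactly 100.
#' @export
largest_remainder_percent <- function(n, digits = 0) {
  stopifnot(all(n >= 0), sum(n) > 0)
  unit <- 10^digits
  exact <- n / sum(n) * 100 * unit
  fl <- floor(exact + 1e-9)    # guard against 48.0 landing at 47.999...
  rem <- round(100 * unit - sum(fl))
  add <- integer(length(n))
  if (rem > 0) {
    add[order(exact - fl, decreasing = TRUE)[seq_len(rem)]] <- 1L
  }
  (fl + add) / unit
}

#' TSS-distance histogram
#'
#' @param assignments tibble from [annotate_peaks()].
#' @param bin_width histogram bin width in bp (default 500).
#' @return tibble: `bin_start`, `bin_end`, `n` (bins aligned on multiples of
#'   `bin_width`, empty bins inside the observed range included).
#' @export
tss_distance_histogram <- function(assignments, bin_width = 500) {
  assignments <- drop_unassigned(assignments)
  if (nrow(assignments) == 0) stop("no assigned peaks to summarize", call. = FALSE)
  b <- floor(assignments$tss_distance / bin_width)
  rng <- seq(min(b), max(b))
  cnt <- table(factor(b, levels = rng))
  tibble::tibble(bin_start = rng * bin_width,
                 bin_end = (rng + 1) * bin_width,
                 n = as.integer(cnt))
}

drop_unassigned <- function(assignments) {
  un <- is.na(assignments$gene_id)
  if (any(un)) message(sum(un), " unassigned peak(s) dropped")
  assignments[!un, , drop = FALSE]
}
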