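#' Coverage tracks and threshold peak calling
#'
#' A coverage track is a tibble with columns `chrom` (character), `pos`
#' (0-based base position, integer) and `depth` (non-negative numeric),
#' dense over `[0, chrom_length)` for every chromosome it contains.
#' Peak calling operates on a *difference* track: the per-base subtraction
#' of an untagged control from a tagged ChIP sample, with negative values
#' clamped to zero, thresholded at a fixed depth `T`.
#'
#' @name coverage
NULL

track_cols <- c("chrom", "pos", "depth")

assert_track <- function(track, arg = "track") {
  if (!is.data.frame(track) || !all(track_cols %in% names(track))) {
    stop("`", arg, "` must be a tibble with columns chrom, pos, depth", call. = FALSE)
  }
  if (any(track$depth < 0 & !is.na(track$depth))) {
    # difference tracks may hold negatives before clamping; raw coverage may not
    invisible(track)
  }
  invisible(track)
}

#' Build a dense coverage track from per-chromosome depth vectors
#'
#' @param depths named list of numeric vectors, one per chromosome; element
#'   `i` of a vector is the depth at 0-based position `i - 1`.
#' @return a coverage track tibble (`chrom`, `pos`, `depth`).
#' @export
coverage_track <- function(depths) {
  stopifnot(is.list(depths), !is.null(names(depths)))
  purrr::imap_dfr(depths, function(v, chrom) {
    tibble::tibble(chrom = chrom, pos = seq_along(v) - 1L, depth = as.numeric(v))
  })
}

#' Extract per-chromosome depth vectors from a track
#'
#' Inverse of [coverage_track()]; positions must be dense from 0.
#' @param track a coverage track tibble.
#' @return named list of numeric depth vectors.
#' @export
track_depths <- function(track) {
  assert_track(track)
  track <- dplyr::arrange(track, .data$chrom, .data$pos)
  sp <- split(track, track$chrom)
  purrr::map(sp, function(d) {
    if (!identical(as.integer(d$pos), seq_len(nrow(d)) - 1L)) {
      stop("track is not dense from position 0 on chromosome ", d$chrom[1], call. = FALSE)
    }
    d$depth
  })
}

#' Read a bedGraph file into a dense coverage track
#'
#' bedGraph intervals are 0-based half-open. Positions not covered by any
#' interval get depth 0. Overlapping intervals, negative depths and
#' malformed lines are reported as errors with the offending line number.
#'
#' @param path path to a bedGraph file (plain text, no track lines required;
#'   `track` and `#` header lines are skipped).
#' @param seqlengths optional named vector of chromosome lengths used to pad
#'   the dense representation; defaults to the largest end seen per
#'   chromosome.
#' @return a coverage track tibble.
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(), depth = numeric()))
  }
  fields <- strsplit(lines[idx], "\t| +")
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop("malformed bedGraph line ", idx[bad[1]], ": expected 4 fields", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  depth <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(depth) | start < 0 | end <= start)
  if (length(bad)) {
    stop("malformed bedGraph line ", idx[bad[1]], ": bad coordinates or value", call. = FALSE)
  }
  bad <- which(depth < 0)
  if (length(bad)) {
    stop("negative coverage value at bedGraph line ", idx[bad[1]], call. = FALSE)
  }
  df <- tibble::tibble(chrom = m[, 1], start = start, end = end,
                       depth = depth, line = idx)
  # overlap check per chromosome
  for (d in split(df, df$chrom)) {
    d <- d[order(d$start), ]
    ov <- which(d$start[-1] < d$end[-nrow(d)])
    if (length(ov)) {
      stop("overlapping bedGraph intervals at line ", d$line[ov[1] + 1], call. = FALSE)
    }
  }
  chroms <- unique(df$chrom)
  lens <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]), integer(1))
  if (!is.null(seqlengths)) {
    for (ch in intersect(names(seqlengths), chroms)) {
      lens[ch] <- max(lens[ch], as.integer(seqlengths[ch]))
    }
    for (ch in setdiff(names(seqlengths), chroms)) {
      lens[ch] <- as.integer(seqlengths[ch])
      chroms <- c(chroms, ch)
    }
  }
  depths <- lapply(chroms, function(ch) {
    v <- numeric(lens[ch])
    d <- df[df$chrom == ch, ]
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1):d$end[i]] <- d$depth[i]
    v
  })
  names(depths) <- chroms
  coverage_track(depths)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are collapsed into intervals; zero-depth runs are
#' omitted (bedGraph semantics: unspecified means 0).
#'
#' @param track coverage track tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  depths <- track_depths(track)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(depths)) {
    r <- rle(depths[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         format(r$values[keep], trim = TRUE, scientific = FALSE)), con)
    }
  }
  invisible(path)
}

#' Sum replicate coverage tracks
#'
#' Replicates are combined by per-base summation, mirroring the pooling of
#' reads from biological replicates before peak calling.
#'
#' @param tracks list of coverage track tibbles with identical chromosome
#'   sets and lengths.
#' @return one coverage track tibble.
#' @export
combine_replicates <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  ds <- lapply(tracks, track_depths)
  ref <- ds[[1]]
  for (d in ds[-1]) {
    if (!setequal(names(d), names(ref)) ||
        !all(lengths(d)[names(ref)] == lengths(ref))) {
      stop("replicate tracks have mismatched chromosomes or lengths", call. = FALSE)
    }
  }
  out <- ref
  for (d in ds[-1]) for (ch in names(out)) out[[ch]] <- out[[ch]] + d[[ch]]
  coverage_track(out)
}

#' Tagged-minus-untagged difference track
#'
#' Computes `tagged - s * untagged` per base. By default `s = 1`; with
#' `scale_untagged = TRUE`, `s` is the ratio of total tagged depth to total
#' untagged depth, so globally proportional tracks cancel exactly.
#' Negative values are clamped to 0 when `clamp_negative` (the default),
#' since peaks are defined on excess tagged signal only.
#'
#' @param tagged,untagged coverage track tibbles over the same chromosomes.
#' @param clamp_negative clamp negative differences to zero (default TRUE).
#' @param scale_untagged depth-normalize the untagged track first
#'   (default FALSE; the published procedure mentions no normalization).
#' @return a difference track tibble (`chrom`, `pos`, `depth`).
#' @export
difference_track <- function(tagged, untagged, clamp_negative = TRUE,
                             scale_untagged = FALSE) {
  dt <- track_depths(tagged)
  du <- track_depths(untagged)
  if (!setequal(names(dt), names(du)) || !all(lengths(du)[names(dt)] == lengths(dt))) {
    stop("tagged and untagged tracks have mismatched chromosomes or lengths", call. = FALSE)
  }
  s <- 1
  if (scale_untagged) {
    tot_u <- sum(unlist(du))
    if (tot_u == 0) stop("cannot scale: untagged track has zero total depth", call. = FALSE)
    s <- sum(unlist(dt)) / tot_u
  }
  out <- lapply(names(dt), function(ch) {
    v <- dt[[ch]] - s * du[[ch]]
    if (clamp_negative) v[v < 0] <- 0
    v
  })
  names(out) <- names(dt)
  coverage_track(out)
}

#' Call peaks by thresholding a difference track
#'
#' A peak is a maximal run of positions with depth `>= threshold`. Runs
#' separated by fewer than `merge_gap` sub-threshold bases are merged, and
#' (after merging) runs narrower than `min_width` are discarded. `area` is
#' the summed depth over the peak interval and `max_height` its maximum.
#'
#' @param diff difference track tibble.
#' @param threshold calling threshold `T` in reads/base; must be positive.
#' @param min_width minimum peak width in bp (default 1).
#' @param merge_gap merge runs separated by fewer than this many
#'   sub-threshold bases (default 0 = never merge).
#' @return tibble of peaks: `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `max_height`, `area`, sorted by (chrom, start).
#' @export
call_peaks <- function(diff, threshold, min_width = 1L, merge_gap = 0L) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  stopifnot(min_width >= 1, merge_gap >= 0)
  depths <- track_depths(diff)
  rows <- purrr::imap_dfr(depths, function(v, ch) {
    above <- v >= threshold
    if (!any(above)) return(tibble::tibble())
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths      # 0-based starts
    ps <- starts[r$values]
    pe <- ends[r$values]
    # merge runs separated by < merge_gap below-threshold bases
    if (merge_gap > 0 && length(ps) > 1) {
      keep_start <- c(TRUE, (ps[-1] - pe[-length(pe)]) >= merge_gap)
      grp <- cumsum(keep_start)
      ps <- tapply(ps, grp, min)
      pe <- tapply(pe, grp, max)
    }
    w <- pe - ps
    ok <- w >= min_width
    ps <- ps[ok]; pe <- pe[ok]
    if (!length(ps)) return(tibble::tibble())
    tibble::tibble(
      chrom = ch, start = as.integer(ps), end = as.integer(pe),
      max_height = vapply(seq_along(ps), function(i) max(v[(ps[i] + 1):pe[i]]), numeric(1)),
      area = vapply(seq_along(ps), function(i) sum(v[(ps[i] + 1):pe[i]]), numeric(1))
    )
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(peak_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          max_height = numeric(), area = numeric()))
  }
  rows <- dplyr::arrange(rows, .data$chrom, .data$start)
  dplyr::mutate(rows, peak_id = sprintf("peak_%04d", dplyr::row_number()),
                .before = 1)
}

#' Write peaks as BED6
#'
#' Columns: chrom, start, end, name (peak id), score (rounded max height),
#' strand (`.`). Round-trip safe with [read_peaks_bed()].
#'
#' @param peaks peak tibble from [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", peaks$chrom, peaks$start,
                   peaks$end, peaks$peak_id, round(peaks$max_height))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 peak file
#'
#' @param path BED file written by [write_peaks_bed()] (or any BED with at
#'   least chrom/start/end; missing names/scores are filled in).
#' @return peak tibble (`peak_id`, `chrom`, `start`, `end`, `max_height`).
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(tibble::tibble(peak_id = character(), chrom = character(),
                          start = integer(), end = integer(), max_height = numeric()))
  }
  fields <- strsplit(lines, "\t")
  n <- lengths(fields)
  if (any(n < 3)) stop("malformed BED line ", which(n < 3)[1], call. = FALSE)
  tibble::tibble(
    peak_id = vapply(seq_along(fields), function(i)
      if (n[i] >= 4) fields[[i]][4] else sprintf("peak_%04d", i), character(1)),
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    max_height = vapply(seq_along(fields), function(i)
      if (n[i] >= 5) as.numeric(fields[[i]][5]) else NA_real_, numeric(1))
  )
}
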