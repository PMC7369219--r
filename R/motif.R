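#' PWM scanning with exact p-values and a randomized-peak null
#'
#' A position weight matrix (PWM) holds per-position nucleotide
#' probabilities. Sites are scored by the log-odds (in bits) of the window
#' under the motif versus a 0-order background; a site's p-value is the
#' exact probability that a background-drawn word of the same width scores
#' at least as high, computed by dynamic programming over a discretized
#' score lattice. The enrichment of motif sites in observed peaks is judged
#' against size-matched intervals placed uniformly at random on the genome.
#'
#' @name motif
NULL

dna_letters <- c("A", "C", "G", "T")

#' Construct a PWM object
#'
#' @param mat numeric matrix, width x 4 (columns A, C, G, T), rows summing
#'   to 1 (renormalized if close).
#' @param bg background nucleotide frequencies (length 4, sums to 1;
#'   default uniform).
#' @param name motif name.
#' @param pseudocount pseudocount mixed into the probabilities at log-odds
#'   time: `p' = (p + pc * bg) / (1 + pc)` (default 0.1).
#' @return object of class `pwm`.
#' @export
pwm <- function(mat, bg = rep(0.25, 4), name = "motif", pseudocount = 0.1) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)", call. = FALSE)
  if (any(mat < 0) || any(bg < 0)) stop("probabilities must be non-negative", call. = FALSE)
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 0.01)) stop("PWM rows must sum to 1", call. = FALSE)
  mat <- mat / rs
  if (abs(sum(bg) - 1) > 0.01) stop("background must sum to 1", call. = FALSE)
  bg <- bg / sum(bg)
  if (any(bg == 0) && pseudocount <= 0) {
    stop("zero background frequency requires a positive pseudocount", call. = FALSE)
  }
  colnames(mat) <- dna_letters
  names(bg) <- dna_letters
  structure(list(mat = mat, bg = bg, name = name, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- width", nrow(x$mat), "- consensus",
      pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param x a `pwm`.
#' @return character scalar, the most probable letter at each position.
#' @export
pwm_consensus <- function(x) {
  paste(dna_letters[apply(x$mat, 1, which.max)], collapse = "")
}

# strictly positive backgrounds are used as-is; zero frequencies get the
# pseudocount mixed in so log-odds and the DP stay finite
pwm_bg <- function(x) {
  if (all(x$bg > 0)) return(x$bg)
  (x$bg + x$pseudocount / 4) / (1 + x$pseudocount)
}

#' Log-odds score matrix in bits
#'
#' @param x a `pwm`.
#' @return width x 4 matrix of `log2(p'/bg')` with the pseudocount applied
#'   to both motif probabilities and background.
#' @export
pwm_log_odds <- function(x) {
  bg <- pwm_bg(x)
  p <- (x$mat + x$pseudocount * matrix(bg, nrow(x$mat), 4, byrow = TRUE)) /
    (1 + x$pseudocount)
  lo <- log2(sweep(p, 2, bg, "/"))
  colnames(lo) <- dna_letters
  lo
}

#' Read a motif in MEME minimal format
#'
#' Parses the first (or named) motif from a MEME minimal-format file:
#' `MEME version`, optional `ALPHABET`/`strands`/`Background letter
#' frequencies` blocks, then `MOTIF <name>` and a
#' `letter-probability matrix` block.
#'
#' @param path MEME motif file.
#' @param pseudocount pseudocount stored on the returned PWM (default 0.1).
#' @return a `pwm`; background from the file, or uniform if absent.
#' @export
read_meme_pwm <- function(path, pseudocount = 0.1) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(lines[bg_i[1] + 1], "\\s+")[[1]]
    if (length(toks) < 8) stop("malformed background line in MEME file", call. = FALSE)
    vals <- as.numeric(toks[seq(2, 8, by = 2)])
    names(vals) <- toks[seq(1, 7, by = 2)]
    bg <- unname(vals[dna_letters])
  }
  mi <- grep("^MOTIF\\b", lines)
  if (!length(mi)) stop("no MOTIF block in MEME file", call. = FALSE)
  name <- sub("^MOTIF\\s+", "", lines[mi[1]])
  name <- strsplit(name, "\\s+")[[1]][1]
  hi <- grep("^letter-probability matrix", lines)
  hi <- hi[hi > mi[1]][1]
  if (is.na(hi)) stop("no letter-probability matrix in MEME file", call. = FALSE)
  w <- if (grepl("w= *[0-9]+", lines[hi])) {
    as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hi]))
  } else NA_integer_
  rows <- list()
  i <- hi + 1
  while (i <= length(lines) && nzchar(lines[i]) &&
         grepl("^[-+0-9.eE[:space:]]+$", lines[i])) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (length(vals) != 4 || anyNA(vals)) {
      stop("malformed matrix row at line ", i, " of MEME file", call. = FALSE)
    }
    rows[[length(rows) + 1]] <- vals
    i <- i + 1
  }
  if (!length(rows)) stop("no matrix rows in MEME file", call. = FALSE)
  mat <- do.call(rbind, rows)
  if (!is.na(w) && nrow(mat) != w) {
    stop("MEME matrix has ", nrow(mat), " rows but header says w=", w, call. = FALSE)
  }
  if (any(abs(rowSums(mat) - 1) > 0.01)) {
    stop("MEME matrix rows do not sum to 1", call. = FALSE)
  }
  pwm(mat, bg = bg, name = name, pseudocount = pseudocount)
}

#' Write a PWM in MEME minimal format
#'
#' @param x a `pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f",
            x$bg[1], x$bg[2], x$bg[3], x$bg[4]), "",
    sprintf("MOTIF %s", x$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            nrow(x$mat))
  ), con)
  writeLines(apply(x$mat, 1, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                                 r[1], r[2], r[3], r[4])), con)
  invisible(path)
}

#' Exact score distribution of a PWM under the background
#'
#' Discretizes the per-position log-odds scores to a lattice of step
#' `granularity` bits and convolves the per-position distributions under
#' the background model. The result maps any window score to
#' `p = P_bg(score >= s)`.
#'
#' @param x a `pwm`.
#' @param granularity lattice step in bits (default 1/1000).
#' @return object of class `pwm_score_dist` with the lattice probabilities
#'   and the survival function.
#' @export
score_distribution <- function(x, granularity = 0.001) {
  stopifnot(inherits(x, "pwm"), granularity > 0)
  lo <- pwm_log_odds(x)
  bg <- pwm_bg(x)
  q <- round(lo / granularity)         # integer lattice scores per position
  # DP: start with point mass at 0 before any position
  cur <- c(1)
  cur_min <- 0L
  for (i in seq_len(nrow(q))) {
    qmin <- min(q[i, ]); qmax <- max(q[i, ])
    new_min <- cur_min + qmin
    new <- numeric(length(cur) + qmax - qmin)
    for (b in 1:4) {
      shift <- q[i, b] - qmin
      idx <- seq_along(cur) + shift
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_min <- new_min
  }
  surv <- rev(cumsum(rev(cur)))
  surv <- pmin(surv, 1)
  structure(list(min_score = cur_min, probs = cur, survival = surv,
                 granularity = granularity, width = nrow(x$mat)),
            class = "pwm_score_dist")
}

#' Exact p-value for a motif score
#'
#' @param dist a `pwm_score_dist` from [score_distribution()].
#' @param score window score(s) in bits.
#' @return `P_bg(score >= s)` per input score, on the distribution's
#'   lattice.
#' @export
motif_score_pvalue <- function(dist, score) {
  idx <- round(score / dist$granularity) - dist$min_score + 1
  idx <- pmin(pmax(idx, 1), length(dist$survival) + 1)
  out <- numeric(length(idx))
  inside <- idx <= length(dist$survival)
  out[inside] <- dist$survival[idx[inside]]
  out[!inside] <- 0
  out
}

#' Smallest score with p-value at or below a threshold
#'
#' @param dist a `pwm_score_dist`.
#' @param p_threshold p-value cutoff.
#' @return score in bits (lattice value); `Inf` if unattainable.
#' @export
score_at_pvalue <- function(dist, p_threshold) {
  i <- which(dist$survival <= p_threshold)
  if (!length(i)) return(Inf)
  (dist$min_score + i[1] - 1) * dist$granularity
}

encode_dna <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  match(v, dna_letters)     # N and others become NA
}

revcomp <- function(s) {
  chartr("ACGTacgtNn", "TGCAtgcaNn",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Scan sequences for PWM hits on both strands
#'
#' Windows containing non-ACGT letters are skipped. Reverse-strand hits are
#' reported on the forward coordinate axis (`start` is the leftmost base of
#' the window, 0-based). Scanning is case-insensitive. A window is a hit
#' when its exact p-value is at or below `p_threshold`.
#'
#' @param x a `pwm`.
#' @param sequences named character vector or `Biostrings::DNAStringSet`.
#' @param p_threshold site p-value cutoff (default 0.001).
#' @param bg background model: `"sequence"` (0-order frequencies estimated
#'   from the scanned sequences, the default) or `"uniform"`, or a length-4
#'   numeric vector.
#' @param granularity score-lattice step in bits for the p-value DP.
#' @return tibble of hits: `chrom`, `start`, `end`, `strand`, `score`,
#'   `p_value`.
#' @export
scan_pwm <- function(x, sequences, p_threshold = 0.001, bg = "sequence",
                     granularity = 0.001) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  w <- nrow(x$mat)
  if (is.numeric(bg)) {
    x <- pwm(x$mat, bg = bg, name = x$name, pseudocount = x$pseudocount)
  } else if (identical(bg, "sequence")) {
    counts <- colSums(do.call(rbind, lapply(sequences, function(s) {
      v <- encode_dna(s)
      tabulate(v[!is.na(v)], nbins = 4)
    })))
    if (sum(counts) == 0) stop("no ACGT letters in sequences", call. = FALSE)
    x <- pwm(x$mat, bg = (counts + 1) / (sum(counts) + 4), name = x$name,
             pseudocount = x$pseudocount)
  } else if (!identical(bg, "uniform")) {
    stop("`bg` must be 'sequence', 'uniform' or a length-4 vector", call. = FALSE)
  } else {
    x <- pwm(x$mat, bg = rep(0.25, 4), name = x$name, pseudocount = x$pseudocount)
  }
  # score windows on the same discretized lattice the p-value DP uses, so a
  # window's reported p is exactly the background probability of its score
  lo <- round(pwm_log_odds(x) / granularity) * granularity
  dist <- score_distribution(x, granularity = granularity)
  scan_one <- function(code, L) {
    n_win <- L - w + 1
    if (n_win < 1) return(NULL)
    sc <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      letters_j <- code[j:(j + n_win - 1)]
      na <- is.na(letters_j)
      ok <- ok & !na
      letters_j[na] <- 1L
      sc <- sc + lo[j, letters_j]
    }
    list(score = sc, ok = ok)
  }
  out <- purrr::imap_dfr(sequences, function(s, chrom) {
    L <- nchar(s)
    if (L < w) {
      warning("sequence ", chrom, " shorter than motif width; skipped", call. = FALSE)
      return(tibble::tibble())
    }
    fwd <- scan_one(encode_dna(s), L)
    rev <- scan_one(encode_dna(revcomp(s)), L)
    n_win <- L - w + 1
    hit_rows <- function(scan, strand) {
      p <- motif_score_pvalue(dist, scan$score)
      keep <- scan$ok & p <= p_threshold
      if (!any(keep)) return(tibble::tibble())
      i <- which(keep)            # 1-based window index on scanned strand
      start <- if (strand == "+") i - 1L else L - (i - 1L) - w
      tibble::tibble(chrom = chrom, start = as.integer(start),
                     end = as.integer(start + w), strand = strand,
                     score = scan$score[keep], p_value = p[keep])
    }
    dplyr::bind_rows(hit_rows(fwd, "+"), hit_rows(rev, "-"))
  })
  if (nrow(out)) out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  out
}

#' Size-matched randomized peak placement
#'
#' Each observed peak width is placed uniformly at random on a chromosome
#' chosen with probability proportional to chromosome length (among
#' chromosomes the width fits on); placements are independent and may
#' overlap. Deterministic for a given seed.
#'
#' @param peaks peak tibble with `start`, `end`.
#' @param chrom_lengths tibble with `chrom`, `length`.
#' @param seed integer seed.
#' @return peak tibble (`peak_id`, `chrom`, `start`, `end`) with the same
#'   width multiset as the input.
#' @export
randomize_peaks <- function(peaks, chrom_lengths, seed) {
  widths <- peaks$end - peaks$start
  if (any(widths > max(chrom_lengths$length))) {
    stop("a peak is wider than every chromosome", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(widths)
  chrom <- character(n)
  start <- integer(n)
  for (i in seq_len(n)) {
    fits <- chrom_lengths$length >= widths[i]
    probs <- chrom_lengths$length * fits
    ch <- sample(seq_len(nrow(chrom_lengths)), 1, prob = probs)
    chrom[i] <- chrom_lengths$chrom[ch]
    start[i] <- sample.int(chrom_lengths$length[ch] - widths[i] + 1, 1) - 1L
  }
  tibble::tibble(peak_id = sprintf("null_%04d", seq_len(n)),
                 chrom = chrom, start = start,
                 end = as.integer(start + widths))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fraction of intervals overlapping at least one hit
#'
#' An interval overlaps a hit when they share at least one base on the same
#' chromosome (strand is ignored).
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param hits tibble with `chrom`, `start`, `end`.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(intervals, hits) {
  if (nrow(intervals) == 0) stop("empty interval list", call. = FALSE)
  if (nrow(hits) == 0) return(0)
  ir <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L, intervals$end))
  hr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  mean(IRanges::overlapsAny(ir, hr))
}
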