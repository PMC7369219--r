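# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive results by direct enumeration / per-base scanning, not by the
# package's own algorithms.

# Per-base peak caller: mark bases >= T, fill below-threshold gaps shorter
# than merge_gap between marked runs, then collect runs of width >= min_width.
brute_force_peaks <- function(v, threshold, min_width = 1, merge_gap = 0) {
  mask <- v >= threshold
  if (merge_gap > 0) {
    filled <- mask
    i <- 1
    n <- length(mask)
    while (i <= n) {
      if (!mask[i]) {
        j <- i
        while (j <= n && !mask[j]) j <- j + 1
        gap_len <- j - i
        left <- i > 1 && mask[i - 1]
        right <- j <= n && mask[j]
        if (left && right && gap_len < merge_gap) filled[i:(j - 1)] <- TRUE
        i <- j
      } else {
        i <- i + 1
      }
    }
    mask <- filled
  }
  peaks <- list()
  i <- 1
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j <= n && mask[j]) j <- j + 1
      if (j - i >= min_width) {
        peaks[[length(peaks) + 1]] <-
          c(start = i - 1, end = j - 1,
            max_height = max(v[i:(j - 1)]), area = sum(v[i:(j - 1)]))
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (!length(peaks)) {
    return(data.frame(start = integer(), end = integer(),
                      max_height = numeric(), area = numeric()))
  }
  as.data.frame(do.call(rbind, peaks))
}

# Positional category re-derived from explicit base-membership sets.
classify_oracle <- function(ps, pe, gs, ge, strand) {
  P <- ps:(pe - 1)
  G <- gs:(ge - 1)
  tss <- if (strand == "+") gs else ge - 1
  tes <- if (strand == "+") ge - 1 else gs
  five_of <- function(base) if (strand == "+") all(P < base) else all(P > base)
  three_of <- function(base) if (strand == "+") all(P > base) else all(P < base)
  if (all(G %in% P)) return("encompass")
  if (tss %in% P) return("overlap_start")
  if (tes %in% P) return("overlap_end")
  if (all(P %in% G)) return("inside")
  if (five_of(tss)) return("upstream")
  if (three_of(tes)) return("downstream")
  NA_character_
}

# Exhaustive PWM p-values: enumerate all 4^w words under the background.
enum_pwm_pvalues <- function(x) {
  lo <- florabind::pwm_log_odds(x)
  w <- nrow(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- vapply(seq_len(nrow(words)), function(i) {
    sum(lo[cbind(seq_len(w), words[i, ])])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(words)), function(i) {
    prod(x$bg[words[i, ]])
  }, numeric(1))
  list(scores = scores, probs = probs,
       pval = function(s) sum(probs[scores >= s - 1e-12]))
}

# Hypergeometric upper tail by direct combinatorial enumeration.
hyper_upper_enum <- function(k, n_a, n_b, N) {
  j <- seq(k, min(n_a, n_b))
  if (!length(j)) return(0)
  sum(choose(n_a, j) * choose(N - n_a, n_b - j)) / choose(N, n_b)
}

# Small random genome/gene fixture helpers.
random_track <- function(len, lambda = 4, seed = 1) {
  set.seed(seed)
  florabind::coverage_track(list(chr1 = stats::rpois(len, lambda)))
}

toy_genes <- function(n, chrom = "chr1", spacing = 2000, len = 1500) {
  florabind::gene_models(tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = chrom,
    start = as.integer(seq(0, by = spacing, length.out = n)),
    end = as.integer(seq(0, by = spacing, length.out = n) + len),
    strand = "+"
  ))
}
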