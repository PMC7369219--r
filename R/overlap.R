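#' Gene-set overlap statistics
#'
#' Overlap between two gene lists is quantified by the Jaccard index
#' `|A n B| / |A u B|` and by the hypergeometric upper-tail probability of
#' seeing at least the observed intersection given a universe of `N`
#' annotated genes (the one-sided Fisher exact test). The same
#' hypergeometric machinery powers generic term enrichment (a GO-style
#' analysis against a user-supplied term-to-gene map).
#'
#' @name overlap_stats
NULL

#' Jaccard index of two gene sets
#'
#' Inputs are deduplicated. Defined as 0 when both sets are empty.
#'
#' @param a,b character vectors of gene identifiers.
#' @return `|A n B| / |A u B|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Hypergeometric overlap test between two gene sets
#'
#' `p = P(X >= |A n B|)` for `X ~ Hypergeometric(N, |A|, |B|)` - the
#' one-sided Fisher exact test on the 2x2 membership table. The sample odds
#' ratio is computed from that table with a 0.5 continuity correction when
#' any cell is zero.
#'
#' @param a,b character vectors of gene identifiers.
#' @param universe_size number of genes in the universe `N`
#'   (`N >= |A u B|`).
#' @return one-row tibble: `n_a`, `n_b`, `n_overlap`, `universe`,
#'   `jaccard`, `odds_ratio`, `fisher_p`.
#' @export
fisher_overlap <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  k <- length(intersect(a, b))
  na <- length(a); nb <- length(b)
  if (universe_size < length(union(a, b))) {
    stop("universe smaller than the union of the sets", call. = FALSE)
  }
  p <- stats::phyper(k - 1, na, universe_size - na, nb, lower.tail = FALSE)
  tab <- c(k, na - k, nb - k, universe_size - na - nb + k)
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  tibble::tibble(n_a = na, n_b = nb, n_overlap = k, universe = universe_size,
                 jaccard = jaccard(a, b), odds_ratio = or, fisher_p = p)
}

#' Pairwise overlap statistics for several gene sets
#'
#' @param sets named list of character vectors.
#' @param universe_size universe size `N` for the Fisher tests.
#' @param digits decimals for the `jaccard_rounded` convenience column
#'   (default 1, the convention used when reporting pairwise heat maps).
#' @return tibble with one row per unordered pair (plus the unit diagonal):
#'   `set_a`, `set_b`, the [fisher_overlap()] columns and
#'   `jaccard_rounded`.
#' @export
pairwise_overlap <- function(sets, universe_size, digits = 1) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  nm <- names(sets)
  pairs <- expand.grid(i = seq_along(nm), j = seq_along(nm))
  pairs <- pairs[pairs$i <= pairs$j, ]
  out <- purrr::pmap_dfr(pairs, function(i, j) {
    dplyr::bind_cols(tibble::tibble(set_a = nm[i], set_b = nm[j]),
                     fisher_overlap(sets[[i]], sets[[j]], universe_size))
  })
  dplyr::mutate(out, jaccard_rounded = round(.data$jaccard, digits))
}

#' Jaccard matrix from pairwise overlap results
#'
#' @param pairwise tibble from [pairwise_overlap()].
#' @param value column to spread (default `"jaccard"`).
#' @return symmetric matrix with unit diagonal (for `jaccard`).
#' @export
overlap_matrix <- function(pairwise, value = "jaccard") {
  nm <- unique(c(pairwise$set_a, pairwise$set_b))
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in seq_len(nrow(pairwise))) {
    m[pairwise$set_a[r], pairwise$set_b[r]] <- pairwise[[value]][r]
    m[pairwise$set_b[r], pairwise$set_a[r]] <- pairwise[[value]][r]
  }
  m
}

#' Hypergeometric term enrichment
#'
#' For every term, tests whether the query set is enriched for the term's
#' genes within the universe (hypergeometric upper tail), adjusts across
#' terms by Benjamini-Hochberg and reports fold enrichment
#' (observed / expected overlap).
#'
#' @param query character vector of gene identifiers.
#' @param annotation tibble with columns `term` and `gene`.
#' @param universe character vector of universe gene identifiers; term and
#'   query genes outside it are dropped.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return tibble: `term`, `n_query`, `n_term`, `n_overlap`, `expected`,
#'   `fold_enrichment`, `p_value`, `q_value`, `significant`, sorted by p.
#' @export
term_enrichment <- function(query, annotation, universe, alpha = 0.05) {
  stopifnot(all(c("term", "gene") %in% names(annotation)), nrow(annotation) > 0)
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("query is disjoint from the universe", call. = FALSE)
  N <- length(universe)
  ann <- annotation[annotation$gene %in% universe, ]
  out <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_term = dplyr::n_distinct(.data$gene),
      n_overlap = length(intersect(unique(.data$gene), query)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_query = length(query),
      expected = .data$n_term * .data$n_query / N,
      fold_enrichment = ifelse(.data$expected > 0,
                               .data$n_overlap / .data$expected, NA_real_),
      p_value = stats::phyper(.data$n_overlap - 1, .data$n_term,
                              N - .data$n_term, .data$n_query,
                              lower.tail = FALSE),
      q_value = bh_adjust(.data$p_value),
      significant = .data$q_value < alpha
    ) |>
    dplyr::arrange(.data$p_value)
  dplyr::relocate(out, "term", "n_query", "n_term", "n_overlap")
}

#' Read a gene list from a text file
#'
#' One identifier per line (or the first column of a TSV); duplicates are
#' removed, order preserved.
#'
#' @param path input file.
#' @return character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(vapply(strsplit(lines, "\t"), `[`, character(1), 1))
}
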