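#' Time-course differential expression with batch adjustment
#'
#' Counts are modeled per gene and per timepoint with a negative-binomial
#' log-linear model
#' `log mu = offset(log effective library size) + batch + treatment`,
#' where the effective library size is the raw library size times a TMM
#' normalization factor. The treatment coefficient is tested with a
#' likelihood-ratio test; p-values are adjusted per timepoint by
#' Benjamini-Hochberg and genes called significant at `q < alpha`
#' (default 0.05).
#'
#' Counts are a wide tibble: a `gene` column followed by one column per
#' sample. Sample metadata is a tibble with `sample`, `treatment`
#' (`mock`/`dex`), `timepoint`, `batch` and `lib_size`. Gene lengths (bp)
#' for RPKM come in a two-column tibble `gene`, `length`.
#'
#' @name de
NULL

assert_counts <- function(counts, meta) {
  stopifnot("gene" %in% names(counts))
  samples <- setdiff(names(counts), "gene")
  if (!all(meta$sample %in% samples)) {
    stop("metadata samples missing from count table: ",
         paste(setdiff(meta$sample, samples), collapse = ", "), call. = FALSE)
  }
  invisible(samples)
}

counts_matrix <- function(counts, samples) {
  m <- as.matrix(counts[, samples, drop = FALSE])
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  m
}

#' Reads per kilobase per million (RPKM)
#'
#' `RPKM = count / (length/1e3) / (lib_size/1e6)`.
#'
#' @param counts wide count tibble (`gene` + sample columns).
#' @param gene_lengths tibble with `gene` and `length` (bp).
#' @param meta sample metadata with `sample` and `lib_size`.
#' @return tibble shaped like `counts` with RPKM values.
#' @export
rpkm <- function(counts, gene_lengths, meta) {
  samples <- assert_counts(counts, meta)
  len <- gene_lengths$length[match(counts$gene, gene_lengths$gene)]
  if (anyNA(len) || any(len <= 0)) stop("missing or non-positive gene length", call. = FALSE)
  ls <- meta$lib_size[match(samples, meta$sample)]
  if (anyNA(ls) || any(ls <= 0)) stop("missing or non-positive library size", call. = FALSE)
  m <- counts_matrix(counts, samples)
  r <- sweep(m / (len / 1e3), 2, ls / 1e6, "/")
  dplyr::bind_cols(tibble::tibble(gene = counts$gene),
                   tibble::as_tibble(r, .name_repair = "minimal"))
}

#' Mean RPKM per (treatment, timepoint) group
#'
#' @inheritParams rpkm
#' @return long tibble: `gene`, `treatment`, `timepoint`, `mean_rpkm`.
#' @export
group_rpkm <- function(counts, gene_lengths, meta) {
  r <- rpkm(counts, gene_lengths, meta)
  tidyr::pivot_longer(r, -"gene", names_to = "sample", values_to = "rpkm") |>
    dplyr::inner_join(meta[, c("sample", "treatment", "timepoint")], by = "sample") |>
    dplyr::group_by(.data$gene, .data$treatment, .data$timepoint) |>
    dplyr::summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop")
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' The reference sample is the one whose 75th percentile of library-size-
#' scaled counts is closest to the mean 75th percentile. For each sample,
#' genes expressed in both sample and reference contribute an M-value
#' (log2 ratio) and an A-value (average log2 abundance); the most extreme
#' 30% of M and 5% of A are trimmed and the factor is the precision-
#' weighted mean of the remaining M-values. Factors are rescaled to
#' multiply to 1.
#'
#' @param counts wide count tibble.
#' @param meta sample metadata with `sample` and `lib_size`.
#' @return tibble: `sample`, `norm_factor`.
#' @export
tmm_factors <- function(counts, meta) {
  samples <- assert_counts(counts, meta)
  if (length(samples) < 2) stop("TMM needs at least two samples", call. = FALSE)
  m <- counts_matrix(counts, samples)
  ls <- meta$lib_size[match(samples, meta$sample)]
  if (any(colSums(m) == 0)) stop("all-zero sample in count table", call. = FALSE)
  scaled <- sweep(m, 2, ls, "/")
  uq <- apply(scaled, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_along(samples), function(j) {
    if (j == ref) return(1)
    tmm_pair(m[, j], m[, ref], ls[j], ls[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample = samples, norm_factor = f)
}

# one TMM factor: sample obs vs reference, edgeR-style trims and weights
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' Per gene, counts are scaled to a common effective depth, the dispersion
#' `phi = (var - mean) / mean^2` is estimated within each treatment group
#' and averaged, then shrunk 50/50 toward the trimmed-mean (trim 0.1)
#' common dispersion across genes.
#'
#' @param m count matrix (genes x samples).
#' @param eff_libsize effective library sizes per sample.
#' @param group factor splitting samples into homogeneous groups.
#' @return numeric vector of shrunken dispersions (>= 1e-8), one per gene.
#' @export
estimate_dispersion <- function(m, eff_libsize, group) {
  z <- sweep(m, 2, eff_libsize / mean(eff_libsize), "/")
  per_group <- vapply(levels(factor(group)), function(g) {
    zz <- z[, group == g, drop = FALSE]
    n <- ncol(zz)
    mu <- rowMeans(zz)
    v <- apply(zz, 1, stats::var)
    # denominator corrected for the variance of the estimated mean:
    # E[mu_hat^2] = mu^2 + sigma^2/n
    den <- mu^2 - v / n
    ifelse(mu > 0 & den > 0, (v - mu) / den, NA_real_)
  }, numeric(nrow(m)))
  raw <- rowMeans(per_group, na.rm = TRUE)
  raw[!is.finite(raw)] <- 0
  raw <- pmax(raw, 0)
  common <- mean(raw, trim = 0.1)
  pmax(0.5 * raw + 0.5 * common, 1e-8)
}

#' Fit per-gene NB models and test the treatment effect at one timepoint
#'
#' For every gene with any nonzero count at the timepoint, a full model
#' (`~ batch + treatment` with log effective-library-size offset) and a
#' reduced model (`~ batch`) are fitted at the gene's shrunken dispersion;
#' the likelihood-ratio statistic is referred to chi-square(1). `logFC` is
#' the treatment (dex vs mock) coefficient divided by `ln 2`. Non-converged
#' fits are flagged and given `p = 1` with a warning; all-zero genes are
#' skipped.
#'
#' @param counts wide count tibble.
#' @param meta sample metadata (`sample`, `treatment`, `timepoint`, `batch`,
#'   `lib_size`); the design at `timepoint` must be paired (one mock and one
#'   dex per batch) with at least two batches.
#' @param timepoint the timepoint to analyze.
#' @param dispersion optional fixed dispersion (single value or per-gene
#'   vector) overriding [estimate_dispersion()].
#' @return tibble: `gene`, `timepoint`, `logFC`, `p_value`, `converged`.
#' @export
fit_de <- function(counts, meta, timepoint, dispersion = NULL) {
  samples <- assert_counts(counts, meta)
  sub <- meta[meta$timepoint == timepoint, ]
  if (nrow(sub) == 0) stop("no samples at timepoint ", timepoint, call. = FALSE)
  check_paired_design(sub)
  m <- counts_matrix(counts, sub$sample)
  nf <- tmm_factors(counts[, c("gene", sub$sample)], sub)
  eff <- sub$lib_size[match(nf$sample, sub$sample)] * nf$norm_factor
  names(eff) <- nf$sample
  eff <- eff[colnames(m)]
  treatment <- factor(sub$treatment[match(colnames(m), sub$sample)],
                      levels = c("mock", "dex"))
  batch <- factor(sub$batch[match(colnames(m), sub$sample)])
  keep <- rowSums(m) > 0
  if (!any(keep)) stop("all genes have zero counts at timepoint ", timepoint, call. = FALSE)
  phi <- if (is.null(dispersion)) {
    estimate_dispersion(m[keep, , drop = FALSE], eff, treatment)
  } else {
    rep_len(dispersion, sum(keep))
  }
  X_full <- stats::model.matrix(~ batch + treatment)
  X_red <- stats::model.matrix(~ batch)
  off <- log(eff)
  genes <- rownames(m)[keep]
  mk <- m[keep, , drop = FALSE]
  res <- vapply(seq_along(genes), function(i) {
    nb_lrt(mk[i, ], X_full, X_red, off, phi[i])
  }, numeric(3))
  n_bad <- sum(res[3, ] == 0)
  if (n_bad > 0) {
    warning(n_bad, " gene fit(s) did not converge; p set to 1", call. = FALSE)
  }
  tibble::tibble(
    gene = genes,
    timepoint = timepoint,
    logFC = res[1, ],
    p_value = res[2, ],
    converged = res[3, ] == 1
  )
}

# returns c(logFC, p, converged)
nb_lrt <- function(y, X_full, X_red, offset, phi) {
  fam <- MASS::negative.binomial(theta = 1 / phi)
  out <- tryCatch({
    f1 <- suppressWarnings(stats::glm.fit(X_full, y, family = fam, offset = offset))
    f0 <- suppressWarnings(stats::glm.fit(X_red, y, family = fam, offset = offset))
    if (!f1$converged || !f0$converged) stop("no convergence")
    lr <- max(0, f0$deviance - f1$deviance)
    beta <- f1$coefficients[ncol(X_full)]
    c(beta / log(2), stats::pchisq(lr, df = 1, lower.tail = FALSE), 1)
  }, error = function(e) c(NA_real_, 1, 0))
  out
}

check_paired_design <- function(sub) {
  tab <- table(sub$batch, sub$treatment)
  if (!all(c("mock", "dex") %in% colnames(tab))) {
    stop("design is missing a treatment arm", call. = FALSE)
  }
  if (nrow(tab) < 2) stop("need at least two batches", call. = FALSE)
  if (!all(tab[, c("mock", "dex")] == 1)) {
    stop("design is not paired: each batch needs exactly one mock and one dex sample",
         call. = FALSE)
  }
  invisible(sub)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper around [stats::p.adjust()] with input
#' validation).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Run the full time-course DE analysis
#'
#' Fits every timepoint with [fit_de()], adjusts p-values per timepoint and
#' flags significance at `q < alpha`.
#'
#' @inheritParams fit_de
#' @param timepoints timepoints to analyze (default: all in `meta`).
#' @param alpha FDR threshold (default 0.05).
#' @return tibble: `gene`, `timepoint`, `logFC`, `p_value`, `q_value`,
#'   `significant`, `converged`.
#' @export
run_de <- function(counts, meta, timepoints = sort(unique(meta$timepoint)),
                   alpha = 0.05, dispersion = NULL) {
  purrr::map_dfr(timepoints, function(tp) {
    r <- fit_de(counts, meta, tp, dispersion = dispersion)
    r$q_value <- bh_adjust(r$p_value)
    r$significant <- r$q_value < alpha
    r
  })
}

#' Summarize a time-course DE result
#'
#' Computes per-timepoint significant counts, the 7-cell Venn partition of
#' the unique DE gene set across timepoints, the logFC range over
#' significant calls, and direction tallies at two levels: unique genes
#' (direction = sign of logFC at the gene's significant timepoints; mixed
#' signs are counted `ambiguous`) and gene-by-timepoint records.
#'
#' @param results tibble from [run_de()] (needs `gene`, `timepoint`,
#'   `logFC`, `significant`).
#' @param alpha recorded in the summary (informational).
#' @return object of class `de_summary`: a list with `per_timepoint`,
#'   `venn`, `logfc_range`, `gene_directions`, `record_directions`,
#'   `n_unique`, `alpha`.
#' @export
summarize_de <- function(results, alpha = 0.05) {
  stopifnot(all(c("gene", "timepoint", "logFC", "significant") %in% names(results)))
  tps <- sort(unique(results$timepoint))
  sig <- results[results$significant, ]
  per_tp <- tibble::tibble(
    timepoint = tps,
    n_de = vapply(tps, function(tp) sum(sig$timepoint == tp), integer(1))
  )
  sets <- lapply(tps, function(tp) unique(sig$gene[sig$timepoint == tp]))
  names(sets) <- as.character(tps)
  venn <- venn_partition(sets)
  lfc <- if (nrow(sig)) range(sig$logFC) else c(NA_real_, NA_real_)
  dirs <- sig |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(direction = direction_of(.data$logFC), .groups = "drop")
  gene_dir <- c(up = sum(dirs$direction == "up"),
                down = sum(dirs$direction == "down"),
                ambiguous = sum(dirs$direction == "ambiguous"))
  rec_dir <- c(up = sum(sig$logFC > 0), down = sum(sig$logFC < 0))
  structure(
    list(per_timepoint = per_tp, venn = venn,
         logfc_range = c(min = lfc[1], max = lfc[2]),
         gene_directions = gene_dir, record_directions = rec_dir,
         n_unique = length(unique(sig$gene)),
         directions = dirs, alpha = alpha),
    class = "de_summary"
  )
}

direction_of <- function(lfc) {
  s <- unique(sign(lfc))
  s <- s[s != 0]
  if (length(s) == 0) return("ambiguous")
  if (all(s == 1)) "up" else if (all(s == -1)) "down" else "ambiguous"
}

#' Exclusive Venn partition of gene sets
#'
#' @param sets named list of character vectors.
#' @return tibble with `cell` (e.g. `"2"`, `"2&4"`, `"2&4&8"`) and `n`; the
#'   cells partition the union of the sets.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    apply(utils::combn(names(sets), k), 2, paste, collapse = "&")
  }))
  tibble::tibble(
    cell = combos,
    n = vapply(combos, function(cb) sum(key == cb), integer(1))
  )
}

#' @export
print.de_summary <- function(x, ...) {
  cat("Time-course DE summary (alpha =", x$alpha, ")\n")
  cat("  unique DE genes:", x$n_unique, "\n")
  cat("  per timepoint: ",
      paste(sprintf("%sh=%d", x$per_timepoint$timepoint, x$per_timepoint$n_de),
            collapse = ", "), "\n")
  cat("  gene directions: up", x$gene_directions["up"],
      "/ down", x$gene_directions["down"],
      "/ ambiguous", x$gene_directions["ambiguous"], "\n")
  cat("  record directions: up", x$record_directions["up"],
      "/ down", x$record_directions["down"], "\n")
  cat("  logFC range:", sprintf("%.3f .. %.3f", x$logfc_range["min"],
                                x$logfc_range["max"]), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the Venn cells of a DE summary
#' @param x a `de_summary`.
#' @param ... unused.
#' @return tibble of exclusive Venn cells and counts.
#' @export
tidy.de_summary <- function(x, ...) x$venn

#' One-row overview of a DE summary
#' @param x a `de_summary`.
#' @param ... unused.
#' @return one-row tibble with headline counts.
#' @export
glance.de_summary <- function(x, ...) {
  tibble::tibble(
    n_unique = x$n_unique,
    n_up = unname(x$gene_directions["up"]),
    n_down = unname(x$gene_directions["down"]),
    n_ambiguous = unname(x$gene_directions["ambiguous"]),
    records_up = unname(x$record_directions["up"]),
    records_down = unname(x$record_directions["down"]),
    logfc_min = unname(x$logfc_range["min"]),
    logfc_max = unname(x$logfc_range["max"]),
    alpha = x$alpha
  )
}
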