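#' Run the full synthetic-truth pipeline
#'
#' Generates a genome with planted peaks, motif sites and DE targets, then
#' runs the complete analysis: coverage simulation, replicate combination,
#' difference track, threshold peak calling, nearest-TSS annotation,
#' time-course DE with batch adjustment, PWM scanning with the
#' randomized-peak null, and the DE-and-bound intersection. The result
#' carries the ground truth and a comparison against it.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; all stage seeds derive from it.
#' @param threshold peak-calling threshold on the difference track
#'   (default 50, midway between the default background of 5 and
#'   enrichment of 100).
#' @param alpha DE FDR threshold (default 0.05).
#' @param p_threshold motif-site p-value cutoff (default 0.001).
#' @return object of class `florabind_run`: a list with the simulated
#'   inputs, every intermediate result, and `evaluation` (peak recovery,
#'   false peaks, DE calls vs truth, direct-target recovery, observed vs
#'   null motif-overlap fractions).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, threshold = 50,
                         alpha = 0.05, p_threshold = 0.001) {
  gen <- simulate_genome(config, seed = seed)
  truth <- gen$truth
  tagged <- simulate_chip_coverage(truth, config, tagged = TRUE,
                                   seed = seed + 1001)
  untagged <- simulate_chip_coverage(truth, config, tagged = FALSE,
                                     seed = seed + 2002)
  diff <- difference_track(combine_replicates(tagged),
                           combine_replicates(untagged))
  # replicate combination sums depth, so the calling threshold scales with
  # the number of replicates
  peaks <- call_peaks(diff, threshold = threshold * config$n_replicates)
  assignments <- if (nrow(peaks) && nrow(gen$genes)) {
    annotate_peaks(peaks, gen$genes)
  } else {
    tibble::tibble(peak_id = character(), gene_id = character(),
                   tss_distance = numeric(), category = character())
  }
  sim <- simulate_counts(make_design(config$timepoints, config$n_batches),
                         truth, gen$genes, config, seed = seed + 3003)
  de <- run_de(sim$counts, sim$meta, alpha = alpha)
  de_summary <- summarize_de(de, alpha = alpha)
  hits <- scan_pwm(truth$motif, gen$genome, p_threshold = p_threshold)
  observed_frac <- if (nrow(peaks)) overlap_fraction(peaks, hits) else NA_real_
  null_peaks <- if (nrow(peaks)) {
    randomize_peaks(peaks, truth$chrom_lengths, seed = seed + 4004)
  } else peaks
  null_frac <- if (nrow(peaks)) overlap_fraction(null_peaks, hits) else NA_real_
  candidates <- if (any(de$significant) && nrow(assignments)) {
    intersect_de_bound(de, assignments)
  } else {
    tibble::tibble(gene = character(), direction = character())
  }
  structure(list(
    genome = gen$genome, genes = gen$genes, truth = truth,
    difference = diff, peaks = peaks, assignments = assignments,
    counts = sim$counts, meta = sim$meta, gene_lengths = sim$gene_lengths,
    de = de, de_summary = de_summary, motif_hits = hits,
    null_peaks = null_peaks, candidates = candidates,
    evaluation = evaluate_run(peaks, de, candidates, truth,
                              observed_frac, null_frac),
    params = list(seed = seed, threshold = threshold, alpha = alpha,
                  p_threshold = p_threshold)
  ), class = "florabind_run")
}

#' Compare called results against planted truth
#'
#' @param peaks called peak tibble.
#' @param de DE result tibble from [run_de()].
#' @param candidates tibble from [intersect_de_bound()].
#' @param truth `truth` list from [simulate_genome()].
#' @param observed_frac,null_frac motif-overlap fractions of observed and
#'   randomized peaks (optional).
#' @return list of recovery statistics.
#' @export
evaluate_run <- function(peaks, de, candidates, truth,
                         observed_frac = NA_real_, null_frac = NA_real_) {
  planted <- truth$peaks
  n_recovered <- 0L
  n_false <- nrow(peaks)
  if (nrow(peaks) && nrow(planted)) {
    pr <- GenomicRanges::GRanges(planted$chrom,
                                 IRanges::IRanges(planted$start + 1L,
                                                  planted$end))
    cr <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L,
                                                  peaks$end))
    n_recovered <- sum(IRanges::overlapsAny(pr, cr))
    n_false <- sum(!IRanges::overlapsAny(cr, pr))
  }
  sig_genes <- unique(de$gene[de$significant])
  target <- truth$de_targets$gene
  est <- de[de$gene %in% target, c("gene", "timepoint", "logFC")]
  est <- dplyr::left_join(est, truth$de_targets, by = "gene",
                          suffix = c("", "_true"))
  list(
    n_planted_peaks = nrow(planted),
    n_called_peaks = nrow(peaks),
    n_recovered_peaks = n_recovered,
    n_false_peaks = n_false,
    de_true_positives = length(intersect(sig_genes, target)),
    de_false_positives = length(setdiff(sig_genes, target)),
    n_de_targets = length(target),
    logfc_error = est$logFC - est$logFC_true,
    direct_targets_found = sort(unique(candidates$gene)),
    direct_targets_planted = sort(toupper(truth$direct_targets)),
    observed_overlap_fraction = observed_frac,
    null_overlap_fraction = null_frac
  )
}

#' @export
print.florabind_run <- function(x, ...) {
  ev <- x$evaluation
  cat("florabind synthetic run (seed", x$params$seed, ")\n")
  cat("  peaks: ", ev$n_called_peaks, " called, ", ev$n_recovered_peaks, "/",
      ev$n_planted_peaks, " planted recovered, ", ev$n_false_peaks,
      " false\n", sep = "")
  cat("  DE: ", ev$de_true_positives, "/", ev$n_de_targets,
      " targets called, ", ev$de_false_positives, " extra calls\n", sep = "")
  cat("  direct targets: ", length(ev$direct_targets_found), " found vs ",
      length(ev$direct_targets_planted), " planted\n", sep = "")
  cat("  motif overlap: observed ",
      sprintf("%.3f", ev$observed_overlap_fraction), " vs null ",
      sprintf("%.3f", ev$null_overlap_fraction), "\n", sep = "")
  invisible(x)
}
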