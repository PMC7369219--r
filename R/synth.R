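#' Synthetic data with known ground truth
#'
#' The generator emulates the structure of an inducible transcription-factor
#' study: a small multi-chromosome genome with strand-assigned,
#' non-overlapping gene models; ChIP coverage that is Poisson background
#' plus Poisson enrichment over planted peak intervals (the untagged
#' control never receives enrichment); motif consensus strings embedded at
#' recorded positions inside the planted peaks; and negative-binomial
#' counts for a 2-treatment x 3-timepoint x 4-batch paired design with an
#' induced logFC on a designated target set. All generators are
#' deterministic for a given seed.
#'
#' @name synth
NULL

#' Simulation configuration
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 200000).
#' @param n_genes number of gene models (default 200).
#' @param gene_length length-2 range of gene lengths in bp
#'   (default 500-3000).
#' @param n_peaks number of planted binding peaks, each tied to a distinct
#'   gene's TSS (default 20).
#' @param peak_width planted peak width in bp (default 300).
#' @param background_depth Poisson background depth `lambda_bg` in
#'   reads/base (default 5).
#' @param enrichment_depth added Poisson depth `lambda_pk` inside planted
#'   peaks of tagged samples (default 100).
#' @param n_replicates ChIP replicates per condition (default 2).
#' @param nb_dispersion NB dispersion `phi` for counts; 0 gives Poisson
#'   counts (default 0.05).
#' @param library_size length-2 range of library sizes in fragments
#'   (default 0.8e6-1.2e6).
#' @param batch_effect_sd standard deviation of the log-normal
#'   multiplicative batch effect on depth (default 0.1).
#' @param n_batches paired batches per timepoint (default 4).
#' @param timepoints sampling times in hours (default 2, 4, 8).
#' @param n_de number of genes with an induced expression change
#'   (default 30).
#' @param de_logfc magnitude of the induced log2 fold change (default 2).
#' @param frac_down fraction of DE targets that are downregulated
#'   (default 0.3).
#' @param n_direct how many DE targets are also bound (peak-associated);
#'   these are the planted direct targets (default 20, i.e. every planted
#'   peak gene carries an expression change; must be
#'   `<= min(n_de, n_peaks)`). When `n_direct < n_peaks`, bound genes
#'   without an induced change exist and FDR-controlled testing will
#'   occasionally call one, so the DE-and-bound set is only expected to
#'   match the planted direct targets exactly when
#'   `n_direct == n_peaks`.
#' @param baseline_mean mean of the per-gene baseline expression
#'   (counts per million-scale unit, default 100).
#' @param baseline_sdlog sdlog of the log-normal baseline draw (default 1).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 200000L, n_genes = 200,
                       gene_length = c(500, 3000), n_peaks = 20,
                       peak_width = 300, background_depth = 5,
                       enrichment_depth = 100, n_replicates = 2,
                       nb_dispersion = 0.05,
                       library_size = c(0.8e6, 1.2e6),
                       batch_effect_sd = 0.1, n_batches = 4,
                       timepoints = c(2, 4, 8), n_de = 30, de_logfc = 2,
                       frac_down = 0.3, n_direct = 20,
                       baseline_mean = 100, baseline_sdlog = 1) {
  cfg <- as.list(environment())
  stopifnot(
    n_chroms >= 1, chrom_length >= 1, n_genes >= 0,
    length(gene_length) == 2, all(gene_length > 0),
    gene_length[1] <= gene_length[2],
    n_peaks >= 0, peak_width >= 1,
    background_depth >= 0, enrichment_depth >= 0,
    n_replicates >= 1, nb_dispersion >= 0,
    length(library_size) == 2, all(library_size > 0),
    batch_effect_sd >= 0, n_batches >= 2,
    n_de >= 0, de_logfc >= 0, frac_down >= 0, frac_down <= 1,
    n_direct >= 0, n_direct <= min(n_de, max(n_peaks, 0)),
    baseline_mean > 0, baseline_sdlog >= 0
  )
  if (n_peaks > n_genes && n_genes > 0) {
    stop("n_peaks must not exceed n_genes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' A deterministic synthetic PWM
#'
#' An informative motif for planting and recovery tests: probability
#' `strength` on the consensus letter at each position, the remainder
#' spread evenly.
#'
#' @param consensus consensus string (default `"ACGTGGCAAT"`).
#' @param strength consensus letter probability (default 0.85).
#' @return a `pwm` named `"synthetic"`.
#' @export
synthetic_pwm <- function(consensus = "ACGTGGCAAT", strength = 0.85) {
  letters_i <- match(strsplit(toupper(consensus), "")[[1]], dna_letters)
  stopifnot(!anyNA(letters_i), strength > 0.25, strength < 1)
  mat <- matrix((1 - strength) / 3, length(letters_i), 4)
  mat[cbind(seq_along(letters_i), letters_i)] <- strength
  pwm(mat, name = "synthetic")
}

#' Generate a toy genome, gene models and ground truth
#'
#' Chromosome sequences are uniform-random nucleotides. Genes are packed
#' non-overlapping (1 bp minimum gap) with uniform lengths and random
#' strands; packing that exceeds chromosome capacity is an explicit error.
#' `n_peaks` genes get a planted peak of `peak_width` bp centered on their
#' TSS (clipped to chromosome bounds), and the PWM consensus is embedded at
#' the center of each planted peak. DE targets are `n_direct` bound genes
#' plus `n_de - n_direct` unbound genes, with signed logFC applied at every
#' timepoint.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param motif a `pwm` whose consensus gets planted (default
#'   [synthetic_pwm()]).
#' @return list with `genome` (named character vector of sequences),
#'   `genes` (gene tibble as from [gene_models()]) and `truth`, a list
#'   holding `chrom_lengths`, `peaks` (planted intervals + enrichment
#'   depth), `motif_sites`, `bound_genes`, `de_targets` (gene, logFC per
#'   timepoint), `direct_targets`, the planting `motif`, `seed` and
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1,
                            motif = synthetic_pwm()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- vapply(chroms, function(ch) {
    paste(sample(dna_letters, config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  chrom_lengths <- tibble::tibble(chrom = chroms,
                                  length = rep(config$chrom_length,
                                               config$n_chroms))
  # pack genes round-robin across chromosomes
  genes <- tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
  if (config$n_genes > 0) {
    per_chrom <- table(rep(chroms, length.out = config$n_genes))
    gene_rows <- purrr::map_dfr(chroms, function(ch) {
      k <- as.integer(per_chrom[ch])
      if (is.na(k) || k == 0) return(tibble::tibble())
      len <- sample(config$gene_length[1]:config$gene_length[2], k,
                    replace = TRUE)
      free <- config$chrom_length - sum(len) - k   # reserve 1 bp gaps
      if (free < 0) {
        stop("infeasible packing: genes exceed chromosome capacity on ", ch,
             call. = FALSE)
      }
      extra <- as.vector(stats::rmultinom(1, free, rep(1, k + 1)))
      gaps <- c(extra[seq_len(k)] + 1L, extra[k + 1])
      # cumulative layout: gap1, gene1, gap2, gene2, ..., trailing gap
      starts <- cumsum(c(gaps[1], len[-k] + gaps[-c(1, k + 1)]))
      tibble::tibble(chrom = ch, start = as.integer(starts),
                     end = as.integer(starts + len),
                     strand = sample(c("+", "-"), k, replace = TRUE))
    })
    gene_rows <- dplyr::arrange(gene_rows, .data$chrom, .data$start)
    gene_rows$gene_id <- sprintf("GENE%04d", seq_len(nrow(gene_rows)))
    genes <- gene_models(gene_rows[, c("gene_id", "chrom", "start", "end",
                                       "strand")])
  }
  # planted peaks at the TSS of n_peaks distinct genes
  peaks <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character(),
                          enrichment_depth = numeric())
  if (config$n_peaks > 0 && nrow(genes) > 0) {
    half <- config$peak_width %/% 2
    # candidates: genes whose TSS-centered peak fits inside the chromosome;
    # accept in random order, skipping genes whose peak would overlap an
    # accepted one (overlapping planted peaks would merge when called and
    # could not each be recovered as a distinct interval)
    ok <- genes$tss >= half & genes$tss + (config$peak_width - half) <=
      config$chrom_length
    cand <- genes[ok, ][sample(sum(ok)), ]
    sel <- integer()
    for (i in seq_len(nrow(cand))) {
      s <- cand$tss[i] - half
      clash <- any(cand$chrom[sel] == cand$chrom[i] &
                     abs(cand$tss[sel] - cand$tss[i]) < config$peak_width)
      if (!clash) sel <- c(sel, i)
      if (length(sel) == config$n_peaks) break
    }
    if (length(sel) < config$n_peaks) {
      stop("cannot place ", config$n_peaks,
           " non-overlapping peaks on TSSs; reduce n_peaks or peak_width",
           call. = FALSE)
    }
    g <- cand[sort(sel), ]
    g <- g[order(g$gene_id), ]
    peaks <- tibble::tibble(chrom = g$chrom,
                            start = as.integer(g$tss - half),
                            end = as.integer(g$tss - half + config$peak_width),
                            gene_id = g$gene_id,
                            enrichment_depth = config$enrichment_depth)
  }
  # embed the motif consensus at each planted peak center
  consensus <- pwm_consensus(motif)
  w <- nchar(consensus)
  motif_sites <- tibble::tibble(chrom = character(), pos = integer(),
                                strand = character())
  if (nrow(peaks) > 0) {
    pos <- pmax(0L, pmin((peaks$start + peaks$end) %/% 2 - w %/% 2,
                         config$chrom_length - w))
    motif_sites <- tibble::tibble(chrom = peaks$chrom, pos = as.integer(pos),
                                  strand = "+")
    for (i in seq_len(nrow(motif_sites))) {
      ch <- motif_sites$chrom[i]
      p <- motif_sites$pos[i]
      substr(genome[ch], p + 1, p + w) <- consensus
    }
  }
  # DE targets: n_direct bound genes + the rest unbound
  de_targets <- tibble::tibble(gene = character(), logFC = numeric())
  direct <- character()
  if (config$n_de > 0 && nrow(genes) > 0) {
    direct <- if (config$n_direct > 0) {
      sort(sample(peaks$gene_id, config$n_direct))
    } else character()
    pool <- setdiff(genes$gene_id, peaks$gene_id)
    extra <- sort(sample(pool, min(config$n_de - length(direct),
                                   length(pool))))
    target <- c(direct, extra)
    n_down <- round(config$frac_down * length(target))
    sign <- rep(1, length(target))
    if (n_down > 0) sign[sample(seq_along(target), n_down)] <- -1
    de_targets <- tibble::tibble(gene = target,
                                 logFC = sign * config$de_logfc)
  }
  truth <- list(chrom_lengths = chrom_lengths, peaks = peaks,
                motif_sites = motif_sites,
                bound_genes = unique(peaks$gene_id),
                de_targets = de_targets, direct_targets = direct,
                motif = motif, seed = seed, config = config)
  list(genome = genome, genes = genes, truth = truth)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Simulate ChIP coverage tracks
#'
#' Per base, depth is `Poisson(lambda_bg)`; inside planted peaks, tagged
#' samples additionally receive `Poisson(lambda_pk)`. Untagged tracks never
#' receive enrichment.
#'
#' @param truth the `truth` element from [simulate_genome()].
#' @param config a [sim_config()]; defaults to the config recorded in
#'   `truth`.
#' @param tagged logical; plant enrichment (default TRUE).
#' @param seed integer seed.
#' @return list of `n_replicates` coverage track tibbles.
#' @export
simulate_chip_coverage <- function(truth, config = truth$config,
                                   tagged = TRUE, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(config$n_replicates), function(rep_i) {
    depths <- lapply(seq_len(nrow(truth$chrom_lengths)), function(ci) {
      L <- truth$chrom_lengths$length[ci]
      v <- stats::rpois(L, config$background_depth)
      if (tagged && config$enrichment_depth > 0) {
        pk <- truth$peaks[truth$peaks$chrom == truth$chrom_lengths$chrom[ci], ]
        for (i in seq_len(nrow(pk))) {
          idx <- (pk$start[i] + 1):pk$end[i]
          v[idx] <- v[idx] + stats::rpois(length(idx), config$enrichment_depth)
        }
      }
      as.numeric(v)
    })
    names(depths) <- truth$chrom_lengths$chrom
    coverage_track(depths)
  })
}

#' Build the paired time-course design
#'
#' One mock and one dex sample per (timepoint, batch).
#'
#' @param timepoints sampling times (default 2, 4, 8).
#' @param n_batches number of batches (default 4).
#' @return metadata tibble: `sample`, `treatment`, `timepoint`, `batch`.
#' @export
make_design <- function(timepoints = c(2, 4, 8), n_batches = 4) {
  tidyr::expand_grid(timepoint = timepoints,
                     batch = sprintf("b%d", seq_len(n_batches)),
                     treatment = c("mock", "dex")) |>
    dplyr::mutate(sample = sprintf("t%s_%s_%s", .data$timepoint, .data$batch,
                                   .data$treatment), .before = 1)
}

#' Simulate NB counts for the paired design
#'
#' Counts are `NB(mean = mu_g * L_s * b_batch * 2^(logFC_g * [dex]),
#' dispersion = phi)`: `mu_g` is a log-normal per-gene baseline, `L_s` the
#' sample's library size in millions, `b_batch` a log-normal multiplicative
#' batch depth effect, and the induced logFC applies to dex samples of
#' target genes at every timepoint. `phi = 0` gives Poisson counts.
#'
#' @param design metadata tibble from [make_design()]; must contain both
#'   treatments.
#' @param truth `truth` from [simulate_genome()] (or any list with a
#'   `de_targets` tibble).
#' @param genes gene tibble giving the gene universe (ids and lengths).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `counts` (wide tibble), `meta` (design + `lib_size`),
#'   `gene_lengths`, `baseline` (per-gene `mu_g`).
#' @export
simulate_counts <- function(design, truth, genes, config = truth$config,
                            seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("mock", "dex") %in% design$treatment)) {
    stop("design is missing a treatment arm", call. = FALSE)
  }
  if (length(unique(design$batch)) < 2) {
    stop("design needs at least two batches", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gene_ids <- genes$gene_id
  mu <- stats::rlnorm(length(gene_ids),
                      meanlog = log(config$baseline_mean) -
                        config$baseline_sdlog^2 / 2,
                      sdlog = config$baseline_sdlog)
  lib_size <- stats::runif(nrow(design), config$library_size[1],
                           config$library_size[2])
  batches <- unique(design$batch)
  b_eff <- stats::setNames(exp(stats::rnorm(length(batches), 0,
                                            config$batch_effect_sd)), batches)
  lfc <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  hit <- intersect(truth$de_targets$gene, gene_ids)
  lfc[hit] <- truth$de_targets$logFC[match(hit, truth$de_targets$gene)]
  m <- matrix(0, nrow = length(gene_ids), ncol = nrow(design),
              dimnames = list(gene_ids, design$sample))
  for (s in seq_len(nrow(design))) {
    mean_s <- mu * (lib_size[s] / 1e6) * b_eff[design$batch[s]] *
      2^(lfc * (design$treatment[s] == "dex"))
    m[, s] <- if (config$nb_dispersion == 0) {
      stats::rpois(length(mean_s), mean_s)
    } else {
      stats::rnbinom(length(mean_s), mu = mean_s,
                     size = 1 / config$nb_dispersion)
    }
  }
  meta <- dplyr::mutate(design, lib_size = lib_size)
  list(
    counts = dplyr::bind_cols(tibble::tibble(gene = gene_ids),
                              tibble::as_tibble(m, .name_repair = "minimal")),
    meta = meta,
    gene_lengths = tibble::tibble(gene = gene_ids,
                                  length = genes$end - genes$start),
    baseline = tibble::tibble(gene = gene_ids, mu = mu)
  )
}
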