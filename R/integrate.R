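#' Candidate direct targets: DE genes bound by the factor
#'
#' The most likely direct targets are genes that are both differentially
#' expressed after induction and associated with a binding peak. Each
#' candidate carries all of its significant logFC values (with timepoints),
#' all positional categories of its peaks, and a direction (`up`, `down`
#' or `ambiguous`) inherited from the DE direction classification.
#'
#' @name integrate
NULL

#' Intersect DE genes with peak-associated genes
#'
#' Gene identifiers are case-normalized (upper case) before intersection.
#'
#' @param de_results tibble from [run_de()] (`gene`, `timepoint`, `logFC`,
#'   `significant`).
#' @param assignments tibble from [annotate_peaks()] (`peak_id`, `gene_id`,
#'   `category`); unassigned peaks are ignored.
#' @return tibble of candidates, one row per gene: `gene`, `direction`,
#'   `logfc_label` (e.g. `"0.269 (2); 0.262 (4); 0.374 (8)"`),
#'   `categories` (semicolon-joined, in peak order), `peak_ids`, plus
#'   list-columns `timepoints` and `logFC`. Attributes `n_up`, `n_down`,
#'   `n_ambiguous` carry the direction tallies.
#' @export
intersect_de_bound <- function(de_results, assignments) {
  if (nrow(de_results) == 0) stop("empty DE results", call. = FALSE)
  if (nrow(assignments) == 0) stop("empty peak assignments", call. = FALSE)
  de <- de_results[de_results$significant, ]
  de$gene <- toupper(de$gene)
  bound <- assignments[!is.na(assignments$gene_id), ]
  bound$gene_id <- toupper(bound$gene_id)
  genes <- sort(intersect(unique(de$gene), unique(bound$gene_id)))
  cand <- purrr::map_dfr(genes, function(g) {
    d <- de[de$gene == g, ]
    d <- d[order(d$timepoint), ]
    b <- bound[bound$gene_id == g, ]
    tibble::tibble(
      gene = g,
      direction = direction_of(d$logFC),
      logfc_label = format_logfc(d$logFC, d$timepoint),
      categories = paste(b$category, collapse = "; "),
      peak_ids = paste(b$peak_id, collapse = "; "),
      timepoints = list(d$timepoint),
      logFC = list(d$logFC)
    )
  })
  if (nrow(cand) == 0) {
    cand <- tibble::tibble(gene = character(), direction = character(),
                           logfc_label = character(), categories = character(),
                           peak_ids = character(), timepoints = list(),
                           logFC = list())
  }
  attr(cand, "n_up") <- sum(cand$direction == "up")
  attr(cand, "n_down") <- sum(cand$direction == "down")
  attr(cand, "n_ambiguous") <- sum(cand$direction == "ambiguous")
  cand
}

format_logfc <- function(lfc, tp) {
  paste(sprintf("%s (%s)", format(lfc, trim = TRUE, scientific = FALSE),
                format(tp, trim = TRUE)), collapse = "; ")
}

#' Export the candidate table as TSV
#'
#' Columns: `gene`, `direction`, `logfc_label`, `categories`, `peak_ids`.
#' Round-trips through [parse_candidates()].
#'
#' @param candidates tibble from [intersect_de_bound()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_candidates <- function(candidates, path) {
  flat <- candidates[, c("gene", "direction", "logfc_label", "categories",
                         "peak_ids")]
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Parse an exported candidate table
#'
#' Reconstructs the `timepoints` and `logFC` list-columns from the
#' `logfc_label` strings.
#'
#' @param path TSV written by [export_candidates()].
#' @return candidate tibble equivalent to the exported one.
#' @export
parse_candidates <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  parsed <- purrr::map(flat$logfc_label, function(lbl) {
    parts <- strsplit(lbl, ";\\s*")[[1]]
    m <- regmatches(parts, regexec("^(-?[0-9.eE+-]+) \\((.+)\\)$", parts))
    list(logFC = vapply(m, function(x) as.numeric(x[2]), numeric(1)),
         timepoints = vapply(m, function(x) as.numeric(x[3]), numeric(1)))
  })
  out <- tibble::tibble(
    gene = flat$gene,
    direction = flat$direction,
    logfc_label = flat$logfc_label,
    categories = flat$categories,
    peak_ids = flat$peak_ids,
    timepoints = purrr::map(parsed, "timepoints"),
    logFC = purrr::map(parsed, "logFC")
  )
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  attr(out, "n_ambiguous") <- sum(out$direction == "ambiguous")
  out
}
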