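---
title: "Identifying direct transcription-factor targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying direct transcription-factor targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florabind)
```

# The problem

A transcription factor's *direct* targets are genes it both binds and
regulates. Neither data type alone suffices: ChIP-seq finds binding that may
be non-functional, and an expression time course after induced activation
finds responses that may be indirect. florabind implements the integration
of the two: threshold-based peak calling on a tagged-minus-untagged
difference coverage track, assignment of each peak to the gene with the
nearest transcription start site (TSS), negative-binomial differential
expression (DE) across an induction time course with batch adjustment, and
the intersection of the bound and DE gene sets, supported by motif-scanning
and gene-set-overlap statistics.

The motivating experimental design is a glucocorticoid-inducible factor in
*Arabidopsis* flowers: dexamethasone application activates the factor, floral
tissue is collected at 2, 4 and 8 h in four paired mock/treated batches, and
binding is profiled by ChIP-seq against an untagged control line. Every
operation here generalizes to any design of that shape.

# Peak calling on difference tracks

Replicate coverage tracks are combined by per-base **summation** (pooling
reads from replicates sums their coverage). The difference track is
`tagged - s * untagged` with `s = 1` by default; `scale_untagged = TRUE`
sets `s` to the ratio of total depths. Negative values are clamped to zero,
since peaks are defined on excess tagged signal only.

A peak is a **maximal run of bases at or above the threshold `T`**
(reads/base). Two knobs generalize this: runs separated by fewer than
`merge_gap` sub-threshold bases are merged, and merged runs narrower than
`min_width` bp are dropped (defaults 0 and 1: plain thresholding). This is
the simplest faithful reading of browser-style threshold peak definition;
peak count is non-increasing in `T` and every high-threshold peak is
contained in a lower-threshold peak, which the tests verify against a
per-base brute-force oracle. Because replicates are summed, a threshold
stated per replicate must be scaled by the replicate count
(`run_pipeline()` does this).

# Peak-to-gene annotation

Each peak is assigned to the gene with the closest TSS on its chromosome.
The distance anchor is the **peak midpoint** (configurable to nearest edge);
ties break to the lexicographically smallest gene id; no maximum distance is
imposed by default (a cap is available). Signed distance is reported in gene
orientation (negative = 5' of the TSS).

Position categories use the precedence
`encompass > overlap_start > overlap_end > inside > upstream > downstream`:
a peak containing the whole gene body is `encompass`; covering the TSS base,
`overlap_start`; covering the transcription-end base, `overlap_end`; within
the gene body, `inside`; otherwise entirely 5' or 3' of the gene in its
orientation. These six categories are exhaustive and mutually exclusive for
any peak/gene pair on one chromosome; the tests re-derive them from explicit
base-membership sets over random geometries and check strand-mirror
invariance.

Category percentages use **largest-remainder rounding** so they always sum
to exactly 100. Published pie charts often round each slice independently,
which can total 101; the summaries here never do.

# Differential expression

Counts for gene *g*, sample *s* are modeled per timepoint as

$$\log \mu_{gs} = \log(\hat N_s) + \beta_{\text{batch}(s)} +
  \beta_{\text{trt}} \cdot [s \text{ treated}],\qquad
  y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$$

where the effective library size $\hat N_s$ is the recorded library size
times a TMM normalization factor (reference sample = upper quartile closest
to the mean upper quartile; 30% trim on M-values, 5% on A-values;
precision-weighted mean; factors scaled to multiply to 1). The treatment
effect is tested by a likelihood-ratio test against the batch-only model,
and `logFC` is the treatment coefficient / ln 2. P-values are adjusted per
timepoint with Benjamini-Hochberg; the significance threshold is `q < 0.05`
by default.

Dispersion $\phi_g$ is a per-gene method-of-moments estimate — computed
within treatment groups on depth-normalized counts with the denominator
corrected for the variance of the estimated mean — shrunk 50/50 toward the
common dispersion (trimmed mean across genes, trim 0.1; the trim level is
this package's choice). Each timepoint is fitted separately with its own
batch structure, matching a paired mock/treated flats-within-batch design.

**Calibration.** With the true dispersion supplied, the LRT's type-I error
at $\alpha = 0.05$ is 0.049. With the estimated dispersion it is ~0.06 on
2000-gene null simulations (4 paired batches): plugging a noisy 4-sample
dispersion estimate into a known-dispersion test is mildly liberal, and the
empirical FDR among called genes runs at roughly 1.5-1.6x the nominal level
under the same conditions. Small gene panels (hundreds of genes) estimate
the common dispersion less reliably and sit at the upper end of that range.
Genes significant at several timepoints with conflicting logFC signs are
reported as `ambiguous`, never silently assigned a direction. Two direction
tallies are reported, because both appear in published work of this shape:
unique genes (each counted once) and gene-by-timepoint records.

# Motif scanning

Sites are scored by log-odds in bits against a 0-order background
(estimated from the scanned sequence by default, with Laplace smoothing;
uniform or user-supplied optional). A pseudocount of 0.1 (a common scanning
default) is mixed into the motif probabilities — and into the background
only if it contains zeros — before log-odds.

A site's p-value is **exact**: the per-position scores are discretized to a
lattice (default 1/1000 bit) and convolved under the background by dynamic
programming, giving $p(s) = P_{bg}(\text{score} \ge s)$. Windows are scored
on the same lattice, so a reported p-value is exactly the background
probability of the reported score; tests verify agreement with exhaustive
$4^w$ enumeration to within one lattice step per position. Both strands are
scanned, reverse-strand hits are reported on forward coordinates, windows
containing `N` are skipped, and hits are windows with $p \le 0.001$ by
default.

The binding-enrichment null places each observed peak width uniformly at
random on a chromosome chosen with probability proportional to its length;
placements are independent and may overlap. The comparison statistic is the
fraction of peaks sharing at least one base with a motif hit, observed
versus randomized.

# Overlap statistics

The Jaccard index $|A \cap B| / |A \cup B|$ and the hypergeometric upper
tail $P(X \ge |A \cap B|)$ (the one-sided Fisher exact test) quantify
gene-list overlap; the universe size is an explicit required argument
because published analyses rarely state it and it changes the p-value
(the Jaccard index needs none). Odds ratios add 0.5 to zero cells so a
finite value is always reportable. Term enrichment is the same
hypergeometric machinery applied per term of a user-supplied term-to-gene
map with BH adjustment — no ontology content is bundled.

# The synthetic-data generator

`simulate_genome()`, `simulate_chip_coverage()` and `simulate_counts()`
generate data with recorded ground truth, emulating the study structure:

* a uniform-random genome (default 2 chromosomes x 200 kb) with 200
  non-overlapping strand-assigned gene models (0.5-3 kb);
* 20 planted peaks (300 bp) centered on gene TSSs, chosen so planted
  intervals do not overlap (overlapping plants would merge when called and
  could not be recovered as distinct intervals);
* ChIP coverage = Poisson(5) background per base, plus Poisson(100) inside
  planted peaks for tagged samples only, two replicates per condition;
* the scanning motif's consensus embedded at each planted peak center
  (exact consensus rather than probabilistic draws, so scan recovery is
  deterministic);
* negative-binomial counts (dispersion 0.05) for the 2-treatment x
  3-timepoint x 4-batch paired design, with log-normal library sizes
  (0.8-1.2 M), a multiplicative log-normal batch depth effect (sd 0.1 on
  the log scale) absorbed by the batch coefficient, and a planted log2
  fold change of +/-2 on 30 target genes (30% down).

By default **all 20 bound genes are among the DE targets**
(`n_direct = 20`). This is deliberate: FDR-controlled testing admits an
expected ~5% false discoveries among calls, so if bound genes with no true
expression change existed, an occasional false call would land on one and
the DE-and-bound set would not be expected to equal the planted direct
targets exactly. With the default design, exact end-to-end recovery is a
well-posed expectation and holds across the 20-seed test suite. Setting
`n_direct < n_peaks` creates bound-null genes for studying that leakage.

What the generator does **not** emulate: read-level sequencing (fragments,
mappability, GC bias), peak-shape structure (uniform enrichment rather than
fragment pileup shoulders), isoform structure, count outliers, and
correlated gene expression. Passing tests therefore demonstrate the
correctness of the pipeline's logic and its statistical calibration under
the stated model, not performance on real libraries.

The generative choices (scales, depths, effect sizes) are this package's
own; published studies of this design report no generative model.

# Numerical choices and degenerate inputs

* bedGraph/BED coordinates are 0-based half-open; GFF3 is converted from
  1-based inclusive at the parser boundary; all distances are bp.
* Parsers fail with line-numbered errors on overlapping bedGraph intervals,
  negative depths and malformed rows; empty files give empty, well-typed
  tibbles.
* `call_peaks` requires `T > 0`; an all-zero track yields no peaks.
* Non-converged NB fits are flagged with `p = 1` and a warning; all-zero
  genes are skipped.
* Nearest-TSS ties break lexicographically; a peak on a gene-less
  chromosome is flagged unassigned rather than dropped silently.
* The motif DP lattice is 1/1000 bit; coarser lattices trade accuracy for
  speed linearly in the score range.
* Seeds: every generator takes one and is byte-reproducible under it.

# Problem sizes used in the tests

The test and acceptance workloads were sized to exercise every code path at
statistically meaningful scale: the end-to-end suite runs the full pipeline
on 20 seeds of the default 2 x 200 kb genome; DE calibration uses 2000-gene
simulations over 10 seeds; oracle comparisons enumerate all $4^w$ words for
motif widths up to 6 and all hypergeometric tables for universes up to 20.

# Known limitations

* The DE engine is self-contained and is not numerically identical to any
  published package; its acceptance surface is synthetic-truth recovery.
* Dispersion estimation at n = 4 pairs is noisy; the prescribed 50/50
  shrinkage leaves the LRT mildly liberal (see Calibration above).
* Threshold peak calling has no statistical model of enrichment; the
  threshold is in raw difference-depth units and must be chosen by the
  analyst (model-based callers are out of scope).
* One randomized-peak draw estimates the null overlap fraction by default;
  repeat with different seeds for a confidence interval.
* Transcript-isoform-aware TSS selection and ontology-aware enrichment
  (term hierarchies) are out of scope.
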