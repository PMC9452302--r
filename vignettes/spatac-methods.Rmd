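---
title: "Models and methods behind spatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and the computational problem

Microfluidic deterministic barcoding turns a tissue section into a grid of
spatially addressed ATAC-seq measurements. Tn5 transposase inserts adapters
into accessible chromatin in situ; two successive ligation rounds then flow
known barcode sets (A1–A50 across, B1–B50 down) through perpendicular
microchannels, so each grid intersection — a *pixel*, typically 20–50 µm —
receives a unique barcode pair. After sequencing, read 1 carries the
construct

```
[barcode B (8 bp)][linker 2 (30 bp)][barcode A (8 bp)][linker 1 (30 bp)][genomic insert]
```

and the computational task is to (i) decode each read into its pixel,
(ii) turn aligned pairs into a deduplicated spatial fragments file,
(iii) quantify library quality per pixel, and (iv) run the accessibility
analysis stack — tile matrix, gene scores, iterative LSI, graph clustering,
UMAP, marker detection and backbone pseudotime — over the pixel grid.

`spatac` implements that chain, together with a fully seeded synthetic-read
simulator that provides ground truth for every stage.

# Decoding model

Linkers are matched **positionally** by Hamming distance at their fixed
offsets. Ligation chemistry yields fixed-length constructs, so no indel
alignment is attempted; a read whose fixed region is truncated is
unrecoverable by design. `N` counts as a mismatch everywhere, so
low-confidence calls can never rescue a match. Defaults: up to 3 mismatches
per 30-bp linker, barcode correction radius 1. Since the published filter's
exact tolerances are not stated, both are configuration, chosen
conservatively.

Barcode correction returns the unique whitelist entry within the radius;
ties at the minimum distance are rejected as `ambiguous`, never guessed.
The bundled default whitelists are synthetic 8-mers with minimum pairwise
Hamming distance 3, which makes radius-1 correction unambiguous by
construction; real datasets must supply their own layout file and
whitelists (the defaults stand in for sequences that live in the original
assay's oligo tables). Each read is classified exactly once
(`assigned`, `linker_fail`, `barcode_unmatched`, `barcode_ambiguous`,
`too_short`); unmatched takes precedence over ambiguous when the two
barcodes fail differently. Status counts always sum to the input count,
and the vectorised decoder is tested for exact agreement with a per-read
brute-force Hamming oracle.

# Fragments

Aligned proper pairs become fragments via the standard Tn5 correction:
`[plus-strand 5' + 4, minus-strand 5' + 1 − 5)` in 0-based half-open
coordinates, accounting for the 9-bp target-site duplication. The shifts
are configurable because the upstream convention differs between aligners.
Duplicates are defined by the key `(contig, start, end, pixel)` — the assay
has no UMIs — and collapse to one record with a `dup_count`. Defaults:
MAPQ ≥ 30, primary alignments only. The fragments file is the 5-column
BED-like TSV of the single-cell ATAC ecosystem, sorted and optionally
gzipped.

# Quality metrics

Per pixel: unique nuclear fragments (excluding `chrM`), mitochondrial
fraction, TSS fraction, TSS enrichment, FRiP, and the insert-size
histogram. Windows not fixed by the published workflow were set to the
common single-cell conventions and exposed as configuration:

* **TSS fraction** — fragments overlapping TSS ± 2,000 bp by ≥ 1 bp.
* **TSS enrichment** — mean per-base insertion depth in TSS ± 50 bp
  divided by the mean depth in the distal flanks (± 1,901–2,000 bp),
  with a pseudocount of one insertion in the flank count. A uniform
  insertion null scores ≈ 1; the score is reported per pixel (flagged when
  flank coverage is zero) and pooled.
* **FRiP** — computed over unique fragments, since the fragment file is
  the unit of record.

A naive deterministic peak caller (smoothed pooled insertion coverage over
a threshold) substitutes for a model-based caller so peak-dependent tests
need no external tool; it is not intended for real data.

# Matrices

The **tile matrix** bins the genome into fixed 5-kb tiles and counts Tn5
*insertions* (two per fragment — its start and `end − 1`), not fragment
overlaps: insertions are the assayed events, and the rule keeps the exact
conservation `sum(matrix) = 2 × unique nuclear fragments` testable. The
counting rule is recorded in the matrix attributes.

The **gene score** uses a deliberately simple, fully specified
exponential-decay model: gene body extended 5 kb upstream (strand-aware);
insertions within 100 kb of the extended body contribute weight 1 inside
it and `exp(−d/5000)` outside. The original tooling's model has additional
elaborations (neighbour-gene masking, tiled weighting, imputation); this
package documents its simpler model and keeps every parameter
configurable. Per-pixel depth normalisation to 10⁴ exists but is off by
default so conservation stays exact.

# Dimensionality reduction and clustering

Iterative LSI follows the published parameterisation (iterations = 2,
interim clustering at resolution 0.2, varFeatures = 25,000,
dims = 1:30) with the TF-IDF variant pinned because the method name alone
does not fix it:

```
tf  = count / pixel_total
idf = log(1 + N_pixels / (1 + n_pixels_with_tile))
x   = log1p(tf · idf · 1e4)
```

followed by truncated SVD (irlba). Components with |Pearson r| > 0.75
against log depth are dropped — the standard guard against
sequencing-depth dominance. Iteration 2 re-selects features by variance
across cluster pseudo-bulk profiles (depth-normalised log counts). When a
matrix has fewer tiles than `var_features` (always true at desk scale),
all tiles are used with a warning.

Clustering builds a cosine kNN graph (k = 30; exact search — grids are a
few thousand pixels, so brute force is both exact and fast), converts it
to shared-nearest-neighbour Jaccard weights (neighbourhoods include the
point itself, edges below 1/15 pruned), and runs seeded Leiden modularity
optimisation. Labels are relabelled 0..k−1 by decreasing size. UMAP uses
cosine metric, 30 neighbours, min_dist 0.5, single-threaded so a fixed
seed gives identical coordinates.

Markers are two-sided Wilcoxon rank-sum tests of each feature, one
cluster against the rest, BH-adjusted per cluster, with
`log2FC = log2((mean_in + 1)/(mean_out + 1))` and the two conventional
cutoffs (0.25 for gene-level features, 0.1 for peak-level ones).

# Backbone pseudotime

A trajectory is an ordered vector of cluster labels. Cluster centroids are
computed in the retained LSI space; each pixel of backbone cluster *j* is
projected onto the segment from centroid *j* to centroid *j + 1* (final
cluster: onto the preceding segment, continuing past its end), the
projection is clamped, and the resulting positions are min-max rescaled to
[0, 100]. This replaces the original tooling's spline fitting with a
simpler, fully deterministic geometry; on gradient-structured synthetic
tissue the two agree in rank terms (Spearman ≥ 0.8 against the planted
coordinate). Feature dynamics along pseudotime use equal-occupancy bins
and a 3-bin rolling mean that shrinks at the edges.

# The simulator: what it emulates, and what it does not

The generator's defaults describe one desk-scale study condition and are
not tuned per test:

| parameter | default | rationale |
|---|---|---|
| grid | 50 × 50 | the assay's 2,500-tile mosaic |
| depth | 150 unique fragments/pixel (Poisson, floor 1) | small enough to run everywhere, deep enough for structure recovery |
| duplicate rate | 0.3 | copies per fragment `1 + Geom(0.7)`, so mean copies = 1/0.7, with a closed-form unique/total expectation |
| per-base error | 0.01 | typical sequencer scale; with default tolerances ≈ 99.4% of reads decode |
| mito fraction | 0.05 | mid-range of the real libraries' 1–13% |
| peak weight | 0.7 | strong but not total accessibility concentration |
| region own-share | 0.8 | each region puts 80% of its peak mass on its own peak subset |
| fragment lengths | 0.6·N(60, 15) + 0.4·N(200, 25), truncated [20, 600] | reproduces the qualitative subnucleosomal/nucleosomal bimodality without claiming the real curve |
| TSS multiplier | 10 | target core:flank insertion ratio |

The synthetic genome is random sequence (3 × 600 kb nuclear contigs +
16 kb `chrM`), with non-overlapping peaks placed by stratified jitter and
gene TSSs at the centres of a peak subset, so promoter accessibility
differences propagate into gene scores. Tissue layouts are vertical bands
(contrasting peak-set weights per region) or a gradient whose peak-set
weights interpolate smoothly (Bernstein weights over the region sets).

The TSS component is calibrated exactly rather than by a nominal weight:
each fragment deposits two insertions, so the background (= flank)
insertion density is `2·w_bg·D/L`; a TSS-component fragment places one
cut site uniformly in a 101-bp core and its second cut site re-enters the
core with probability `γ = E[max(0, 1 − len/101)]` under the length
mixture. The component weight solves
`core density = multiplier × flank density`, which is why a configured
multiplier of 10 is recovered by the pooled enrichment score within
sampling error.

What the simulator does **not** model: PCR/GC sequence bias, chimeras,
indels, real genome sequence and repeat structure, nucleosome positioning,
doublets, and imaging artefacts. Passing the recovery tests therefore
demonstrates correctness of the pipeline's computations and calibration of
its statistics under a controlled generative model — not performance on
real tissue, whose headline metrics (tens of thousands of unique fragments
per pixel, replicate r = 0.95 on real libraries) are functions of real
sequencing depth and biology.

# Numerical and degenerate-input choices

* Sequencing errors are applied by drawing the global error count from the
  matching binomial and sampling positions uniformly — exactly equivalent
  to per-base Bernoulli draws, but vectorised.
* Fragment-length draws are clamped (not resampled) at [20, 600]; the
  clipped mass is < 0.5% per mode.
* Coordinates are kept ≥ 10 bp from contig ends so Tn5 shifts and read
  extraction never leave the contig.
* An all-identical-row matrix yields a flagged `degenerate` LSI embedding;
  UMAP refuses a fully degenerate embedding.
* Pixels with zero flank insertions get a flagged pseudocount-only TSS
  enrichment score rather than NA.
* Clusters smaller than 3 pixels are skipped (with a warning) in marker
  detection; Wilcoxon tests use the normal approximation.
* Leiden cannot merge disconnected SNN components, so the
  "resolution → 0 gives one cluster" limit applies to connected graphs.
* Deduplication is idempotent; re-writing a read-back fragments file is
  byte-stable.

# Problem sizes used by the test-suite and acceptance runs

Unit tests run on an 8 × 8 grid (depth 50) and a compact two-contig
(2 × 200 kb) genome with 30 peaks and 12 genes. Calibration checks
(uniform-null and 10× TSS enrichment) use depth 1,600 on the small grid so
pooled insertions exceed 10⁵. End-to-end recovery, gradient pseudotime and
replicate-reproducibility checks run at the full default condition
(50 × 50 grid, depth 150, ≈ 535k read pairs), which completes in a couple
of minutes on one CPU. These sizes are the package's chosen desk-scale
study conditions, stated here so results are interpretable.

# Known limitations

* The gene-score model is simpler than the original tooling's; absolute
  scores are not comparable across the two, though region contrasts are.
* The naive peak caller is a test scaffold, not a peak caller.
* Exact linker/barcode sequences of the real assay are not bundled; real
  data requires a user-supplied layout and whitelists.
* Pseudotime assumes the backbone's centroid chain is roughly monotone in
  the underlying process; strongly curved trajectories would need the
  spline machinery this package intentionally omits.
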