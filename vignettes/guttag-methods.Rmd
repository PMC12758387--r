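---
title: "Methods: single-cell H3K27me3 analysis of the aging fly gut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell H3K27me3 analysis of the aging fly gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`guttag` reimplements, as a tested pipeline, a single-cell CUT&Tag analysis
of the repressive H3K27me3 landscape in the *Drosophila* midgut across three
adult ages (1, 15 and 40 days), together with the bulk RNAPII-S5P and
Polycomb promoter analyses that accompany it. The pipeline starts from
barcoded fragment BED files; read trimming, alignment and demultiplexing are
out of scope. Because the real dataset is large and not bundled, every stage
is validated against a synthetic fragment generator with planted ground
truth (`synth_config()` / `generate_single_cell()` / `generate_bulk()`),
whose defaults encode the study conditions described below.

# Domain calling

H3K27me3 forms broad, multi-kilobase domains rather than sharp peaks. The
caller (`call_blocks()` + `threshold_blocks()`) follows the
sparse-enrichment idea: decompose the binned, genome-normalized pseudobulk
coverage into maximal runs of strictly positive signal ("signal blocks"),
rank blocks by AUC (signal x width) and keep the top fraction, 0.01 by
default (the stringent numeric threshold). Calling is per age on the
pseudobulk of all cells of that age; the per-age domain sets are merged with
bedtools-merge semantics (`merge_domain_sets()`) into the cross-age peak
universe used everywhere downstream.

Choices worth knowing:

* Numeric-threshold mode only. The single-cell pseudobulks have no IgG
  control track, so the control-based FDR mode of sparse-enrichment callers
  does not apply; 0.01 is interpreted as the top-AUC fraction.
* Block detection runs on 25 bp bins of the genome-normalized track
  (`normalize_track()`: coverage scaled by genome length over total
  coverage, so uniform coverage maps to exactly 1). Both bin width and the
  raw/normalized switch are exposed.
* No minimum block width is applied; downstream gene overlap suppresses
  tiny blocks naturally.

Normalization divides by total per-base coverage rather than fragment
count. That makes the defining property — a uniform track maps to all ones
— exact, and it is the testable contract; a fragment-count divisor is
available via the raw track plus your own scale if needed.

# Per-cell QC and doublets

`qc_metrics()` computes fragments per cell, FRiP (fraction of fragments in
the merged domain set) and blacklist fraction; `apply_filters()` applies
the published thresholds: at least 100 fragments, FRiP >= 0.7 (inclusive),
blacklist fraction <= 0.2 (inclusive). Filters are conjunctive and
idempotent.

Doublets are scored by synthetic-doublet kNN enrichment
(`doublet_scores()`): sum the count vectors of random cell pairs, project
observed cells and synthetic doublets into the fitted LSI space, and score
each cell by observed synthetic doublets among its k nearest neighbours
over the expected count `k * n_synth / (n_synth + n_cells)`. The pipeline
uses k = 50 with 5 synthetic doublets per cell: the score is a local
density ratio, and with a 5:1 synthetic-to-observed ratio a neighbourhood
of ~50 samples estimates it stably, whereas k = 10 is noticeably noisier.
The flagging threshold takes the top fraction by score; the pipeline
default (0.05) matches the generator's doublet rate. Same-type doublets
are emitted by the generator (pairs are drawn proportionally to type
frequencies) and are close to undetectable by profile — this is the worst
case for detection and bounds the attainable AUROC; the acceptance check
sits near that bound by construction.

# Embedding, clustering, typing

The cell x domain count matrix is embedded by TF-IDF/LSI
(`lsi_embed()`): term frequency = count over cell depth, IDF =
`log(1 + n_cells / (1 + feature cell count))`, truncated SVD, and
components correlating with log depth above 0.9 in absolute value are
dropped. Clustering (`snn_cluster()`) builds a cosine kNN graph (k = 20),
reweights edges by shared-neighbour Jaccard and runs Leiden under the
modularity objective at resolution 0.8. UMAP (`umap_embed()`) is for
plotting only. Defaults d = 30, k = 20, resolution 0.8 are the standard
single-cell choices; all are logged in the run manifest.

Cell types are assigned from chromatin silencing scores (`css_scores()`):
for each gene, 500 bp tiles covering the gene span +/- 50 kb are weighted
`exp(-d / tau)` with tau = 5 kb, where d is the distance from the tile
midpoint to the gene span (0 inside); a cell's raw score is the weighted
sum of its fragment-midpoint counts, scaled to 10,000 fragments per cell.
High CSS = repressed; a *low* CSS at a marker gene therefore identifies
the cell type that expresses it (escargot for ISC/EB, Piezo for
enteroendocrine, nubbin for enterocytes). `assign_types()` z-scores each
marker's cluster-mean CSS across clusters and gives every cluster the type
with the most negative z-score, ties broken by raw CSS, all-zero z flagged
ambiguous. Fragments are assigned to a single tile by midpoint to avoid
double counting; windows are not truncated at neighbouring genes — the
simplest model consistent with a distance-weighted tile aggregation, with
tau, window and tile width exposed rather than guessed constants.

# Pseudobulk differential repression

Counts are summed per (cell type, age, chip replicate) over genes within
domains (`pseudobulk()`), library-size normalized by total counts in the
feature universe, and tested per feature with a negative-binomial Wald
test (`differential()`): a single common dispersion phi (variance =
mu + phi mu^2) is estimated by method of moments — a regression through
the origin of the replicate variance excess on mu^2 across all features —
and `Var(log mean) = (1/mu + phi)/n` drives the Wald z. BH correction
across features; a feature is called (direction gain/loss) when FDR <
0.05 and |log2FC| >= 1, both configurable and logged. The same operation
runs verbatim on enhancers within domains. Per-feature dispersion
shrinkage is deliberately out of scope: with a handful of pseudobulk
replicates a single pooled dispersion is the honest model, and the null
calibration (type-I error within [0.03, 0.08] at alpha = 0.05 on a
Poisson null with two replicates per condition) is part of the acceptance
suite. CPKM (`cpkm()`) and row z-scores (`zscore_rows()`, population SD so
output rows have SD exactly 1) feed the heatmap-style summaries.

# Motif scanning

`pwm()` converts count matrices (MEME format via `read_meme()`) to
probabilities with a 0.1 pseudocount per cell. Sites score
`sum log2(p/background)` in bits; both strands are scanned and hits with
p < 1e-4 are kept. Site p-values are exact tail probabilities of the
score distribution under the background: up to width 8 the full outcome
distribution (at most 4^8 terms) is enumerated outright, so
`site_pvalue()` agrees with brute force exactly; for wider motifs a
dynamic program over finely discretized integer scores takes over, and
because per-column rounding can displace a score's mass point by up to
half a grid unit per column, the tail is bracketed between the sums just
outside that window with grid refinement (1e-4 then 4e-6 bits) until the
bracket is tight. `scan_pwm()` always scores sites on the discretized
matrix itself, so its p-value lookups are exact by construction.
`motif_enrichment()` compares hit presence in age-changing versus stable
in-domain enhancers with a two-sided Fisher exact test and BH correction —
an explicit extension that turns "motifs found in changing enhancers" into
a testable contrast.

# Bulk RNAPII-S5P, Pc/IgG, and the hypertranscription statistic

`promoter_counts()` counts fragments per promoter per replicate;
`replicate_correlation()` gates merging on pairwise Pearson r of
log2(CPM+1) (threshold 0.8), and replicates are merged by summing.
`ma_stat()` produces the difference-versus-average table per promoter:
D = CPM(old) − CPM(mid), A = log10 of the mean CPM, ranked by descending
D (raw-count mode behind a flag). Significance uses the exact Poisson
rate test (`poisson_rate_test()`): conditional on the total, the second
count is binomial with probability proportional to its library size, and
the two-sided p sums all outcomes no more likely than the observed one.
Pc-versus-IgG promoter comparisons use mean genome-normalized track
values over promoters (`track_score_intervals()`) and descending quartile
ranks with ties sharing the better quartile (`quartile_rank()`).

# Composition testing

`composition()` tabulates proportions per age; `permutation_test()` tests
a focal type's proportion difference between two ages by shuffling age
labels (10,000 permutations, add-one p estimator, so the smallest
attainable p is 1/10,001). Cells are the permutation unit; a chi-square
mode over the full age x type table is provided as an alternative
statistic.

# The synthetic world: what it emulates and what it does not

The generator plants, deterministically per seed:

* a 4 Mb genome (2 chromosomes), 400 non-overlapping genes of 2–10 kb,
  300 enhancers, one 10 kb blacklist region, and a tandem histone array
  (10 units x His1/His2A/His2B/His3/His4 promoters);
* 22 domains shared by all three cell types, pairwise-shared marker
  domains (the marker gene of each type is repressed in the *other* two
  types), and 6/8/12 type-specific domains for ISC/EB, EE and EC, each
  spanning 1–2 genes plus 400 bp flanks;
* singlet cells at exactly the configured counts per (type, age):
  young 55/45/150 (ISC/EB, EE, EC), mid 75/45/130, old 130/45/75, so the
  progenitor share grows from 22% to 52%; lognormal depths (median 250
  fragments, enterocytes x3 for polyploidy); each cell draws 80% of its
  fragments from its (type, age) domain set and the rest uniformly;
* graded age changes: gain domains are weak in young cells (sampling
  weight 0.1 for EC, 0.35 for EE/ISC-EB) and strengthen at their onset
  age, losses mirror that; enterocytes change at both mid and old age
  and therefore separate by age in clustering, while EE and ISC/EB ages
  mix — with planted differential gene budgets 21/4/2 preserving the
  enterocyte >> enteroendocrine >> ISC/EB ordering;
* per-cell, per-domain Gamma(shape 4) weight jitter, a simple model of
  variegated silencing that sets the within-type spread;
* 5% doublets (merged draws of two same-age cells, pair types
  proportional to type frequencies, same-type allowed) and 2% blacklist
  artifact cells whose planted blacklist fraction always exceeds the 0.2
  QC cutoff;
* bulk replicates (4 per age): RNAPII-S5P Poisson counts per promoter,
  histone promoters multiplied by 10 in old age with base rates
  His2A/His2B 60 >> His3/His4 25 >> His1 8 per replicate (so His2A/His2B
  gain the most, His1 least); Pc peaks on a fixed 30% promoter subset,
  constant across ages; IgG uniform background. Replicates are pure
  Poisson by default, with a Gamma overdispersion knob;
* an 8 bp consensus motif embedded in 80% of age-changing enhancers and
  5% of stable in-domain enhancers, plus 4 decoy PWMs, on an i.i.d.
  uniform genome sequence.

The scale (about 750 singlets, 4 Mb) is chosen so the full pipeline runs
in well under a minute while every recovery statistic has adequate power;
the per-age fragment totals also keep the uniform background sparse
enough that signal-block decomposition is meaningful, which is a real
property of the assay (CUT&Tag backgrounds are sparse) that the generator
must respect at reduced genome size.

What the generator does not emulate: Tn5 insertion sequence bias, PCR
duplication, barcode collisions, chromatin-state-dependent fragment
lengths (fixed at 150 bp), batch effects between chips, ambient
contamination, or realistic promoter sequence composition. Passing the
recovery suite therefore shows the pipeline's statistics are implemented
correctly and are well calibrated under the planted model — not that they
are robust to every artifact of real data.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout; bookended intervals merge
  (bedtools semantics) but do not overlap for counting.
* All-zero tracks normalize to all-zero with a warning; empty block lists
  threshold to empty domain sets; AUC ties at the threshold are all kept.
* Constant rows z-score to zeros and are flagged; empty pseudobulk groups
  are dropped with a warning, never silently.
* The common-dispersion estimate is clamped at 0 (Poisson) with a warning
  when the method-of-moments value is negative.
* `threshold_blocks()` keeps `ceiling(f * n)` blocks; `quartile_rank()`
  uses minimum ranks so ties share the better quartile.
* Every stochastic step takes an explicit seed, and `run_pipeline()`
  writes a JSON manifest (parameters, seed, input hashes) per step; a
  rerun with the same config and seed reproduces outputs byte for byte.

# Validation problem sizes

The test and acceptance suites use: the default synthetic dataset (seed
given on the command line) for domain recovery, clustering, typing, QC,
doublet and motif recovery; 2,000 features x 2 replicates per condition
for differential calibration and power; 10,000 draws for the Poisson rate
test's size; widths 4 and 6 with full 4^w enumeration for motif p-values;
and 200 repeats x 10,000 permutations (1,000 cells per age) for
permutation-p uniformity.

# Known limitations

* The doublet AUROC bound is structural (see above): with same-type
  doublets allowed at realistic compositions, roughly 40% of doublets are
  profile-invisible, capping AUROC near 0.8 at this scale.
* The NB Wald test with two replicates per condition relies on the pooled
  dispersion; features whose variability deviates strongly from the
  common value (e.g. residual doublet contamination concentrated in one
  group) can reach nominal significance.
* Cluster-level CSS is the mean of per-cell CSS, not a pseudobulk
  recomputation; per-cell scores stay inspectable but are noisier for
  small clusters.
* The permutation test treats cells as exchangeable units; if cells
  within a chip are correlated, the test is anticonservative at the chip
  level.
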