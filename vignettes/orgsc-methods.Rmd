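---
title: "Models, parameters and validation design in orgsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and validation design in orgsc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each stage of the package, the
parameters that matter (with defaults and why), the design choices made
where the procedures were genuinely open, what the synthetic-data
generator does and does not emulate, and the problem sizes used by the
test and validation runs.

## Quantification model

An STRT-style multiplexed library puts, for each cell, an 8-nt cell
barcode and an 8-nt unique molecular identifier (UMI) at the start of
read 2 (the sequenced orientation of the barcode-RT primer, whose 3' end
is an oligo-dT stretch), while read 1 carries cDNA behind a
template-switch oligo (TSO) and runs into the poly-A tail. Quantification
is molecule counting: after demultiplexing and gene assignment, the
expression of gene *g* in cell *c* is the number of **distinct** UMI
strings observed for (*g*, *c*). Deduplication is exact-string and scoped
per gene — the same UMI on two genes counts once for each — and no
network/directional collapsing of sequencing-error UMIs is attempted,
because at the error rates the generator emulates the planted counts are
exact and any collapsing rule would be untestable against them. Barcode
matching is exact by default; a rescue mode accepts barcodes at Hamming
distance 1 from a *unique* whitelist entry (ties reject), and is off by
default as the more conservative reading.

Read-1 processing removes a TSO prefix when a suffix of the TSO overlaps
the read start by at least 10 nt, then a trailing poly-A run of at least
10 bases (one internal mismatch allowed), then rejects reads with more
than 10% N bases, reads containing a configured adapter (defaults: the
ISPCR and library-PCR oligos), or reads shorter than 30 nt after
trimming. The 10-nt overlap, the poly-A run definition and the 30-nt
minimum are package choices where the procedure is conventionally
under-specified; all are arguments.

Gene assignment replaces genome alignment — out of scope here — with a
unique-k-mer majority vote (k = 21) against a toy reference whose
transcripts are constructed to share no k-mers, so exact fragments vote
unambiguously and fragments with a few substitutions still carry a
majority of intact k-mers.

## Normalization, filters, saturation

Expression is `log2(TPM/10 + 1)` with TPM = UMIs per million per cell: no
gene-length term (UMIs count molecules), and the /10 compensates for the
fact that per-cell molecule counts are far below one million, preventing
each molecule from being counted several times over on the per-million
scale. The value is 0 exactly when the raw count is 0, and the transform
is invariant to per-cell count scaling.

The cell filter removes cells with fewer than `min_genes_per_cell`
detected genes (raw count >= 1; default 2000 for genome-scale data); the
gene filter then removes genes *expressed* (normalized value >= 1) in
fewer than `min_cells_per_gene` cells (default 3). The two stages run in
that order and are idempotent. Whether a cell with exactly the threshold
count is kept is genuinely ambiguous in common usage ("fewer than" vs "at
most"); the default keeps it, and `cell_boundary = "drop"` selects the
other convention. "Detected" (raw >= 1) and "expressed" (normalized >= 1)
are deliberately distinct notions, mirroring how the two filters are
usually phrased.

Highly variable genes are those with mean normalized expression > 1 and
dispersion > 1, with dispersion defined as variance/mean of the
normalized values — the simplest definition consistent with those two
unit thresholds; no mean-binning is applied.

The saturation analysis gives every accepted read one uniform draw and
keeps it at fraction *f* iff the draw is <= *f*. Subsamples at increasing
fractions are therefore nested, making the detected-gene curve monotone
non-decreasing by construction rather than on average; at *f* = 1 it
equals full detection. Detection means a post-deduplication count of at
least `detection_min_count` (default 1) in at least one cell.

## Regulon activity

A regulon is a transcription factor together with its target genes (the
TF is a member of its own set). For one cell, all genes are ranked by
descending expression — ties broken by stable gene order, so the score is
deterministic — and the recovery curve R(i) counts regulon genes among
the top i ranks. The activity score is the area under R over the top
`top_fraction` of the ranking (default 0.05, the conventional window for
this statistic), scaled so that a regulon occupying the top ranks scores
1 and a regulon absent from the window scores 0. Only ranks enter, so any
strictly monotone transform of the expression vector leaves the score
unchanged.

Binarization fits, per regulon, a two-component Gaussian mixture
(unequal variances) to the AUC values across cells and thresholds where
the posterior probability of the upper component crosses 0.5 between the
two means. When the fit fails or collapses to one component, the fallback
is the regulon's 0.75 quantile, with a warning; constant columns are all
zero. The mixture default reflects the bimodal on/off structure regulon
AUCs show when a regulon is active in a subset of cells; the exact scheme
is a parameter because no single convention exists.

Top TFs for a cluster are ranked by mean binary activity inside the
cluster minus mean outside — a bigger difference ranks higher — with
lexicographic tie-breaks for determinism.

## Recursive clustering

Each node of the tree is processed as follows.

1. **Bipartition.** Pairwise distance 1 − Pearson *r* between samples,
   average-linkage agglomeration, cut at two clusters. Average linkage is
   the package default (the choice is open; complete linkage is an
   argument). On an expression matrix, highly variable genes are
   re-selected within the node first. Zero-variance samples, whose
   correlations are undefined, are attached to their nearest Euclidean
   neighbor's side and logged.
2. **Feature selection.** Ten random forests, each trained with one fold
   held out, rank features by mean impurity importance; the top
   `num_features` (default 100) are retained for the node.
3. **Gated training and relabeling.** A forest on the initial labels
   yields out-of-bag own-class vote probabilities; samples above the
   training gate (0.6, strict) form the training set, whose classifier
   relabels all remaining samples. "Internal vote probability" is read as
   the forest's held-out/out-of-bag vote fraction for the sample's
   class — the only forest quantity matching that phrase.
4. **Repeated CV and pruning.** Over `cv_runs` repetitions of
   `cv_folds`-fold cross-validation (defaults 100 × 10), each sample
   accumulates a mean held-out vote probability for its assigned class;
   samples below the retention gate (0.55, strict) are discarded as
   unassigned — reported, never reassigned. Step-2 features are reused
   across folds within a node.
5. **Recursion** into each child with at least `2 * min_leaf` samples.

Termination is necessarily a package design (no standard criterion
exists): a branch becomes a leaf when it is too small (`min_leaf` 10),
too deep (`max_depth` 6), unsplittable (degenerate bipartition, empty
training class, or one-class prediction), or below the split-quality
gate. **Split quality** is the mean cross-validated own-class vote over
retained samples, gated at 0.9. A plain CV accuracy over retained samples
cannot serve here: retention already conditions on votes >= 0.55, so such
an accuracy is ~1 by construction even on homogeneous noise, where the
initial labels are a circular function of the very features the forest
sees. The mean retained vote separates the two regimes cleanly in
simulation (about 0.77–0.83 on homogeneous nulls versus >= 0.94 on
genuinely split nodes), which is what lets a homogeneous population
terminate as a single leaf.

A related honest caveat: the 0.55 retention gate sits barely above the
0.5 coin flip, and because step 3 assigns each ambiguous sample to the
side the forests already favor, even maximally ambiguous samples
(half-and-half mosaics of two class profiles) receive mean votes around
0.5–0.7 and are discarded only about half the time. The gate removes the
most conflicted tail, not every intermediate sample; the tests assert the
vote-separation property rather than a high discard rate.

Determinism: one master seed fans out deterministically to per-node,
per-run streams (forests run single-threaded with fixed seeds), so the
full tree is reproducible.

## Markers

For gene *g* and cluster *k*, the AUC is the probability that a random
in-cluster cell exceeds a random out-of-cluster cell (midrank ties count
half), computed via the Mann–Whitney construction; classification power
is `2·|AUC − 0.5|`. A gene is reported iff |mean difference| of
log2-normalized expression >= 1 (equivalently fold change >= 2 or
<= 0.5 on the linear scale) **and** power >= 0.4. The effect size is a
difference of log-scale means (the common convention for log-normalized
single-cell data); ratio-of-means is available as an alternative reading.
No multiple-testing correction applies — the rule is threshold-based, not
p-value-based. An optional minimum expressed fraction per cluster
(`min_pct`) is off by default.

## Scores and state calls

Panel scores are arithmetic means of normalized expression over panel
genes present in the matrix; absent genes are dropped with a warning
rather than an error (gene symbols drift across annotations). Cells with
G1/S and G2/M scores both < 2 are quiescent; otherwise the cell is G2/M
iff its G2/M score strictly exceeds G1/S (ties go to G1/S). The E/M
hybrid call requires both *Epcam* and *Vim* strictly above 2. All
boundary behavior is pinned by truth-table tests.

The pseudo-developmental axis is PC1 of the centered (not scaled)
expression of a cell subset. A PCA axis has arbitrary sign, so PC1 is
oriented to correlate non-negatively with the per-cell detected-gene
count — a proxy anchored to the transcriptome breadth that rises as the
developmental program switches on; when that anchor is degenerate (every
gene detected everywhere) the sign of the largest gene loading breaks the
tie, keeping the orientation invariant to cell order.

The default E/M/S and cell-cycle panels ship as an editable TSV
(`inst/extdata/panels_default.tsv`): epithelial junction/cytoskeleton
genes (Cdh1, Tjp1, claudins, Ocln, cytokeratins, type IV collagen),
mesenchymal genes (Vim, S100a4, Acta2, Fn1, Cdh2, type I/III collagens),
a stemness set drawn from the "stem cell population maintenance" GO
term, and the standard core 43-gene G1/S and 54-gene G2/M sets in mouse
symbol case. They are declared package defaults, not assertions about any
particular study's exact membership, and every scoring function accepts
arbitrary panels.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume:

* **Counts**: negative binomial with dispersion 0.2 (typical for UMI
  data; 0 gives Poisson), per-cell log-normal library sizes (mean 20,000
  UMIs, CV 0.4), per-gene log-normal baseline abundances.
* **Groups**: `n_groups` major groups with optional nested subclusters;
  5 marker genes per group at fold 8; per-group regulons (5 per group,
  10 targets each, fold 4 in the active group) whose targets are
  co-expressed — a regulon screen on real data yields tens to hundreds
  of regulons, and the binary activity matrix needs that dimensionality
  for groups to be genuinely well separated.
* **Pseudotime**: uniform on [0, 1] within each group. Score panels (8
  genes each, baseline boosted 4×) change by `gradient_slopes` log2
  units per unit pseudotime (default −2 for E/M/S). A broad
  **developmental program** of 100 further genes switches on (60%) or
  off (40%) along pseudotime with slope 4 in on/off form — up-genes rise
  *towards* their baseline, down-genes fall *from* it — which keeps the
  per-cell abundance denominator nearly constant (so zero-slope panels
  stay uncorrelated with time) while making PC1 of a group track latent
  pseudotime and the detected-gene count rise along it, anchoring the
  PC1 orientation convention. This emulates the property that the first
  principal axis of a developing cell population orders cells by
  developmental time.
* **Reads**: one read pair per molecule with distinct UMIs drawn without
  replacement within each (gene, cell) — so planted counts equal
  distinct-UMI counts exactly and the round-trip oracle is
  deterministic; configurable PCR-duplicate fraction (duplicates reuse
  molecules), per-base substitution errors, and a fraction of reads
  degraded with 15% N. Read 1 is TSO + a uniformly placed 80-nt fragment
  + 25 A's; read 2 is barcode + UMI + poly-T; qualities are constant
  Phred+33 'I', and read lengths are package defaults since such
  conventions vary by run.

It does **not** emulate realistic error profiles, splicing, ambient RNA,
doublets, batch structure, or gene–gene correlation beyond the planted
blocks — so passing tests demonstrate correctness of the computations and
recoverability of planted structure, not robustness to every artifact of
real libraries.

## Benchmark sizes and numerical choices

The validation runs use desk-scale sizes chosen to make the statistics
stable: quantification round-trip at 50 cells × 200 genes (~50,000 read
pairs); dedup oracle on 10,000 random triples; rank-statistic oracles on
100 (AUC) and 50 (roc) random instances; clustering recovery on 400
cells (100 per group) over 5 seeds with `cv_runs = 20` and 100 trees per
forest — a documented reduction of the 100 × 10 CV protocol that leaves
vote estimates stable at these node sizes — plus a 5-seed homogeneous
null; marker recovery on 400 cells over 5 seeds; gradient recovery on
600 cells over 10 seeds. Tolerances: oracle comparisons are exact to
floating point (1e-12); stochastic recoveries assert the planted sign
and magnitude bounds stated with each test.

Degenerate inputs are handled explicitly rather than by accident:
zero-total cells error by name in normalization; constant AUC columns
binarize to zero; constant score vectors report NA correlations;
zero-variance samples in the bipartition are attached by nearest
neighbor; empty panel intersections error with the panel name.

## Known limitations

* Gene assignment is exact-k-mer voting against a toy reference; it is
  not a spliced aligner and is not meant to process real genomes.
* The recursive clustering inherits the circularity of all
  cluster-then-classify procedures: cross-validated votes can ratify a
  partition of pure noise, which is why the split-quality gate uses the
  mean retained vote rather than a CV accuracy (see above).
* UMI deduplication ignores sequencing errors inside the UMI itself;
  with error rates high enough to corrupt UMIs, counts inflate.
* The binarization mixture assumes two Gaussian components; regulons
  active in graded rather than switch-like fashion get a threshold that
  is well-defined but less interpretable.
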