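---
title: "Calling kilobase-scale A/B compartments by direct interaction preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling kilobase-scale A/B compartments by direct interaction preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcall)
```

## The problem

Chromatin partitions into two spatial neighborhoods — the active A and
inactive B compartments — visible in Hi-C maps as a plaid (checkerboard)
enrichment pattern: loci of the same compartment contact each other more
often than expected at their genomic distance. The standard caller takes the
first principal component (PC1) of the correlation matrix of the
distance-normalized (O/E) contact map. PC1 targets the dominant axis of
*global chromosomal variance*, which has two well-known failure modes:

* at kilobase bin sizes the map is so sparse that the correlation matrix
  degenerates and PC1 returns nothing usable — fine-scale calling then
  demands extreme sequencing depth;
* whenever another variance component dominates (chromosome-arm-level
  contact enrichment is the classic case), PC1 reports that component
  instead of compartments.

`abcall` instead scores each bin *directly*: how much more does this bin
contact the A-like reference environment than the B-like one? This per-bin
statistic needs no global decomposition, degrades gracefully with depth, and
is refined iteratively from coarse to fine bin sizes so that kilobase tracks
remain dense at modest depth.

## The preference score

Let `e(d)` be the chromosome's mean contact count at bin distance `d` (the
O/E denominator), and let A and B be the current reference bin sets. For bin
`i`, every reference bin `j` at distance at least `min_distance_bins`
contributes the shrunk per-pair log-ratio

```
x_ij = log( (c_ij + 1/2) / (e(|i-j|) + 1/2) )
```

with weight `w_ij = e / (1 + e)`. The reference-set summaries are geometric
means, `abar = exp( weighted mean of x_ij over j in A )` and `bbar`
likewise over B, and the score is the bounded contrast

```
s_i = (abar - bbar) / (abar + bbar)   in [-1, 1],  A-positive.
```

Three numerical choices matter and are worth stating plainly:

* **Saturating precision weights.** A pair's O/E ratio has Poisson sampling
  variance roughly `1/e`, so sparse pairs are weighted by their precision
  `e`; without this, a single contact at a rare distance can swing a bin's
  score on a shallow map (equal-weight means visibly oscillate during
  refinement at low depth). The weight saturates at one expected contact so
  that on deep maps every reference bin gets an equal vote — pure
  precision weighting would concentrate the statistic on near, high-`e`
  neighbors and make it local rather than compartmental.
* **Log scale.** A multiplicative confounder shared by a subset of
  reference bins — the arm-level enrichment above — multiplies into an
  arithmetic mean but only *adds* to a log mean, so its influence is
  bounded by the arm-composition imbalance of the reference sets rather
  than by the factor's size. On simulated maps with a strong arm factor
  the arithmetic contrast drifts to the arm pattern while the geometric
  contrast recovers the planted compartments at every layout we tested.
* **Short-range exclusion.** Contacts within `min_distance_bins` (default
  10 bins, capped at a quarter of the chromosome so short chromosomes stay
  scorable) are excluded: TAD-scale structure lives there and is not
  compartment signal. A bin never scores against itself.

## Iterative refinement and the resolution cascade

Starting from a GC-content median split per chromosome (GC is the field's
standard A-orienting covariate; without it, the eigenvector baseline seeds
the labels), every unmasked bin is scored against the current reference
sets and labels are reassigned, until fewer than `convergence_frac` of bins
flip or `max_iter` is reached. Two stabilizers:

* **Hysteresis.** Zero-score and unscorable bins keep their previous label,
  preventing oscillation.
* **Evidence-gated flips.** A labeled bin flips only when
  `|s_i| > flip_evidence_z / sqrt(coverage)` (default `z = 2`, coverage =
  contacts entering the score) — about two sampling standard deviations.
  Within that band the sign of the score is simply not identified, so the
  current assignment stands and supplies the sign of the reported score.
  On deep maps the threshold is negligible; on shallow maps it is what
  stops the iteration from destroying a good initialization.

The cascade then walks a descending resolution ladder (default 250 kb →
50 kb → 25 kb → 5 kb → 1 kb). Each finer rung starts from the parent rung's
labels projected onto its bins; bins whose coverage falls below
`min_contacts_per_bin` (default 10 contacts) are not re-estimated but
inherit the parent's score, flagged `inherited` — this is what keeps 1 kb
tracks dense at depths where per-bin estimation is impossible. The coarsest
rung, having no parent, scores every covered bin regardless of the floor.

When a GC track is available the cascade also guards against basin capture:
at each rung refinement is run both from the parent projection and from the
GC prior, and the result more coherent with GC is kept (the
parent-initialized one is preferred within a 0.1 correlation margin). This
matters exactly in the arm-confounded regime: compartment blocks smaller
than a coarse bin are diluted by aggregation while the arm factor is not,
so the coarse rung can converge to the arm pattern and would otherwise hand
every finer rung the wrong fixed point. A rung whose track correlates with
GC at less than 0.1 in absolute value is additionally flagged incoherent,
and finer rungs restart from the GC prior.

All tracks are sign-oriented so that their correlation with GC is
nonnegative; a global sign flip of the initialization therefore does not
change the result.

## The eigenvector baseline

`eigenvector_compartments()` implements the conventional caller in its
correlation-of-O/E dialect: PC1 of the Pearson correlation matrix of the
unmasked O/E rows, rescaled to maximum absolute score 1, GC-oriented.
Zero-variance rows are masked, not imputed — imputation would hide exactly
the sparsity failure the baseline is meant to exhibit. A track is flagged
`incoherent` when more than half its bins are masked or its |GC
correlation| falls below 0.1. Absent-distance entries are imputed with the
matrix mean so the output is invariant to positive rescaling of O/E.

## Track statistics

* `msd()` — mean squared score difference on the shared unmasked support;
  `iqr = TRUE` IQR-normalizes both tracks first and is the right mode for
  cross-method comparisons, since preference scores and PC1 live on
  different scales. `passage_replicate_ratio()` compares biological-passage
  variability against replicate variability.
* `iqr_normalize()` — `(score - median) / IQR` over unmasked bins.
  Quantiles use mid-interpolation (R type 5), under which the score vector
  `(-1, 0, 0, 1)` has IQR exactly 1 and is its own normalization.
* `classify_flips()` — partitions bins into AA/BB/AtoB/BtoA/unscored by the
  sign pair of two tracks; `relative_contact_ratio()` adjudicates flip bins
  by the geometry of the map itself (geometric-mean A-contact over
  B-contact, same exclusion radius as the score).
* `metagene_profile()` — IQR-normalized track averaged over scaled gene
  coordinates, `n_points` samples in each of the upstream flank (one gene
  length), body, and downstream flank, strand-aware, with per-position SD.
  Pausing status is an *input* label: the nascent-transcription data that
  defines it is outside this package's scope; the simulator plants it.

## Single-cell mode

`call_compartments_cell()` calls compartments on one cell's contact list at
25 kb by default. Per-cell maps are orders of magnitude sparser than bulk,
so three things change: the decay curve is estimated in 50 log-spaced
distance bands (individual diagonals are empty); a single scoring pass is
run from the GC split with the evidence gate disabled (`z = 0`) — the call
is meant to be the cell's own data speaking, with the GC split only
defining the reference sets; and uncovered bins are masked, never
inherited, so per-cell sparsity stays visible.

Gene-level summaries (`gene_scores()`), group-difference rankings
(`rank_differential_genes()` — a ranking by difference of group means, not
a test; the downstream use is a top-`size` signature, not per-gene
inference), signature scoring, and `roc_auc()` (Mann-Whitney tie
convention) build the cell-type classification layer. Signatures should be
built on a training split and evaluated on held-out cells; building them on
all cells flatters the AUC.

## Regulatory statistics

`interval_compartment_fraction()` calls an interval A/B by the mean score
of its overlapping unmasked bins (on the *raw* track — normalization
shifts the zero). `delta_track()` is the focal condition's IQR-normalized
score minus the mean of the others. `unique_interval_enrichment()` tests
condition-uniqueness of interval sets by shuffling interval-to-condition
assignments over the pooled set (`n_perm` times, add-one one-sided p in the
A-gain direction) — genomic positions are preserved, so the test asks
specifically whether *this condition's* intervals carry more focal signal
than a random assignment would. One consequence worth knowing: when one
condition carries a strong planted shift, the pooled null is contaminated
and the *other* conditions can also reach small p (their intervals sit
above the pooled average); calibration under a global null is uniform.
`tf_activity_rank()` scores transcription factors by the mean differential
signal at their motif sites and over their target-gene bodies, converts
each component to a rank, and aggregates by mean rank — rank aggregation is
scale-free, which matters because the two components live on different
supports.

## The simulator

`synthetic_map_spec()` plants alternating A/B blocks with geometric lengths
(mean 10 bins) on a 10 Mb / 25 kb chromosome by default, contact weights
`|i-j|^decay * affinity^[same label]` (defaults −1.0 and 2.0, the plaid
regime of real maps), and draws exactly `depth` contacts multinomially —
multinomial rather than per-pair Poisson so depth-titration experiments
compare identical totals. Optional components: `arm_split` multiplies
same-arm pairs by `arm_boost` (default 6, chosen so the arm factor
dominates chromosomal variance — the regime where PC1 misassigns — while
affinity-2 compartments remain recoverable by direct scoring);
`condition_shift` flips a set of bins in a second condition, and
`sample_block_shift()` picks whole blocks so the shifted condition is still
block-structured, as real cell-type differences are; `tss_bins` add
promoter-restricted A-affinity for the paused-gene metagene fixture; GC
tracks map labels to 0.55/0.40 with noise SD 0.03, informative but
imperfect like real GC.

What the simulator does *not* model: TADs and loops, balancing biases,
trans contacts, duplicate reads, and mappability gaps. Tests passing on it
show that the estimator, the cascade, and the statistics behave as designed
under a known plaid ground truth — not that every real-data artifact is
handled.

## Problem sizes and practical limits

The test and acceptance workloads run on single chromosomes of 400–800
bins (10–20 Mb at 25 kb) at depths from 10^3 to 10^7 contacts, 20–40
simulated cells at 50,000 contacts each, and 500-repetition permutation
calibrations; the full suite and the acceptance script each complete in
about a minute on one CPU. O/E matrices are held dense per chromosome, so
memory grows with the square of bins per chromosome — comfortable to a few
thousand bins per chromosome; genome-wide 1 kb analyses of mammalian
chromosomes would need a sparser O/E backend than this implementation
carries.

Input formats are the 4-column pairs text dialect (1-based positions,
optionally gzipped) and a plain-text bin-pair triples format with optional
balancing weights; binned HDF5 containers are not read directly — dump them
to triples first. Balancing weights, when present, are applied
multiplicatively before O/E; raw counts are the default, as single-cell
lists are never balanced.

## Known limitations

* Intrachromosomal signal only; no subcompartments (two states), no
  TAD/loop calling.
* The GC-coherence guard assumes GC is a valid compartment orienting
  covariate, which is the field convention but can be locally violated;
  without a GC track the cascade has no arbiter against confounded basins
  and the coarse rung's basin wins.
* The per-cell mode's single pass trades refinement for transparency;
  cells below `min_cell_contacts` (default 5,000) are skipped, not
  rescued.
* `label_accuracy()` reports the better of the two global orientations by
  default, which is the honest metric for sign-ambiguous callers but
  should be read accordingly.
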