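---
title: "Methods: identifying and analysing DMSP-lyase homologs"
author: "dlhscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and analysing DMSP-lyase homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlhscan)
```

`dlhscan` identifies eukaryotic DMSP-lyase homologs (DLHs) among protein
sequences, builds their phylogeny, and analyses their biogeography and
expression. This vignette explains the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The classification model

A protein is called a DLH when three independent lines of evidence
coincide:

* **Racemase-domain profile hit.** The Asp/Glu/Hydantoin racemase domain
  shared by DLHs and bacterial racemases is modelled as an ungapped
  position-specific scoring profile: per-column log2 odds of gap-excluded
  residue frequencies (pseudocount 0.1) over a uniform background,
  restricted to seed-alignment columns with at least 50% occupancy.
  Scanning slides the full profile along the sequence; windows at or
  above the calibrated threshold are reported, and overlapping candidates
  are merged keeping the higher score. Sequences shorter than the profile
  are slid along the profile instead, paying `gap_penalty` bits (default
  2) per uncovered profile column. Ungapped scanning trades alignment
  fidelity for a completely specified, fast algorithm; the profile's job
  here is ranking power, not homology-quality alignment. The bundled
  consensus used by the generator and examples is synthetic (see
  `synthetic_racemase_consensus()`): it stands in for the real conserved
  domain, which cannot be redistributed, and shares no sequence with it.
* **Canonical cysteine pair.** The two catalytic cysteines carry the
  contexts `[D/N]CGF` and `ECT[E/Q]`. Both must be present, with the
  `[D/N]CGF` site upstream of the `ECT[E/Q]` site by default
  (`require_order = TRUE`), mirroring their arrangement (C108 before
  C265) in the one biochemically characterized enzyme. The order
  requirement is configurable because sequence rearrangements, while
  unobserved, cannot be excluded a priori. Spacing between the sites is
  deliberately unconstrained. `X` residues never match a context.
* **Discriminative motifs.** At least `min_motifs` distinct motifs from a
  bank must match. The default of 5 out of 10 is a majority rule: the
  catalogue evidence does not tabulate per-motif presence, so requiring
  all 10 would be arbitrary strictness and requiring 1 arbitrary
  leniency. The parameter is prominent in every interface because it is a
  genuine open choice.

Domain duplication is flagged when two or more non-overlapping profile
hits survive merging. Two detection regimes matter: at the default
`fpr = 0.01` a long non-domain stretch has about a 1% chance of a
spurious second hit, which blurs duplication *counting*; analyses whose
object is the duplication fraction itself should calibrate the profile
strictly (`fpr = 0.001`), which the bundled acceptance computations do.

### Threshold calibration

The profile threshold is set from a decoy set as the smallest best-hit
score attained by at most a fraction `fpr` of decoys. This is the
`1 - fpr` decoy quantile made tie-aware: with a degenerate
(identical-sequence) seed alignment, scores live on a coarse lattice and
a plain interpolated quantile can sit *on* a tied value, letting every
tied decoy through (observed 2.9% at nominal 1%). Taking the smallest
score whose exceedance frequency is ≤ `fpr` preserves the guarantee under
ties and reduces to the usual quantile for continuous scores.

## Discriminative motif discovery

The discovery algorithm is deterministic given a seed:

1. Positives and controls are each split in half (train/hold-out) by a
   seeded shuffle.
2. For every width w in 4–15, every w-mer occurring in ≥20% of training
   positives becomes a candidate seed.
3. Each seed's position weight matrix is built under a zero-or-one
   occurrence model: a training positive contributes its best-matching
   window only when that window is an exact seed occurrence, otherwise it
   contributes nothing. Pseudocount 0.1; background residue frequencies
   are pooled over the controls, because the background to discriminate
   against is the bacterial racemase family, not uniform chance.
4. The match threshold is the seed's occurrence score when it clears
   every training-control best score, else just above the control
   maximum — maximum sensitivity at zero training false-positive rate.
   Thresholds that admit training controls are dominated: under the
   zero-or-one model they add false positives without adding occurrence
   sensitivity. (An earlier variant that let all sequences contribute
   "best windows" to the PWM and searched thresholds for maximal
   training discrimination overfitted the training positives' own
   background and recovered planted motifs in only 6/20 runs.)
5. Significance is a one-sided Fisher exact test (hypergeometric tail)
   on the hold-out 2×2 table — sequences with ≥1 match versus without,
   positives versus controls — multiplied by the number of seeds tested
   (a Bonferroni-style E-value; simple, conservative, reproducible).
6. The best motif with E below `alpha` is accepted; ties resolve by more
   hold-out positive matches, then larger width, then lexicographic
   consensus. The width step matters: a fragment of a planted motif
   produces the *identical* hold-out table as the full motif, so
   significance and match count cannot separate them, and lexicographic
   order alone would pick an arbitrary fragment. Matches of the accepted
   motif are masked with `X` in all positives and discovery repeats.

Known limitation: because significance is counted at the sequence level,
a fragment seed can beat the full motif outright when a chance exact
occurrence of the (shorter) fragment lands in a hold-out positive and
none lands in a hold-out control. At width 4–5 this happens in roughly
10–15% of runs on the benchmark conditions (planted width-8 motif,
penetrance 0.6, 100 + 100 sequences). The exact-occurrence thresholds
also mean the discovered models match conservatively; degenerate motif
variants below exact-match score are not recalled.

`logo_matrix()` converts a motif to letter heights in bits: per column,
information content `IC = log2(20) − H` with no small-sample correction,
heights = frequency × IC. Matrices are exported as TSV; graphical
rendering is out of scope.

## Phylogeny

Sequences are cut to their domain hit, aligned externally (alignment
construction is deliberately not re-implemented; any aligner producing
aligned FASTA works), and columns with fewer than `min_occupancy = 10`
residues are removed — the column rule that cleans lineage-specific
extensions. Only the stated column rule is applied; no additional
terminal trimming is inferred.

Distances use pairwise gap exclusion; `X` counts as a mismatch
(consistent with identity calculations, where `X` never matches).
Three models are available: p-distance, Poisson `−ln(1 − p)`, and the
protein Kimura correction `−ln(1 − p − 0.2 p²)` (default, matching the
behaviour of the classic alignment program whose neighbor-joining
implementation the pipeline mirrors; the model itself is otherwise a
free choice and all three are exposed). Saturated pairs (log argument
≤ 0) are capped at `max_distance = 10` rather than erroring, so single
saturated pairs do not abort a tree; a pair with *no* scored columns is
an error naming the pair, since no defensible distance exists.

Neighbor-Joining follows the canonical Saitou–Nei agglomeration.
Numerical choices: negative branch lengths are clamped to zero with the
deficit transferred to the sister branch, preserving path lengths; ties
in the Q criterion resolve by the lexicographically smallest pair of
subtree representative labels (each subtree represented by its smallest
tip label, C-locale collation). Tie-breaking on labels rather than row
positions makes the tree — and bootstrap supports — invariant to the row
order of the input, which row-index tie-breaking violates whenever exact
distance ties occur (common for near-identical sequences). Bootstrap
support resamples columns with replacement (seeded), rebuilds the tree,
and maps bipartition frequencies onto the full-data tree only; no
consensus tree is built. Replicates with a degenerate distance matrix are
skipped, counted, and excluded from the support denominator.

## Ecology

* **Abundance** is percent of mapped reads: `100 × count / total mapped`
  per sample.
* **Correlations**: per (taxon, region, variable), the taxon's gene
  abundances are summed per sample within the region and
  Spearman-correlated with the variable using pairwise deletion of
  missing values; cells with fewer than 3 usable samples are `NA`.
  Correlation is per sample, not per station-averaged depth profile; a
  depth-averaging alternative would pool real vertical structure and is
  intentionally not the default. The p-value uses the t approximation
  with n − 2 degrees of freedom; Benjamini–Hochberg correction is applied
  across the full emitted grid, the standard choice for a grid of
  correlations.
* **Size factors** are median-of-ratios: reference = per-gene geometric
  mean over samples (genes with any zero excluded; `poscounts` handles
  the all-zeros-somewhere case), factor = median of count/reference. The
  estimator is implemented directly rather than calling the package that
  popularized it; the package implementation serves as an independent
  cross-check in the tests. Note the scaling behaviour: multiplying one
  sample by k scales its factor *relative to any other sample* by exactly
  k (the geometric-mean reference itself shifts by k^(1/m)).
* **Fold change** is the ratio of mean normalized counts with a
  pseudocount of 0.5 on both means, keeping all-zero genes at fold 1.
* **Depth-differential expression** splits samples at `boundary_m = 200`
  (euphotic ≤ 200 m, mesopelagic > 200 m; configurable), computes per
  gene the difference of zone means of `log2(value + 0.5)`, and obtains
  two-sided p-values by seeded permutation of the zone labels
  (`(1 + #{|perm| ≥ |obs|}) / (B + 1)`), followed by BH correction. A
  permutation test was chosen because the claim being tested
  ("significantly expressed in a zone") names no parametric test;
  permutation is assumption-light and exactly reproducible given the
  seed. With 6 + 6 samples the attainable p-value floor is ≈ 1/924 of
  distinct label splits, so at least ~2000 permutations are needed for
  BH-corrected calls at alpha 0.05.

## The synthetic-data generator

The generator replaces the external sequence databases and ocean survey
tables with data of known structure:

* `generate_protein_sets()` builds positives (noised synthetic domain
  with both cysteine contexts planted at spacing 80–130, ten motifs of
  widths 6–10 planted at penetrance `motif_penetrance`, random flanks)
  and bacterial-like decoys (noised domain, all cysteine contexts
  scrubbed, no motifs). Duplication is planted as an exact count
  (`round(frac × n)` sequences receive a second, context-free domain
  copy): a fraction parameter that is itself the quantity under study
  should not be realized with binomial noise. Default sizes (100 + 100,
  5% domain noise) make classifier checks fast and unambiguous.
* `generate_family_alignment()` evolves sequences along a random
  unrooted tree (per-branch, per-site substitution probability equal to
  branch length) or builds a two-clade design with a fixed number of
  diagnostic differences for bootstrap checks.
* `generate_abundance_dataset()` emulates a station × depth survey.
  A taxon's per-sample abundance is tied to one environmental variable
  through a Gaussian copula: the latent Pearson correlation is
  `2 sin(π ρ/6)` so the *rank* correlation hits the target ρ exactly at
  the latent level. The latent field modulates gene means only for taxa
  with a correlation target — leaving it on everywhere would inject
  correlated sample-level noise that the stated noise model (negative
  binomial dispersion, default 0.2) does not describe. The modulation
  amplitude (1.0 log-units) is chosen so the link dominates counting
  noise; realized Spearman at target 0.7, n = 60 centres near 0.69
  (slight attenuation from count noise and library-size variation is
  unavoidable in count data). Counts are negative binomial
  (overdispersed, as real expression data are, rather than Poisson)
  around zone-specific means implementing the per-gene fold-change map
  (defaults mirror a 23-gene dinoflagellate panel: 4 mesopelagic- and 16
  euphotic-enriched genes at 8-fold); library sizes are lognormal
  (σ = 0.1) and independent of the signal.

What passing tests on generator data do **not** show: robustness to real
alignment error, to compositional coupling between taxa competing for
read share, to environmental covariates correlated with each other, or
to motif degeneracy (planted motifs are exact). The generator's truths
are emitted as manifests so every stage is scored against ground truth
without re-reading generator internals.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use problem sizes chosen to
make the statistical checks decisive while staying quick on a laptop:
100 + 1000 sequences for classifier confusion, 20 seeded discovery runs,
200 random trees for the NJ oracle, 100 copula runs at n = 60, 20 seeded
depth-differential runs at 10,000 permutations, and 50 null runs at 500
permutations for type-I control. Every stochastic step takes an explicit
integer seed, and all generators restore the caller's RNG state, so runs
are exactly reproducible.
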