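---
title: "Models and methods behind toeholdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind toeholdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`toeholdr` implements a complete computational pipeline for high-throughput
toehold-switch studies: library design, flow-seq quantification,
thermodynamic and kinetic featurization, sequence-to-function neural
models, and gradient-saliency visualization of learned RNA secondary
structure (VIS4Map). This vignette is the package's own account of the
models it implements, the parameters that matter, and the choices made
where the design was genuinely open.

## The construct and its arithmetic

A first-generation fused-trigger switch is fully determined by its 30-nt
trigger. The 145-nt model input concatenates eight segments:

| segment | length | origin |
|---|---|---|
| trigger | 30 | variable |
| unstructured linker | 20 | constant |
| toehold | 12 | reverse complement of trigger (positions 19-30) |
| ascending stem | 18 | reverse complement of trigger (positions 1-18) |
| SD-containing loop | 11 | constant |
| descending stem | 18 | pairs ascending stem; start codon as 3-nt bulge |
| AA linker | 21 | constant |
| GFP head | 15 | constant |

The descending stem pairs back onto the ascending stem in a
9-pair / 3-unpaired / 6-pair pattern; the start codon (`AUG`) sits as the
3-nt bulge on the descending side (descending positions 7-9). All pairing
arithmetic is 0-based half-open internally and verified by
reverse-complement round trips in the test suite.

The exact constant segments are not fixed by the architecture; the
defaults in `design_constants()` are first-generation conventions (a loop
carrying the canonical `AGAGGAGA` Shine-Dalgarno core, the common 21-nt AA
linker `AACCTGGCGGCAGCGCAAAAG`, the first 15 nt of GFPmut3b after the start
codon) and are fully configurable. The synthesis oligo nominally totals
230 nt; the named segments sum to less, so the remainder is an explicitly
configurable 3' adapter auto-sized to reach the target length.

## The fold engine

No nearest-neighbour thermodynamic engine is available in this
environment, so the package ships a self-contained, deterministic backend
used throughout:

* **MFE** — Nussinov-style maximum base pairing (Watson-Crick plus G-U
  wobble, minimum hairpin loop 3 nt), energy −1 *score unit* per pair.
  These are not kcal/mol; every feature records the engine that produced
  it. An alternative `scoring = "stacks"` assigns −1 per *stacked* pair
  (a helix of length *h* scores −(*h*−1)), which rewards contiguous
  helices the way nearest-neighbour models do; it exists because the plain
  pair count on random sequences is almost entirely determined by
  composition, which matters for the saliency validation below.
* **Partition function / pair probabilities** — the matching McCaskill-style
  recursion with Boltzmann weight `exp(beta)` per pair (`beta = 1`,
  i.e. one score unit per kT). The exterior recursion is exact; both are
  verified against exhaustive structure enumeration for all sequences up
  to 12 nt.
* **Ensemble defect** — `N − Σ_target pairs 2 p(i,j) − Σ_target-unpaired
  p_unpaired(i)`: the expected number of incorrectly paired nucleotides at
  equilibrium. *Ideal* ensemble defect (IED) uses the designed structure as
  target; *native* (NED) uses the region's own MFE structure.
* **Kinetic folding** — a simplified Kinfold analogue: kinetic Monte-Carlo
  whose move set is the addition or removal of one base pair, Metropolis
  acceptance `min(1, exp(−β ΔE))`, unit attempt frequency per candidate
  move, and an exponential waiting-time clock. Times are dimensionless
  arbitrary units and are not convertible to Kinfold's; only dimensionless
  summaries (the four kinetic features) are comparable. If a trajectory
  reaches the MFE energy within `t_max` (default 10^3), the molecule is
  assumed to stay there and the energy is clamped.

## Rational and kinetic features

Each switch yields 14 MFE values, 8 ideal and 8 native ensemble defects
(30 rational features), and 4 kinetic features. The 8 composite regions
carry designed ideal structures (SwitchOFF, SwitchOFF_GFP, SwitchOFF_NoTo,
SwitchON, SwitchON_GFP, ToeholdON, Stem, StemTop), reconstructed from the
pairing pattern of the architecture and validated against region lengths
(the `Stem` region is 18 + 11 + 18 = 47 nt). Which 14 regions enter the
MFE set is a free choice of the protocol; the package uses
the 8 composite regions plus 6 primary segments (Trigger, Switch, Stem1,
Stem2, Linker, Post_linker), documented and configurable.

The kinetic region defaults to the toehold start through the AA-linker end
(model-input positions 51-130, 80 nt); an 85-nt variant of this region is
sometimes quoted but is inconsistent with the segment arithmetic, so the
package keeps the segment-aligned default and makes the offsets
configurable. The four features are the mean and SD of the
per-trajectory time-average energy (trapezoidal integration of the energy
step function over `[0, t_max]`, divided by `t_max`), the ratio of mean
average energy to the MFE (defined as 1 when the MFE is 0), and the
fraction of trajectories reaching the MFE.

## Flow-seq quantification

Counts are normalized per bin to sequencing depth, renormalized across
bins to a per-variant weight distribution, and summarized as the weighted
mean of bin representative values (0, 1/3, 2/3, 1). The endpoints are
fixed by the scaling rule — all reads in the lowest bin give 0, all in the
highest give 1 — but the interior values are a free choice; equal spacing
is the minimal assumption and `bin_values` is configurable (e.g. to
log-fluorescence gate centers). ON/OFF = ON − OFF ∈ [−1, 1]. QC tiers
QC1-QC5 default to minimum read counts 5/10/20/50/100 — package defaults,
not externally calibrated thresholds — with an optional cap on the weighted SD of the
bin-index distribution; variants with reads in a single bin are flagged as
potential gate-boundary artifacts.

## The synthetic flow-seq world

The generator plants structure-driven mechanisms so every downstream stage
can be tested without the real dataset:

* **OFF*** = `plogis(off_intercept + w_off · d)` + noise, where `d` is the
  number of MFE base pairs of the variant's SwitchOFF region *not* in the
  designed hairpin — off-target structure competing with the repressive
  stem (misfolding → leak).
* **ON*** = `plogis(on_intercept − w_on · a)` + noise, where `a` is the
  trigger's self-structure pair count (a structured trigger sequesters its
  own toehold).

Defaults (`w_on = 1.2`, `w_off = 0.35`, intercepts centering the link at
the typical random-trigger values of about 9.4 self-pairs and 21
off-target pairs, noise SD 0.05) were chosen once so that ground truths
span the full [0, 1] range, as the real library does. The measurement
model draws per-cell log10 fluorescence as Normal around a truth-mapped
mean (SD 0.3 decades — a clonal population spans roughly one decade), uses
four gates at decade spacing, and samples reads per bin multinomially with
depth proportional to bin occupancy; 160 cells and 150 reads per variant
reflect the scale of a 10-million-events-per-gate sort and a
~15M-read sequencing run over a 100k-variant library. What the generator
does **not** emulate: synthesis truncations and frameshifts, PCR bias,
gate spillover optics, and the heavy OFF-skew of the real library; a green
recovery test therefore establishes pipeline correctness, not robustness
to those artifacts.

## Models and training

Seven families are provided (dense 25/10/7 on rational features; dense
128/64/32 on the flattened one-hot sequence; their hybrid joined through a
4-unit dense layer; a 1D CNN with 32/64/128 filters of size 3; a 2D CNN on
the complementarity map with 32/64/128 filters of 5×5; an LSTM with 128
units plus a 100-unit dense layer; and a linear/logistic baseline), each
with ReLU, batch normalization and 30% dropout, a 3-output linear head for
regression and a 2-output softmax head for classification (positive iff
ON/OFF ≥ 0.7, an inclusive boundary: a single positive threshold that
selects roughly the top tail of the ON/OFF distribution).
The 2D CNN adds 2×2 max-pooling after each convolution block — without it
a 145×145×128 flatten into dense layers is computationally infeasible. The layers are
implemented directly on R arrays (no deep-learning framework exists in
this environment) and every layer's backward pass is verified against
numerical gradients in the test suite. Optimizer (Adam), learning rate
(1e-3), and losses (MSE / cross-entropy) are package defaults — the
training protocol's stated parts are the 300-epoch cap, 20-epoch early
stopping patience, batch size 64, 10-fold regression / 3-fold
classification cross-validation, and the four balancing strategies
(rank-preserving quantile transform with exact empirical inverse, 20-bin
resampling to the largest bin, class undersampling, class oversampling),
applied to training folds only.

## Encodings and VIS4Map

The complementarity map is an L×L×7 one-hot tensor over ordered position
pairs: G-C = 6, C-G = 5, A-U = 4, U-A = 3, G-U = 2, U-G = 1, anything else
= 0. The encoding is directional (row = first base, both axes 5'→3'),
the diagonal is not masked (configurable), and the channel order of the
one-hot sequence encoding is pinned to (A, C, G, U).

Saliency is the gradient of a chosen output head with respect to the
input map, reduced across the 7 channels by L2 norm (configurable to max
or absolute sum) and
min-max normalized to [0, 1]; a constant model returns zeros rather than
NaN. Overlap with a reference structure binarizes the saliency at its
top-k cells with k equal to the number of reference cells — the package's
operationalization of percentage overlap — and a permutation (shuffled-assignment)
baseline makes the statistic self-calibrating. The negative control
(untrained model → no matched/shuffled separation) is part of the test
suite.

### Why the saliency validation uses the stacking score

Under the plain −1-per-pair model, the maximum pair count of a random
40-60-nt RNA is ~92% determined by its length and base composition; a
CNN can therefore predict this MFE accurately without ever attending to
*which* cells pair, and its saliency shows no structural localization
(we verified this directly: saliency mass on true-pair cells equals that
on arbitrary complementary cells). Nearest-neighbour energy models reward contiguous helices; the stacking score
(−1 per stacked pair) is the minimal analogue, shifts a substantially
larger share of the variance onto arrangement, and makes helix diagonals
the natural predictive feature. The scaled-down saliency validation
therefore trains its CNN to predict the stacking-score MFE and compares
saliency maps against the stacking-MFE structures.

## Numerical choices and degenerate inputs

* Ties in top-k saliency cells break deterministically by position order.
* Maximum base-pairing structures are highly degenerate; the traceback
  returns one canonical co-optimal structure (single-pair additions are
  preferred late, matching textbook Nussinov tracebacks).
* `functional_value` requires weights summing to 1 (enforced to 1e-6);
  variants with zero reads across all bins are excluded, not imputed.
* Quantile-transform inverse uses the empirical mid-rank grid, making
  `inverse(transform(x))` exact on the training sample up to ties.
* The kinetic simulator records at most `record_limit` events but
  accumulates the energy-time integral exactly either way.
* Contrast enhancement for averaged saliency maps is a 1st-99th percentile
  linear stretch.

## Known limitations

* Score-unit energies are not kcal/mol; absolute feature values are not
  comparable to nearest-neighbour engines, only their information content.
* The kinetic time scale is not convertible to Kinfold arbitrary units.
* The Nussinov ensemble is flatter than a realistic thermodynamic
  ensemble; ensemble defects are correspondingly larger and less
  structure-specific.
* Models are CPU-trained at scaled-down sizes in the test suite;
  full-dataset training on the real 10^5-variant library (GEO GSE149225)
  takes hours of GPU time and is provided only as an optional script
  (`inst/scripts/full-data-integration.R`), deliberately outside the
  test suite.
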