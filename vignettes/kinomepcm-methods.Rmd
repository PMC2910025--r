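---
title: "Proteochemometric modelling of kinase-inhibitor interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteochemometric modelling of kinase-inhibitor interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kinomepcm)
```

## The modelling problem

Small-molecule kinase inhibitors are rarely selective: most bind many of
the >500 human protein kinases, because the targeted ATP pocket is highly
conserved. Proteochemometric (PCM) modelling treats the binding strength
of a kinase-inhibitor pair as a joint function of *both* partners'
descriptors, so that a single model trained on a panel of measured
dissociation constants can predict activities for untested pairs — and,
more ambitiously, for kinases with no measured data at all.

The response is pK_d = -log10(K_d). A typical primary screen only
quantifies pairs that bind better than 10 µM (pK_d >= 5); pairs that fail
the screen are recorded at a fixed floor one unit below the detection
limit, pK_d = 4. The response is therefore *censored*: roughly three
quarters of the matrix sits exactly at the floor, and measurable
activities span 5 to about 10.6.

## Protein description schemes

Six sequence description schemes are implemented, each mapping a kinase
sequence to a fixed-width numeric vector (`describe_kinases()`):

* **`aligned_z`** — every column of a gap-filtered multiple alignment is
  encoded by the five Sandberg z-scales (principal property scores:
  hydrophobicity, sterics, polarity, two electronic terms). Alignment
  columns gapped in more than 50% of sequences are removed first
  (strictly "more than": a 50% column is kept). Gaps encode as the zero
  5-tuple; because z-scales are centred over the amino acids, zero acts
  as an "average residue". Width: 5 x positions.
* **`acc`** — auto- and cross-covariances of the z-scales at lags
  1..L: term(a, b, lag) = sum_i V[a,i] V[b,i+lag] / (N - lag), computed on
  *per-sequence mean-centred* z-values. Centring makes a homopolymer map
  to the zero vector and matches common chemometric practice for this
  transform; the normalisation is by the number of summed products.
  Width: 25 L.
* **`macc`** — signed maxima of the same products, computed on *raw*
  z-values, separated by the sign quadrant of the two property values:
  (+,+), (-,-), (+,-), (-,+). Raw values are essential here — the sign of
  z1 distinguishes hydrophilic from hydrophobic residues, which is the
  very contrast the transform is meant to pinpoint. Each term is exactly
  attained by one residue pair or is 0 when no pair shows that sign
  pattern. Width: 100 L.
* **`ctd`** — composition, transition and distribution statistics over
  seven three-class physico-chemical attributes. We implement the
  standard 147-descriptor layout (21 + 21 + 105); distribution
  descriptors use the ceiling convention for the 25/50/75% residues and
  report all-zero quintuples for absent classes.
* **`so_paa`** — sequence-order coupling numbers tau_d (sum of squared
  residue-pair distances at separation d, d = 1..30) under two embedded
  residue distance matrices, the derived 50 quasi-sequence-order
  descriptors per matrix (weight w = 0.1), and 50 type-1 pseudo-amino-acid
  descriptors (lambda = 30, w = 0.05) whose correlation factors average
  squared differences of standardised hydrophobicity, hydrophilicity and
  side-chain mass. Width: 60 + 100 + 50 = 210.
* **`aac_dc`** — amino-acid (20) plus dipeptide (400) composition.

Two residue distance matrices back the `so_paa` scheme. The Grantham
chemical distance is reconstructed exactly from Grantham's published
composition/polarity/volume values and constants. The second,
`"physchem"`, is this package's own physico-chemical distance: the
root-mean-square difference of z-standardised hydrophobicity (Eisenberg),
hydrophilicity (Hopp-Woods) and side-chain mass — the same three
properties used by the pseudo-amino-acid correlation factors. It is
symmetric with zero diagonal by construction.

Non-standard residues (B, J, O, U, X, Z) are rejected with an error that
names the sequence and position; descriptor orderings are frozen and
named, so blocks are byte-stable across runs. The default maximum lag for
`acc`/`macc` is L = 50, the value that lag-selection experiments on
kinase panels identify as the sweet spot between resolution and chance
correlation.

## Ligand descriptors

Compound descriptor tables are inputs (any numeric table; molecular
descriptor software is upstream of this package). `load_ligand_table()`
validates ids and numeric completeness and drops constant columns.
`prune_correlated()` applies redundancy pruning: while any descriptor
pair has pairwise r^2 > 0.9, the member of the worst pair with the
highest maximum r^2 against the remaining descriptors is removed. The
rule leaves iteration order open; we iterate to convergence
with a lexicographic tie-break, which makes the result deterministic and
independent of column order. Correlations are computed on raw columns —
later scaling cannot change r^2.

## Preprocessing and the design matrix

All descriptor columns are mean-centred and scaled to unit variance
(`autoscale()`); scaling states are always fitted on training entities
and applied unchanged to held-out entities. Blocks are then weighted by
1/sqrt(N_b) (`block_scale()`), which makes every block's total variance
equal to 1 regardless of width, so a 5000-column MACC block cannot drown
a 150-column ligand block.

Non-linear selectivity enters a linear model through **cross-terms**:
element-wise products of ligand principal-component scores with kinase
principal-component scores, one row per pair (`make_cross_terms()`). All
ligand PCs are used (for n compounds they reconstruct the ligand block
losslessly with n - 1 components), but only as many kinase PCs as explain
95% of the kinase block's variance. Cross-term columns are Pareto-scaled
(divided by the square root of their standard deviation — the standard
chemometric middle ground between no scaling and autoscaling) and the
whole block is multiplied by a weight that is swept from 0 upwards during
hyperparameter selection; weight 0 recovers the purely linear model.

PCA is computed by NIPALS (`pca_nipals()`), extracting components one at
a time with deflation; the sign of each component is fixed by making its
largest-magnitude loading positive. Exported defaults are tol 1e-9 and
500 iterations; the cross-validation engine uses tol 1e-7 and 150
iterations, which changes extracted subspaces negligibly while keeping
nested CV affordable. Reconstruction at full rank is exact to < 1e-8
regardless, because deflation removes each component's contribution
exactly.

## Models

All methods consume the same design-matrix contract; switching methods
changes no preprocessing.

* **PLS** (`pls_fit()`): NIPALS partial least squares. Single-response
  fits use the covariance-deflation recursion (only X'y is deflated),
  which is algebraically identical to the classical X-deflating NIPALS —
  the test suite proves the equivalence against an independent SIMPLS
  implementation — but far cheaper on wide blocks. The model exposes one
  regression coefficient vector, so the fitted equation remains directly
  interpretable. `pls_x` adds the Pareto-scaled cross-term block with the
  weight swept over a grid (default 0 to 2 in steps of 0.1) inside the
  inner CV.
* **PLS-DA** (`plsda_fit()`): PLS2 on a 0/1 class indicator matrix, with
  per-class and overall cross-validated Q2; used to quantify how well a
  description scheme separates the kinase groups.
* **epsilon-SVR** (`svr_fit()`, and the `svm` method of `double_cv()`):
  RBF-kernel support vector regression. The quadratic-programming core is
  delegated to established libsvm-type implementations (e1071 for
  standalone fits; kernlab with precomputed kernels inside the CV engine,
  where the squared-distance matrix is computed once per fold and
  exp(-gamma D2) is reused across the whole gamma grid — the two backends
  agree to machine precision). Grids are log2-spaced, gamma in 2^-7..2^1
  and C in 2^-2..2^6 by default: with block-scaled designs the total
  variance per block is 1, so pair distances concentrate near these
  scales and wider grids only waste the inner loop. Epsilon defaults to
  0.1 of the training response SD.
* **k-NN** (`knn_predict()`): 1/distance-weighted k nearest neighbours in
  the block-scaled descriptor space; exact matches return the mean
  response of the zero-distance neighbours. The kinase block weight is
  multiplied by factors {0.25, 0.5, 1, 2, 4} during tuning, steering the
  similarity toward ligand or kinase resemblance; k is tuned over
  {1, 3, 5, 7, 9}.
* **Model tree** (`model_tree_fit()`): an M5-style regression tree —
  standard-deviation-reduction splits, linear models at the nodes (on the
  attributes tested in each node's subtree; the root falls back to all
  attributes), bottom-up pruning by complexity-adjusted mean absolute
  error with the (n + v)/(n - v) factor, and leaf-to-root smoothing with
  constant 15. Inside `double_cv()` trees operate on the PC-compressed
  design (all ligand PCs plus the 95%-variance kinase PCs): split search
  over thousands of raw, individually weak columns is uninformative,
  while the PC design preserves the geometry the tree partitions.

Hyperparameters are always chosen by the inner cross-validation loop,
maximising pooled inner Q2; grids are ordered so that ties resolve to the
simplest model (fewest components, smallest C, largest k, largest leaf).

## Double cross-validation and metrics

`double_cv()` implements the nested protocol: the dataset is split into
25 parts — by pair, or by kinase so that a held-out kinase is entirely
unseen — and five outer rounds each set 5/25 aside, run 5-fold inner CV
on the remaining 20/25 (train 16/25, validate 4/25), refit on the 20/25
with the selected hyperparameters, and score the untouched 5/25. Every
preprocessing state (scaling, block weights, PCA, Pareto factors,
response mean) is refit inside each training set; an audit asserts that
no row (and in kinase-wise mode no kinase) ever appears on both sides of
an outer split. Pooled outer predictions give P2 (new pairs) or P2_kin
(new kinases): 1 - PRESS/SS with the mean taken over the evaluated pooled
set, so a mean-only model scores 0. Hyperparameters are re-selected in
every outer round (the stricter reading of the nested protocol);
censored cells participate in fitting and scoring like any other cell,
matching how the original panel models were built.

`roc_analysis()` classifies pairs as interacting when the *observed*
pK_d is at least 5 and uses the predicted pK_d as score; AUC is computed
by the trapezoidal rule and is verified to equal the Mann-Whitney rank
statistic. `error_histogram()` reports the cumulative fraction of
absolute errors below 0.25/0.5/1/2 pK_d units. `dataset_size_sweep()`
retrains on random fractions of pairs (or of kinases) and evaluates on
the remainder, averaging over repeats.

## The synthetic study panel

No public kinase-inhibitor panel ships with the package, so
`simulate_kinome_panel()` generates one with the same shape as the
kinome-wide screens this methodology targets: by default 317 kinases in
the 7 canonical groups crossed with 38 inhibitors (12,046 pairs), kinase
domains mostly 240-300 residues with tails at 194 and 606, ~24.8%
interacting pairs, measured pK_d clipped to [5, 10.62], censored pairs
floored at 4.

*Sequences* follow a star phylogeny: one ancestral core consensus
(default 170 residues) from which each group's consensus diverges at 35%
of positions; individual kinases copy their group consensus with
per-position probability 0.7 and substitute group-tilted background
residues elsewhere. A fully conserved five-residue group motif sits at a
group-specific core position (±2 jitter), and unconserved flanks carry
each sequence to its drawn length. The emitted alignment anchors the
cores, so gap-filtering trims it back to roughly the core — mirroring how
alignment of real kinase domains collapses to the alignable catalytic
region. This conservation structure is what makes the groups separable
to *every* description scheme, positional or alignment-free; a lone
5-residue motif in an otherwise random 270-residue background would be
invisible to averaged transforms such as ACC or dipeptide composition.

*Activities* follow pK_d(k, l) = mu + a_k + b_l + u_k' M v_l + eps. The
latent factors are non-negative and sparse: each compound carries a few
recognition features (v ~ Exp(1), two thirds zeroed), each group responds
to a few (concentrated simplex profiles u), M is positive. The cross
effect is double-centred — orthogonal to the additive effects — and
scaled to SD 1.6 versus an additive part of SD ~0.9, so selectivity
dominates promiscuity. These shape choices matter: a symmetric latent
surface under 24.8%-active censoring caps *any* linear model near
P2 = 0.58, whereas the sparse non-negative construction produces the
short sub-threshold tail and long active tail of a real
detection-limited screen, under which linear cross-term PLS is
competitive — the behaviour the real methodology reports. Per-kinase
offsets (SD 0.35) model individual pocket idiosyncrasies; they are
exploitable for kinases seen in training and act as irreducible noise for
unseen kinases. Assay noise defaults to 0.3 pK_d units (the assay error
model is not specified anywhere we could inherit it from; 0.3 is a
realistic K_d-assay reproducibility figure and is exposed in the
configuration). The intercept mu is calibrated by bisection so the
active fraction hits its target within 0.01; censoring is applied after
noise, as in a detection-limited assay.

What the generator does *not* emulate: real phylogenetic tree structure
within groups, indels inside the core, assay-specific heteroscedasticity,
chemical series structure among compounds, and the correlation structure
of real molecular descriptor software. Passing recovery tests therefore
demonstrate that the pipeline's machinery is correct and that its
statistics behave as designed — not that any particular real panel would
yield the same numbers.

## Problem sizes and observed behaviour

Development and test runs use a reduced panel of 80 kinases x 20
inhibitors (1600 pairs, 60 ligand descriptors), which preserves the full
protocol — 7 groups, 25-part double CV, all descriptor schemes — while a
complete multi-method comparison stays in the minutes range; the
acceptance script uses the same scale with a cross-weight grid step of
0.25 and at most 12 PLS components. At this scale, with the default
generator, the methods reproduce the expected qualitative pattern:
PLS without cross-terms explains only the additive part (P2 ~ 0.15-0.2),
cross-term PLS and SVR recover the planted selectivity surface
(P2 ~ 0.6-0.7), k-NN performs comparably on pairwise splits, and AUCs
exceed 0.9. P2 and P2_kin are close — on this synthetic panel the
kinase-individual signal is small relative to the group-level structure,
so predictions for unseen kinases are nearly as good as for unseen
pairs, and the strict P2 >= P2_kin ordering holds for SVR but can invert
within fold noise for other methods.

## Known limitations

* The "orthogonalised PLS" variants of commercial chemometrics suites are
  proprietary; this package implements NIPALS PLS1/PLS2 and proves it
  against SIMPLS. Any systematic difference from proprietary
  implementations would surface as small component-wise differences, not
  as different model classes.
* The MACC sign-quadrant convention ("positive and negative values
  considered separately, maxima per lag") admits more than one reading;
  we take the maximum product magnitude per quadrant with its natural
  sign, which keeps every term traceable to one residue pair.
* Kinase PCs for cross-terms are computed per training fold
  (leakage-safe). Computing them once globally would mirror some
  historical practice but mixes test kinases into the compression;
  we deliberately do not offer that as the default path.
* `dataset_size_sweep()` retrains with inner-CV tuning at every fraction
  and repeat; at very small fractions the inner folds become tiny and the
  selected hyperparameters are accordingly noisy.
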