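---
title: "Predicting cell-penetrating peptides from sequence descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-penetrating peptides from sequence descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-penetrating peptides (CPPs) are short chains — typically up to about
30 residues — that cross cell membranes and can ferry cargo such as
antibiotics or nucleic acids into cells. Experimentally testing penetration
is slow and expensive, so sequence-based classifiers are widely used to
triage candidates. CPPs are, as a class, cationic: enriched in arginine and
lysine, with isoelectric points above 7 and positive net charge at
physiological pH, and correspondingly nitrogen-rich at the atomic level
(the guanidinium group of arginine alone carries three nitrogens).
Non-penetrating peptides skew anionic and oxygen-rich. `cpptools` encodes
exactly these kinds of signals as interpretable descriptors and classifies
peptides in two stages: cell-penetrating vs not, then — for CPPs — high vs
low uptake efficiency.

`cpptools` works only with sequences over the 20 proteinogenic amino acids.
Ambiguity and non-natural codes (B, J, O, U, X, Z) are hard errors rather
than being silently dropped, because every descriptor table below is
defined for exactly those 20 residues. The minimum accepted length is 3,
the weakest constraint under which every descriptor block (including
tripeptide composition) has at least one window.

## The descriptor set

With the default configuration a peptide of length $L$ maps to 8831
descriptors, all either length-normalized or intrinsic:

| block | dimension | definition |
|---|---|---|
| AAC | 20 | count of each residue / $L$ |
| DPC | 400 | count of each overlapping dipeptide / $L$ |
| TPC | 8000 | count of each overlapping tripeptide / $L$ |
| CKSAAGP | 400 | count of group pairs at gap $k = 0..15$ / $L$ (5 groups) |
| physicochemical | 5 | GRAVY, mass, isoelectric point, hydrophobicity, net charge |
| atomic | 5 | C, H, N, O, S atoms of the whole molecule / $L$ |
| length | 1 | $L$ |

Normalizing counts by $L$ (rather than by the number of windows) makes the
block sums length-dependent constants — AAC sums to 1, DPC to $(L-1)/L$,
TPC to $(L-2)/L$, and the gap-$k$ CKSAAGP slice to $\max(L-k-1,0)/L$ —
which the unit tests assert exactly. A window-count normalization is
available behind `descriptor_config(normalization = "windows")` for users
who prefer compositions that always sum to one.

CKSAAGP (composition of $k$-spaced amino-acid group pairs) uses a 5-group
partition by physicochemical character: aliphatic `ALI` {G,A,V,L,M,I},
aromatic `ARO` {F,Y,W}, positively charged `PC` {K,R,H}, negatively
charged `NC` {D,E} and polar non-charged `PNC` {S,T,C,P,N,Q}. Five groups
over gaps 0..15 give the $25 \times 16 = 400$ entries that close the 8831
accounting; the partition is configurable because reasonable alternatives
exist (coarser 3-group hydrophobic/charged/polar schemes are common in the
literature, but do not yield a 400-dimensional block).

### Physicochemistry

Net charge at pH $p$ is a Henderson–Hasselbalch sum over ionizable groups:

$$Z(p) = \sum_{b \in \text{basic}} \frac{1}{1+10^{\,p-pK_b}}
       \;-\; \sum_{a \in \text{acidic}} \frac{1}{1+10^{\,pK_a-p}},$$

with basic groups the N-terminus and the K/R/H side chains, and acidic
groups the C-terminus and the D/E/C/Y side chains. The default pKa table
(N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
Y 10.1) is a widely used sequence-analysis default; it is a
`descriptor_config()` parameter because published tables differ by a few
tenths of a pH unit and reproducibility requires pinning one. Each summand
is strictly decreasing in $p$ and both termini are always ionizable, so
$Z$ has exactly one root in $[0, 14]$; `isoelectric_point()` finds it by
bisection to a residual charge below $10^{-6}$ (or interval width below
$10^{-6}$ pH units). Under this table, a free lysine has
$Z(7) \approx +0.976$ and pI $\approx 9.70$.

GRAVY is by definition the Kyte–Doolittle mean; the separate
"hydrophobicity" descriptor defaults to the Eisenberg consensus scale so
the two are not duplicates. Molecular mass uses average (not monoisotopic)
residue masses plus one water, matching the convention of general-purpose
sequence-analysis libraries. Atomic frequencies count the whole molecule's
formula (residue formulas plus one water) divided by $L$; the diglycine
check `atomic_frequencies("GG") = (2, 4, 1, 1.5, 0)` pins the condensation
bookkeeping.

## Feature selection

Selection is two-step, in a fixed order:

1. **Mann–Whitney filter.** Each descriptor is tested for a
   distributional difference between classes; descriptors with two-sided
   $p < 0.05$ survive. The test is two-sided and no multiple-testing
   correction is applied by default — a deliberately permissive screen
   whose job is only to discard clearly uninformative columns before the
   ensemble sees them (an optional Benjamini–Hochberg switch exists for
   users who want a calibrated screen). Constant columns get $p = 1$.
   The scalar `mann_whitney_u()` uses the exact U distribution for
   tie-free samples with both sizes at most 8, and a tie- and
   continuity-corrected normal approximation otherwise; the columnwise
   filter always uses the approximation, appropriate at the row counts
   where filtering matters. Because the test depends on ranks only, the
   kept set is invariant to monotone transformations of any column — a
   property the tests assert directly.
2. **Extra-trees importance ranking.** An extremely randomized trees
   ensemble is fit on the surviving descriptors and they are ranked by
   mean impurity-decrease importance (normalized to sum to 1); the top
   `top_k` are kept. The default `top_k = 522` is exposed as a parameter
   rather than hard-coded logic, since a good cut-off is data-dependent.
   Ties in importance break alphabetically so rankings are reproducible.

A truncated SVD (`svd_reduce()`) is provided for dimensionality-reduction
experiments; columns are mean-centered first so the reported
explained-variance fractions are interpretable, and a rank deficit clamps
the component count with a warning instead of failing.

## The classifier

The default estimator is an extremely randomized trees ensemble: 500
trees, Gini impurity, $\sqrt{d}$ candidate features per split, one random
threshold per candidate, no bootstrap (every tree sees the full training
set), grown to purity, seed 42. Randomized thresholds de-correlate trees
without bagging; growing to purity means a separable training set is
interpolated (training MCC = 1), which the tests use as a fitting
invariant. All randomness flows from the recorded seed and prediction is
single-threaded, so identical seeds give identical models and
byte-identical scores. RF, gradient-boosted trees, SVM and MLP are
selectable through the same `training_params()` surface for comparison
experiments; SVM and MLP get per-column standardization fitted on training
rows only. The decision threshold is 0.5 and exposed as an argument.

Stage 2 — high vs low uptake efficiency — is trained on the five atomic
frequencies only. This is a deliberately tiny, physically interpretable
feature space: nitrogen density tracks the cationic side chains that drive
membrane interaction, and oxygen density tracks the anionic ones. In
`predict_two_stage()`, efficiency is only reported for peptides stage 1
calls penetrating; stage-1 negatives get an explicit `NA`, never a silent
stage-2 score, because the efficiency model is trained exclusively on
CPPs and its scores are meaningless off that support.

### Cross-validation

`cross_validate()` uses stratified folds (class ratio preserved within one
sample per fold) and aggregates per-fold sensitivity, specificity,
accuracy, precision, F1, MCC and AUC. AUC uses the rank (Mann–Whitney)
formulation with half-credit ties, which is exact; the tests verify its
equality with trapezoidal ROC integration to $10^{-12}$.
`cross_validate_pipeline()` additionally refits the *entire* selection
(filter + ranking) inside each training fold. The distinction matters:
selecting descriptors on all rows and then cross-validating the selected
matrix leaks selection information into the held-out folds, and under a
label-independent generator that bias alone lifts apparent AUC well above
chance. The pipeline CV is the honest estimate and is what the package
reports for end-to-end performance; plain `cross_validate()` is
appropriate when the feature set was fixed independently of the data.

Undefined metrics (zero denominators — e.g. precision with no positive
predictions) are reported as `NA` with an explicit flag and excluded from
fold means, never coerced to 0.

## The synthetic generator

`generate_binary_dataset()` emulates the compositional contrast between
CPPs and non-CPPs: lengths uniform on 5–30 (the typical CPP size range),
residues sampled i.i.d. within a class, with R and K up-weighted by an
enrichment factor $e$ (default 4) in positives and D and E up-weighted by
$e$ in negatives. This single knob produces the whole correlated signal
cluster real CPP data shows — positive net charge, pI > 7, high AAC_R and
AAC_K, elevated nitrogen density — and $e = 1$ collapses the generator to
an exact null in which the classes are exchangeable.
`generate_efficiency_dataset()` starts from the cationic (positive-class)
weights for both classes and additionally multiplies the weights of the
nitrogen-rich residues R, N, Q and H by $1 + s$ in the high-efficiency
class, so `atomic_shift` $s = 0$ is again an exact null and larger $s$
plants a graded normnN signal.

What the generator does *not* emulate: positional structure (amphipathic
helices, terminal motifs), the low mutual sequence identity of curated
benchmark sets, and the label noise inherent in artificially generated
negatives. Passing the recovery tests therefore shows the pipeline's
machinery is correct — that it finds compositional/physicochemical signal
when present and reports chance when absent — not that the reported fold
metrics transfer to any particular experimental benchmark.

## Reference problem sizes

The package's own end-to-end checks run at 500 peptides per class for the
penetration stage (comparable to the ~1000-peptide balanced training sets
curated for this task) and 140 per class for the efficiency stage
(matching the size at which public uptake-efficiency training data
exists). At these sizes a full pipeline cross-validation completes in
about a minute and a half on one core. The marker-recovery check asks
that at least 3 of {net_charge, isoelectric_point, AAC_R, AAC_K, normnN}
appear in the selection report's top 10 importances in at least 8 of 10
seeds — "at least 3" because these five markers are strongly mutually
correlated by construction, so the ensemble legitimately splits credit
among them and with correlated surrogates (normnO, AAC_D/E, charged-pair
CKSAAGP terms).

## Numerical and degenerate-input policy

* Composition counts are integers divided by $L$; equality tests against
  oracles use tolerance $10^{-12}$.
* Bisection for pI stops at $|Z| < 10^{-6}$ or width $< 10^{-6}$; the
  grid-scan cross-check requires agreement within 0.002 pH units.
* A gap slice with no valid index pairs ($k \ge L-1$) is all zeros, not an
  error.
* Class-ratio reports flag zero denominators as undefined rather than
  adding an epsilon.
* Prediction refuses any column mismatch (name, order, or count) instead
  of silently reordering; model bundles carry MD5 content hashes and a
  format version, and loading verifies both.
* Fold assignment, generation and training each derive all randomness
  from explicit integer seeds; the caller's RNG state is restored.

## Limitations

* Only natural residues are supported; chemically modified peptides must
  be handled upstream.
* The pKa model treats sites as independent (no charge–charge coupling),
  which is standard for sequence-level tools but approximate for real
  titration behaviour.
* Importances are impurity-based and inherit that estimator's known bias
  toward high-cardinality/continuous features; with strongly correlated
  descriptors, importance mass is shared across the correlated group.
* The efficiency stage's five-feature space is interpretable but coarse;
  with small training sets its fold variance is high, and results on real
  uptake data should be read with that in mind.
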