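---
title: "Methods: factorial MAE optimization and lipidomic chemometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial MAE optimization and lipidomic chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidMAE)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices
behind `lipidMAE`. The package covers the computational side of
developing a Microwave-Assisted Extraction (MAE) method for untargeted
lipidomics of soft cheese: screening candidate extraction solvents with
multivariate diagnostics, then optimizing the extraction conditions with
a factorial design and a Pareto front.

## The factorial model

The extraction is screened over three factors: solvent-to-solid ratio
X₁ (16–32 mL g⁻¹), extraction time X₂ (6–30 min) and temperature X₃
(50–80 °C), each coded affinely onto −1/0/+1
(`coded_to_real()`/`real_to_coded()`). `build_full_factorial()`
enumerates the 2³ corners in Yates order (first factor fastest; a fixed,
documented convention — printed experimental matrices are often a
permutation of the same corners, and `reorder_to_match()` re-keys rows
by their coded triples) and appends center replicates. With 3 center
points the design has 11 runs.

Each response — the abundance sum of one lipid subclass, range-scaled to
[0, 1] so responses of very different magnitudes share a scale — is
fitted by OLS to the 8-term model

$$Y = b_0 + \sum_i b_i X_i + \sum_{i<j} b_{ij} X_i X_j + b_{123} X_1X_2X_3.$$

On the coded corners the model-matrix columns are mutually orthogonal
with integer entries, which the tests check exactly. Inference uses the
residual variance pooled over all runs (3 df with 11 runs), not the
pure-error variance of the center replicates alone: a standard OLS
choice, made because the workflow performs no lack-of-fit analysis.
Coefficient p-values are two-sided t tests; the model p-value is the
overall F test; significance is reported in two tiers (p < 0.05,
p < 0.01). No multiple-testing correction is applied across the 18
responses — the workflow reports nominal p-values, a documented
limitation. The significance table fits the full 8-term model and
*hides* non-significant entries; it does not refit reduced models. A
subclass whose overall model fails the 0.05 threshold is listed as
showing no significant dependence on the conditions.

Degenerate inputs are handled explicitly: a saturated 8-run design
yields a coefficient-only fit (`inference = FALSE`); an exact fit (zero
residuals, as with noiselessly generated responses) is detected by
comparing the residual sum of squares to machine precision at the
response's scale, and reported with r²(adj) = 1 and p-values 0/1 for
nonzero/zero coefficients rather than as 0/0 test statistics.

## Screening diagnostics

`run_screening()` takes a labelled solvent-screening table (three
solvent mixtures, one column per subclass) through:

* **Range scaling** per subclass to [0, 1] (`range_scale_responses()`);
  constant columns are an error because the map is undefined.
* **PCA** (`pca()`, a `prcomp` wrapper). Default pretreatment is
  autoscaling (centering + unit variance), since subclass sums span
  orders of magnitude; configurable. Component signs are fixed
  deterministically by making the largest-magnitude loading positive.
* **UPGMA clustering** on *squared* Euclidean distances of the
  range-scaled data (`hca_average_linkage()`). Average linkage applied
  to squared distances makes every merge height the mean pairwise
  squared distance between the merged groups; the implementation is
  `hclust(dist(x)^2, "average")` and a naive O(n³) re-derivation is kept
  in the test suite as an oracle. `cut_tree()` applies every merge with
  height strictly below the cut, so a cut placed exactly at a merge
  height leaves that merge unapplied.
* **PLS-DA** (`plsda_double_cv()`, `plsda_bootstrap()`): NIPALS PLS2 on
  the one-hot class matrix with sequential deflation, class assignment
  by arg-max predicted response. Model quality is assessed in a double
  (nested) cross-validation: stratified outer folds (default 6 — with 12
  samples per solvent the stratification is exact at 2 per class per
  fold) hold out test samples never used in fitting; inner CV (default
  5-fold, up to 5 components) picks the component count maximizing mean
  held-out Q². Reported per class: RMSECV = √(PRESS/n),
  Q² = 1 − PRESS/TSS, DQ² (residuals zeroed when a prediction overshoots
  its label on the correct side, hence DQ² ≥ Q² always), and one-vs-rest
  accuracy/sensitivity/specificity. The bootstrap variant (default
  B = 1000) fits on stratified resamples and evaluates out-of-bag,
  averaging the same statistics; replicates whose out-of-bag set misses
  a class are skipped and counted. All resampling is seeded and
  restores the caller's RNG state.

## Pareto optimization

After per-subclass fitting, the subclasses with significant models are
taken into a PCA (centered, unscaled — they already share the [0, 1]
scale). PC1 and PC2 scores per run are modelled with the same 8-term
basis (`fit_pc_surfaces()`); because PCA scores are linear combinations
of responses, noiseless 8-term responses give exact score surfaces. The
surfaces are evaluated on a grid of 40 equally spaced values per factor
(64,000 points; `build_grid()`, evaluation in coded units), and
`pareto_front()` extracts the non-dominated set: p dominates q iff p is
at least as good in both oriented objectives and strictly better in
one; coordinate-tied points are all retained. The implementation is an
O(n log n)-style block sweep verified against an all-pairs filter.

Objective *directions* are a required choice, defaulting to (max, max):
which lipid groups sit at which end of a PC depends on the data, so the
pipeline reports the loadings and leaves orientation to the analyst
rather than silently inverting a trade-off. With the synthetic
generator's data, PC1 contrasts lyso-lipids (positive loadings, favored
by high solvent-to-solid ratio) against phospholipids and ceramides
(negative); orienting the objectives as (max PC1, min PC2) makes them
genuinely conflict, and the compromise — the front point nearest the
utopia point after min-max normalization of both objectives over the
front (`select_compromise()`) — lands strictly inside the experimental
ranges, the computational analog of "the best compromise is near the
center point". A single-point front is returned directly; a flat
objective contributes nothing to the normalized distance.

## Lipid annotation

`parse_lipid_name()` implements the shorthand grammar
`Class(chain[/|_]chain...)` with `chain := [d]C:D[+O|+OO]`. `/` marks
resolved sn positions, `_` unresolved (unresolved chains are sorted in
the canonical form, and `format(parse(x))` is idempotent). Oxidation
suffixes promote TG→TG_1OX/TG_2OX and DG→DG_OX. Errors are typed
(`lipid_unknown_class`, `lipid_chain_count_mismatch`,
`lipid_malformed_chain`) so callers can collect them per line, as
`read_lipid_table()` does; `run_annotation()` aborts when more than 5%
of rows fail.

Classification follows the dairy-lipid conventions: SFA/MUFA/PUFA by
0/1/≥2 double bonds; chain length short (4–10 C), medium (11–15 C),
long (≥16 C). The long-chain boundary is set at **16 carbons inclusive**
(configurable `lc_min`): palmitic acid is treated as long-chain, and
the three classes then partition all chains so position-wise percentages
sum to 100. Inventory summaries count species at the 18-subclass
reporting level, where Hex1Cer and Hex2Cer merge into HexCer while the
two oxidation states of TG stay separate — the only counting convention
consistent with the study design this package supports. sn-1/sn-2
labels for DG follow the convention that sn-1,2 and sn-2,3 isomers are
indistinguishable in untargeted lipidomics. Oxidized species are
cross-linked to a non-oxidized parent by comparing chain-composition
multisets with the added oxygens stripped (sn order ignored). Method
comparison keys species by canonical name plus ion mode. The QC gate
computes RSD% = 100·sd/mean per deuterated standard and passes only
strictly below the threshold (default 20%); a zero mean fails with an
explicit reason.

## The synthetic-data generator

No raw abundance data accompany the study design, so
`gen_ffd_responses()`, `gen_solvent_screening()`, `gen_lipid_fixture()`
and `gen_qc_table()` generate inputs with the statistical structure the
analysis assumes. What they emulate — and what they do not:

* **Factorial responses**: Y = Xβ + N(0, σ) per subclass on the scaled
  response scale, with β from the packaged coefficient table for the ten
  condition-dependent subclasses and intercept-only models for the other
  eight (their blank entries are treated as exact zeros — they are
  non-significant, not necessarily zero; a documented approximation).
  Default σ = 0.01, small against coefficient magnitudes of 0.02–0.51 so
  significance patterns are stable; the true replicate variance of
  subclass sums is unknowable from the study design and σ is exposed in
  `generator_config()`. Zero-noise generation followed by fitting is the
  identity on the coefficient table to machine precision — the
  package's central closure property.
* **Solvent screening**: 12 extractions per solvent, 18 subclass columns
  with magnitudes spanning 10²–10⁵. Groups sit on a shared latent
  extraction axis (ME and IE at the ends with tight spread, EE between
  and closer to ME with larger spread) plus a small EE-specific
  signature on a second direction. The construction keeps the ME/EE
  group-mean difference below 20% for every subclass (log-scale gap
  0.2·0.45 + 0.03 ≈ 0.12) while making ME and IE cleanly separable and
  EE only partially so — the qualitative pattern the screening
  diagnostics must reproduce. A pure single-axis design was rejected
  because regression-on-indicators then masks the middle class entirely,
  which is a pathology of the classifier, not a property of the
  chemistry. The generator does *not* emulate inter-batch drift,
  censored/missing peaks, or correlated subclass responses beyond the
  two latent directions; a passing test therefore shows the pipeline
  recovers planted structure, not that real solvent effects are of this
  form.
* **Identification fixture**: fully deterministic (no RNG), 449 species
  in the 18 reporting subclasses with the per-subclass counts, adducts
  and ion modes of the inventory, TG sn-position saturation tallies of
  274/48/0 (sn-1) and 205/101/16 (sn-2), DG sn-1 87%/13%, 24+1 oxidized
  glycerolipids of which exactly six have a non-oxidized parent, and
  oxidized species graded A/B only. Chains are assigned from the dairy
  fatty-acid vocabulary (including the short-chain 6:0/8:0/10:0 and the
  monounsaturated 14:1/16:1 that dairy fat requires for these marginals
  to be jointly satisfiable) by a balanced greedy pairing that
  guarantees unique ordered chain tuples. It is a synthetic stand-in
  that reproduces inventory-level tallies, not any real identification
  export; per-species retention behavior, areas and grades carry no
  analytical meaning.
* **QC tables**: replicate areas Normal(μ, μ·RSD/100) per standard with
  configurable true RSD.

All generators take one seed and are pure functions of their
configuration.

## Numerical choices and problem sizes

Determinism: every stochastic routine takes an explicit seed, seeds are
applied in a local RNG scope, and fold assignment/resampling are
stratified. PCA signs, Yates ordering, arg-max tie-breaking
(`ties.method = "first"`), and the greedy fixture pairing are all fixed
conventions, so reruns are bit-identical. Exact-fit detection uses a
relative 1e-24 threshold on the residual sum of squares; NIPALS stops at
a relative score change of 1e-12 or 500 iterations; constant columns are
left centered-at-zero during autoscaling inside PLS (they carry no
information) but are an error in user-facing scaling and PCA.

The test suite exercises the oracles at deliberately small sizes chosen
for coverage rather than realism: naive UPGMA up to n = 20, brute-force
Pareto filters on 500 random points, 500-replicate unbiasedness
simulations, 1000-draw DQ² ≥ Q² sweeps, 2000-seed noise calibration, and
20-permutation Q² nulls; the full 64,000-point grid is evaluated as-is
(it is vectorized and cheap). Bootstrap defaults to B = 1000 in the API
and 120–500 in tests.

## Known limitations

* Nominal p-values across 18 responses; no curvature/lack-of-fit test
  from the center points; no fractional or response-surface designs
  (quadratic pure terms are not estimable from a 2-level design).
* Q²-maximizing component selection can overfit the inner folds when
  classes are tiny; fold counts are validated against class sizes but
  very small studies should prefer the bootstrap report.
* The Pareto machinery supports exactly two objectives; more subclass
  groups than two directions of conflict require re-running with
  different orientations.
* The parser covers the shorthand dialect used in these exports; ether
  lipids (O-/P- prefixes), glycan isomers and double-bond positional
  notation are out of scope, as is any mass or spectral arithmetic —
  identification happens upstream.
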