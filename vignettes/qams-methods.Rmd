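---
title: "Single-marker quantification and batch grading: models, conventions, design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification and batch grading: models, conventions, design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the quantification
model and its assumptions, the conventions chosen where the published
analysis left them unstated, the synthetic-data generator's scope, and the
numerical corner cases. Everything quantitative stated here is computed by
the test suite or the acceptance script; nothing is asserted from memory.

## The quantification model

HPLC-UV detection is assumed linear in concentration per analyte,
`A = a·C + b`, over the calibration range. The external standard method
(ESM) inverts each analyte's own fitted line. Single-marker quantification
(QAMS) keeps one physical standard — GV, chosen for abundance and
stability — and rescales its unit-concentration response `A_s/C_s` by a
relative correction factor per analyte:

```
f_k = (A_s/C_s) / (A_k/C_k),   C_k = A_k / (A_s/C_s) · f_k
```

The model behind the factor is that the *ratio* of molar responses of two
chromones is a property of the compounds and the detection wavelength, not
of the instrument, column, flow rate or temperature. That assumption is
testable, and `durability_rcf()` tests it: factors recomputed across
conditions must agree within 5% RSD. The factor is the arithmetic mean of
the per-level ratios over the shared dilution ladder (the published
analysis says only "average"); its RSD uses the n−1 sample standard
deviation. On a noiseless ladder with zero intercepts the factor reduces
exactly to the slope ratio, which is the oracle the tests use.

Because `f` is computed from response ratios without intercepts, QAMS and
regression-mode ESM agree exactly only when intercepts vanish; the
equivalence on zero-intercept standards is asserted as a property test.
Both calibration styles for the internal standard are provided
(`regression` and `single_point` modes of `esm_quantify()`), since the
published workflow does not state which was used.

Peaks are assigned by the signed retention offset from the reference peak,
`Δt_Rk = t_Rk − t_Rs`, with a matching window of 0.5 min by default —
generous against the sub-minute cross-run jitter the durability conditions
produce, tight against the several-minute spacing of neighbouring
chromones. Assignment is greedy by smallest absolute deviation; exact ties
break deterministically by analyte code; analytes with no candidate inside
the window are flagged absent rather than silently matched. The operation
re-derives every assignment from scratch, so it is idempotent.

## Detection limits and validation statistics

LOD and LOQ follow the signal-to-noise definition, `3·σ_noise/slope` and
`10·σ_noise/slope`, so their ratio is always 10/3. The baseline noise SD is
a user input: published tables print limits but not noise amplitudes, so
the shipped limits are fixtures, not recomputations. Validation statistics
are conventional: RSD = 100·sd/mean of replicate sets (pass below 3% for
precision, stability, repeatability), spike recovery
`100·(found − original)/added` with a 95–105% default window.

## Chemometric scoring conventions

The published two-component model leaves its standardization convention
unstated. The package resolves it empirically, and the chemometrics tests
pin the resolution down:

* PCA operates on the **correlation matrix** of the 55 × 6 content matrix
  (columns z-scored); component *i* explains `100·λ_i/6` percent. This
  reproduces the printed variance fractions 62.614% and 17.646% to three
  decimals.
* Loadings are eigenvectors scaled by `√λ` (component–variable
  correlations), signs fixed so each component's loading sum is
  non-negative. Retained in full they reproduce the correlation matrix.
* The composite score applies the published coefficient table directly to
  the **z-scored** contents, `Z = 0.62614·Z1 + 0.17646·Z2`. Under this
  convention the package reproduces 54 of the 55 printed composite scores
  to within 0.005; the remaining one (batch 6) matches in magnitude with
  the opposite sign and is treated as a sign misprint. Two further printed
  digits are read per their companion tables: the Z1 coefficient of GH as
  0.903 and the aglycone coefficient of H as 0.599.
* The printed score–total correlation (0.875) is **not** recoverable from
  the printed tables: Pearson correlation of the printed scores against
  the totals computes to 0.880 (0.906 for the recomputed scores). The
  acceptance suite asserts the printed value at its printed precision and
  therefore documents this discrepancy as a failing check rather than
  hiding it.

Grading uses an inclusive qualification bound (total ≥ 3 mg/g) and strict
superior bounds (total > 8 mg/g and aglycone share > 10%), all
configurable. The rule is monotone in both inputs.

For the two-group quality split, the printed partitions (45/9 on totals
with batch 51 set aside; 41/12 on aglycone ratios with batches 13 and 37
set aside) coincide exactly with thresholding the 1-D indicator at 8 mg/g
and 10% respectively, so `threshold_split()` is the partition the package
asserts and the pipeline reports. A dendrogram cut (`hca_split()`, Ward
linkage by default, configurable) is provided alongside: on the ratio
indicator an average-linkage cut reproduces the printed 41/12, and on
cleanly separated two-group data the Ward cut matches the brute-force
variance-minimizing split, but dendrogram cuts on weakly separated 1-D
data are linkage-sensitive, which is why the threshold form is the
default reporting route. Exclusions are an explicit user-supplied list;
`flag_singletons()` offers a nearest-neighbour heuristic but never acts on
its own. Batch 51 satisfies the superior thresholds on its own numbers;
the published nine-batch superior set corresponds to applying the rule to
the non-excluded batches only.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes:

* **Detector response** — areas on the true line `a·C + b`, perturbed by
  multiplicative Gaussian noise (CV-parameterized; default 0.5%, the scale
  of the published instrument-precision RSDs of 0.42–0.75%), with an
  optional additive term for detection-limit experiments.
* **Retention times** — analyte-specific positions in the elution order
  GC < C < GV < V < GH < H, jittered by additive Gaussian noise (default
  SD 0.05 min).
* **Between-batch variation** — content vectors drawn multivariate-normal
  (negatives truncated to zero, mirroring the zero cells of the reference
  table) or moment-matched lognormal on a Gaussian copula; means, SDs and
  the 6 × 6 correlation are computed from the packaged 55-batch table at
  call time, so the simulated population mirrors the published spread
  (totals roughly 3–11 mg/g).

Zero-noise generation composed with the quantification chain is the exact
identity — the module-level oracle for the whole pipeline. All generators
are bit-reproducible under a fixed seed.

What the generator does **not** emulate: chromatographic peak shapes,
co-elution, baseline drift, matrix effects, inter-day instrument drift, or
any systematic ESM/QAMS divergence. Passing round-trip tests therefore
demonstrates the correctness of the computational chain, not the field
performance of the assay on real extracts.

Two generator behaviours worth knowing. First, truncation at zero biases
low-mean columns upward: for the one analyte whose mean sits within about
one SD of zero (V), simulated means run a few percent high, and the tests
assert exactly that split behaviour. Second, with multiplicative noise an
unweighted least-squares fit determines the intercept mostly from the
largest standards, so at concentrations below the bottom of the calibration
range the fitted intercept dominates and ESM (which subtracts it) and QAMS
(which does not) legitimately diverge; the pipeline test asserts 5%
method agreement for in-range cells only. This mirrors real practice:
contents quantified below the calibration range carry no agreement
guarantee.

## Packaged reference tables and misprint policy

The printed tables are shipped as CSV and treated as data. Where a printed
digit is internally inconsistent, the fixture stores the value implied by
the table's own redundant quantities, and the tests document each case:

* four cells of the 15-batch method-comparison table (the printed relative
  errors and nine-decimal correlations identify the intended last digit;
  all 75 relative-error cells then recompute to ±0.01, and the recomputed
  correlations match the printed ones to 1e−5);
* the sign of one printed composite score (batch 6), kept as printed in
  the fixture and excluded from the value-reproduction check;
* one printed total (batch 52, 10.300) that disagrees with the sum of its
  printed components (10.2945), kept as printed and asserted as the single
  exception.

The dilution ladder built from the printed stock concentrations spans the
printed linear ranges for all six analytes, which fixes the
stock-to-analyte assignment unambiguously.

## Problem sizes and numerical choices

Simulation-based tests use sizes chosen to make sampling error negligible
relative to the asserted tolerances: 5000 batches for moment/correlation
recovery (empirical correlations within 0.05 of target), 1000 replicates
for noise-CV calibration, 25 replicate samples for the round-trip bias
bound (< 1% at 0.5% area CV). Calibration is unweighted ordinary least
squares, matching the published `y = ax + b` fits. Negative regression
concentrations clamp to zero with a flag. Relative error uses the ESM
denominator, validated against the printed table
((4.289 − 4.295)/4.295 = −0.14%). Report rounding is two decimals for
relative errors and four significant figures for contents; internal
computation is full precision.

## Known limitations

* The package quantifies integrated peak areas; it is not a chromatogram
  processor. `integrate_trace()` is a deliberately simple
  trapezoid-over-linear-baseline utility for rendered traces, not a
  replacement for instrument integration software.
* Correction-factor durability can only be asserted for the conditions
  actually supplied; the 5% RSD bound is a convention, not a guarantee of
  transfer to unseen instruments.
* Uncertainty propagation beyond RSD (and e.g. Bland–Altman agreement
  analysis) is out of scope.
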