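---
title: "Methods: two-block fingerprinting, one-class modeling and ComDim fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-block fingerprinting, one-class modeling and ComDim fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemfuse)
```

This vignette documents the models behind `chemfuse`, the parameters that
matter, the choices made where the methodology is genuinely open, and what the
synthetic validation does and does not establish.

## The authentication problem

One-class ("class-modeling") authentication asks whether a sample is
compatible with a target population — here, extracts from one subregion —
without requiring a representative sample of everything else. The package
builds such models on two fingerprints of the same extracts: bucketed ¹H NMR
spectra and unfolded EEM fluorescence landscapes, separately and fused.

## NMR preprocessing

Spectra enter post-phasing and baseline correction. Bucketing integrates the
intensity (trapezoidal rule, with exact linear interpolation at interval
edges) over left-closed, right-open 0.04 ppm intervals anchored at 0.50 ppm
and ending at 10.00 ppm; the trailing 0.02 ppm remainder is dropped rather
than padded. Buckets are removed *whole* whenever their interval intersects an
exclusion region — the residual water band (4.50–5.20 ppm) and residual
methanol (3.28–3.40 ppm) by default — so excluded signal is never smeared into
a retained feature. The exclusion bounds are not aligned with the 0.04 ppm
grid at 3.28/3.40 ppm, which is why whole-bucket removal (rather than interval
clipping) is used.

Total-intensity normalization divides each row by its own sum. Whether the
total should be computed before or after the solvent exclusions is ambiguous
in practice; both orders are implemented (`normalize_total(..., total =
"retained" | "full")`) and differ only by a per-row scale, which vanishes
again after re-normalization. The default is the retained-bucket total.
Replicate spectra stay as separate rows, with grouping metadata carried along,
rather than being averaged.

## EEM preprocessing

Scatter handling masks all points within a half-bandwidth of three lines:
first-order Rayleigh (emission = excitation), second-order Rayleigh (emission
= 2 × excitation) and the solvent Raman line, placed at a fixed wavenumber
shift below the excitation line (3400 cm⁻¹ by default, the O–H stretch scale
appropriate for a methanol/water solvent; configurable). Default
half-bandwidths are ±10 / ±15 / ±10 nm — values typical of scatter-correction
practice; instruments with wider slits need wider bands. Masked values are
refilled by monotone (shape-preserving) cubic Hermite interpolation along the
emission mode within each excitation column, clipped at zero; a column with
fewer than two observed points is left missing and reported rather than
guessed. The physically meaningless region below the first-order Rayleigh band
is set to zero by default (switchable to masking or keeping).

Sample-mode normalization divides each slab by the standard deviation of its
own entries, removing per-sample intensity scale (dilution, lamp drift).
Unfolding flattens each slab with the *emission index fastest*; this is an
internal constant, and `refold()` inverts it exactly, which is how loading
vectors of models fitted on unfolded data are mapped back to
excitation/emission coordinates for interpretation.

## PARAFAC

The trilinear model is fitted by alternating least squares with
non-negativity on all three modes. Each mode update solves a ridge-free least
squares problem against the Khatri–Rao design; rows whose unconstrained
optimum is infeasible are re-solved exactly by active-set non-negative least
squares (batched over rows by support enumeration, since all rows share one
small F × F Gram matrix). Initialization is best-of-`n_starts` (default 10:
one SVD-based start, the rest uniform random, all seeded); convergence is a
relative change of the residual sum of squares below `tol = 1e-8`, capped at
`max_iter = 2000`. Loading columns are reported at unit maximum with scale
carried in the scores, components ordered by explained magnitude.

Rank selection tabulates CORCONDIA and explained variance over a candidate
range and takes the *largest* F with CORCONDIA at or above 80 — a documented,
automatic stand-in for the visual inspection a human analyst would do. Two
conventions are adopted: a one-component core is 100 by definition, and a
degenerate fit whose factor covariance is singular reports the diagnostic as
unavailable (treated as below threshold). On preprocessed (scatter-cleaned,
interpolated) cubes the scan can legitimately pick one component more than the
number of fluorophores, because interpolation residue is itself weakly
trilinear; the scan table, not the point choice, is the diagnostic product.

## One-class SIMCA

The target class is mean-centered against its own means and modeled by A
principal components. Two statistics bound the class: the Q residual (squared
distance from the subspace) with its Jackson–Mudholkar closed-form 95% limit
computed from the discarded eigenvalues, and Hotelling's T² (leverage within
the subspace) with the F-distribution limit `A (n² − 1) / (n (n − A)) ·
F₀.₉₅(A, n − A)`. The acceptance rule is the reduced distance — each statistic
normalized by its limit, combined in Euclidean form (a summed form is
available behind a switch). A sample exactly at both limits scores √2, the
default threshold before tuning.

Threshold tuning searches the midpoints between adjacent sorted distances
(plus one candidate below and above all of them) and maximizes sensitivity +
specificity; ties break toward higher sensitivity, then the smaller threshold.
The search is exhaustive over the candidate set, hence deterministic. Target
distances for tuning are computed leave-one-sample-out with replicates leaving
together, because replicate leakage across the fit/score boundary visibly
inflates sensitivity.

Component selection uses leave-one-out RMSECV plus cross-validated
sensitivity. A subtlety: the naive LOO residual (project the left-out sample,
measure the reconstruction error) decreases monotonically with A and cannot
locate a rank. The RMSECV here therefore predicts each *variable* of the
left-out sample from its other variables through the loadings, which has the
closed form `e_j = (x_j − r_j) / (1 − h_j)` with `r` the A-component
reconstruction and `h_j` the loading leverage — this curve turns upward past
the true rank. The chosen A is the smallest within 1% of the minimum RMSECV,
with exact ties resolved by CV sensitivity.

The duplex split alternates rounds between the calibration and test sides
(calibration first), each round claiming the two mutually farthest remaining
points in Euclidean distance on centered data, until the test side holds
⌈(1 − ratio) · n⌉ units; if one slot remains, the pair member farther from the
existing test set enters. Replicate groups are split as units via their
centroids. Outlier screening flags (never removes) samples with leverage above
`3 (A + 1) / n` or Q above its 95% limit on an all-data PCA.

## ComDim and the multiblock one-class classifier

Blocks are normalized in two recorded stages (point divisor, then Frobenius
divisor on concatenation) to equal total variance; the divisors — and the
block means, since blocks are mean-centered first — are replayed exactly on
new samples. Each common dimension is the leading eigenvector of
`W = Σ_b λ_b X_b X_bᵀ`, iterating the saliences `λ_b = qᵀ X_b X_bᵀ q` from
`λ_b = 1` until the largest salience change falls below 1e-10 (at most 500
iterations per CD), with a final eigen pass at the converged saliences so that
training projection reproduces the training scores to machine precision.
Eigenvector signs are fixed by making the largest-magnitude score positive.
Blocks are deflated by each CD before the next is extracted; a block's
salience on a CD equals exactly the variance of that block removed by the CD,
which makes the salience table directly interpretable and makes explained
variance a sum of saliences.

The multiblock one-class classifier fits ComDim on target-class samples only
and bounds it by the score distance (Mahalanobis distance of a sample's CD
scores to the training cloud, used without further pre-processing) and the
orthogonal distance (residual sum of squares after replaying all deflations,
concatenated across blocks by default; a block-wise variant normalizes each
block's OD by its own limit). Limits are moment-matched scaled chi-square on
SD² and OD at 95% (empirical quantiles behind a switch); the reduced-distance
rule and threshold tuning are identical to the single-block case. The number
of CDs defaults to the smallest count whose cumulative explained variance
reaches 90%, unless fixed by the user.

## The synthetic study: what it emulates, and what it does not

The generator reproduces the study conditions this package is exercised
against: three geographic classes, 10 samples per class, triplicate
measurements that share a sample's composition and differ only by instrument
noise. NMR peaks are Lorentzian (the natural lineshape), with markers at the
secoiridoid, sugar and organic-acid shifts listed in the library, plus solvent
residual lines placed inside the standard exclusion windows. Concentrations
and fluorophore abundances are log-normal around per-class means — positive by
construction, with class effects acting as fold changes; between-sample
log-sd defaults (0.15–0.25) are a realism judgment, since within-class
variances are not published for this kind of design. Fluorophores have
Gaussian excitation/emission profiles at literature maxima; scatter ridges sit
on the exact Rayleigh/Raman lines with widths at the monochromator-slit scale
(3–5 nm), i.e. well inside the default removal bands. EEM noise is additive
Gaussian and deliberately *not* clipped at zero: blank-subtracted landscapes
carry negative excursions, and clipping would add a spurious constant (hence
trilinear) offset that corrupts rank diagnostics. Default grids: excitation
250–450 nm in 10 nm steps, emission 250–530 nm in 2 nm steps; the drupe
fluorophore library needs the wider grid (excitation from 220 nm) given its
230 nm band.

The fusion generator places the class contrast per the chosen pattern; the
default "complementary" pattern gives each block only part of the
target-vs-rest signal, the regime in which mid-level fusion has headroom over
either single block.

Not simulated: J-coupling multiplets, pH-dependent shift drift, peak-position
misalignment between samples, inner-filter effects, Raman-unit calibration,
and any instrument drift structure. Passing tests on this generator therefore
demonstrate the correctness and calibration of the algorithms under the stated
model — not robustness to shift drift or matrix effects in real spectra, which
would additionally need alignment and more elaborate error models.

## Numerical choices and degenerate inputs

Ill-conditioned Gram matrices in the ALS updates get a relative ridge
(`1e-10 · (max|G| + 1)`); exactly low-rank target data yield a vanishing
positive Q limit so subspace membership still accepts; zero-variance slabs,
zero-norm blocks, non-positive row totals, grid mismatches and
decimal-comma numerics are hard errors that name the offending sample, file or
line. All randomness fans out from one master seed through per-stage string
hashes (`stage_seed()`), so any stage can be reproduced in isolation and the
full study report is bit-identical across runs.

## Problem sizes

The validation suite runs single cubes of 30 × 141 × 21 (samples × emission ×
excitation) for recovery and rank diagnostics (20 seeds at 2% noise), 500 ×
20 Gaussian classes for limit calibration (20 seeds), and 20 seeds of the full
two-block study (90 measurements, 215 NMR buckets, 2961 EEM variables) for the
fusion comparison — sizes chosen to match the study design while keeping the
whole suite within minutes on one CPU.

## Known limitations

The ComDim projection replays training deflations sequentially and assumes
new samples share the training variable sets exactly; there is no tolerance
for grid drift. CORCONDIA on non-negativity-constrained over-factored fits is
start-dependent — shallow multi-start searches can land on benign local optima
with misleadingly high core consistency, which is why the default is ten
starts. The threshold optimizer maximizes an unweighted sensitivity +
specificity sum; cost-sensitive authentication would need a weighted
objective. Specificity estimates on small stratified test sets are coarse
(steps of 1/n), a property of the design rather than the estimator.
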