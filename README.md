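# chemfuse

Two-block spectroscopic fingerprinting and mid-level data fusion for
geographic-origin authentication of plant extracts, built around the case of
olive (*Olea europaea*) leaves and drupes profiled by ¹H NMR and
excitation–emission matrix (EEM) fluorescence.

Chemical composition of olive tissues tracks soil, climate and agronomic
practice, so their spectroscopic fingerprints carry a geographic signature.
The question this package addresses is operational: given two cheap-to-orthogonal
fingerprints of the same extracts, can a one-class model certify that a sample
comes from a protected subregion — and does fusing the two blocks beat either
block alone? It is written for chemometricians and food-authenticity
researchers who want the full workflow as tested, scriptable functions rather
than GUI toolboxes.

## What is implemented

**NMR block.** Spectra are sectioned into 0.04 ppm buckets over 0.50–10.00 ppm;
buckets touching the residual water (4.50–5.20 ppm) and methanol
(3.28–3.40 ppm) regions are dropped whole; each row is normalized to total
intensity (`bucket()`, `normalize_total()`).

**EEM block.** Per-sample fluorescence landscapes are blank-subtracted, the
first/second-order Rayleigh and Raman scatter bands are masked and refilled by
shape-preserving interpolation along the emission mode, slabs are normalized
to unit variance, and the cube is unfolded to a samples × (emission ·
excitation) matrix with an exactly invertible `unfold()`/`refold()` bijection
(`remove_scatter()`, `interpolate_missing()`, `normalize_sample_variance()`).

**PARAFAC.** Non-negative trilinear decomposition
`X[i, j, k] = Σ_f a[i, f] · b[j, f] · c[k, f]` fitted by alternating least
squares (exact non-negative updates, multi-start, seeded), with the core
consistency diagnostic (CORCONDIA) and explained variance driving rank
selection (`fit_parafac()`, `corcondia()`, `select_components()`).

**One-class SIMCA.** A PCA model of the target class bounded by 95% limits on
the Q residual (Jackson–Mudholkar) and Hotelling T² (F-distribution); samples
are scored by the reduced distance

    d = sqrt( (Q / Q_0.95)² + (T² / T²_0.95)² )

with the acceptance threshold tuned to maximize sensitivity + specificity over
cross-validated distances. Component counts come from leave-one-out RMSECV
(corrected, leave-one-variable-out PRESS) with CV sensitivity as tie-break;
calibration/test splits use the deterministic duplex algorithm with replicate
triplicates kept together (`fit_simca()`, `reduced_distance()`,
`optimize_threshold()`, `select_n_components()`, `duplex_split()`,
`screen_outliers()`, `evaluate()`).

**ComDim fusion.** Blocks are normalized to equal total variance and the
common dimensions are extracted as leading eigenvectors of the
salience-weighted sum of per-block sample association matrices, with deflation
between dimensions; the per-block saliences say how strongly each block
expresses each CD. A multiblock one-class classifier bounds the ComDim score
distance (SD, Mahalanobis) and orthogonal distance (OD, deflation residual)
by moment-matched chi-square limits and applies the same reduced-distance rule
(`normalize_blocks()`, `fit_comdim()`, `project_comdim()`, `fit_mb_occ()`).

**Synthetic study.** Because the original field samples are not deposited, a
first-class generator builds class-structured data with known ground truth:
Lorentzian metabolite spectra (oleuropein 1.64/2.80/3.71/6.73 ppm, mannitol,
glucose, quinic and triterpenic acids, solvent residuals), trilinear EEM cubes
with Gaussian fluorophores at literature excitation/emission maxima plus
Rayleigh/Raman ridges, and paired two-block designs whose class contrast can
be placed in either block or split between them (`synthetic_config()`,
`generate_nmr()`, `generate_eem()`, `generate_fusion_dataset()`).

## Worked example

The `analysis/` scripts run the study end to end on the default synthetic
design (3 subregions × 10 samples × 3 replicate measurements):

```sh
Rscript analysis/01_simulate.R        # raw spectra + EEM cube -> scratch/data/
Rscript analysis/02_preprocess_nmr.R  # 215-bucket normalized table
Rscript analysis/03_preprocess_eem.R  # scatter-cleaned, unfolded cube
Rscript analysis/04_parafac.R         # rank scan + loadings
Rscript analysis/05_simca.R           # single-block one-class models
Rscript analysis/06_fusion.R          # ComDim + multiblock classifier
```

Stage 6 prints (seed 1):

```
ComDim: 3 CDs explain 94.4% of the fused variance
saliences (share of each CD per block):
      CD1   CD2   CD3
nmr 0.805 0.016 0.011
eem 0.195 0.984 0.989

fusion vs single blocks (test-set metrics, %):
     model  accuracy sensitivity specificity
 nmr_simca  66.66667         100    50.00000
 eem_simca  55.55556         100    33.33333
    mb_occ 100.00000         100   100.00000
```

Read: the NMR block dominates the first common dimension and the EEM block the
next two; because the simulated class contrast is complementary (each block
can reject only one of the two non-target subregions), each single-block SIMCA
tops out near 56–67% test accuracy while the fused classifier separates the
target subregion completely. The same pipeline is available as one call:
`run_study(study_config(rng_seed = 1))`.

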