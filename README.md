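# madmri

Multimodal apparent diffusion (MAD) modeling of multi-b-value
diffusion-weighted MRI, for imaging-biomarker studies that grade tumors —
in particular, distinguishing low-grade (WHO-ISUP 1–2) from high-grade
(3–4) clear cell renal cell carcinoma — without biopsy.

A mono-exponential apparent diffusion coefficient (ADC) compresses a
voxel's entire diffusion decay into one number and misses the
microstructural heterogeneity that distinguishes tumor grades. The MAD
model decomposes the normalized signal into four water pools:

    S(b)/S(0) = f_r·exp(−D_r·b) + f_h·exp(−D_h·b^α_h)
              + f_ui·exp(−D_ui·b) + f_f·exp(−D_f·b)

restricted (intracellular; D_r < 0.2 μm²/ms), hindered (extracellular,
stretched-exponential with exponent α_h; 0.2 ≤ D_h ≤ 3), unimpeded (free
water; D_ui fixed at 3) and flow (perfusion; D_f > 3), with fractions
summing to 1. b is handled internally in ms/μm² (= s/mm² ÷ 1000).

The package covers the full analysis chain, each stage usable alone:

* **Fitting** — voxel-wise bound-constrained multistart Levenberg–Marquardt
  least squares (`fitMAD`, `fitVolume`) plus log-linear ADC (`fitADC`);
  deterministic for a fixed seed.
* **ROI analysis** — masked means excluding failed-fit voxels, two-reader
  merging (`roiMean`, `extractSubject`, `combineReaders`).
* **Group statistics** — Kolmogorov–Smirnov/variance-gated t or
  Mann–Whitney comparisons, Cohen's d, clinical characteristics tables
  (`compareGroups`, `summarizeComparisons`, `clinicalSummary`).
* **Classification** — empirical ROC with trapezoid AUC, DeLong 95% CIs,
  Youden operating points, and a combined logistic biomarker of
  D_h + f_r + α_h (`rocAnalysis`, `evaluateCombined`, `diagnosticTable`).
* **Synthetic data** — the reference 12-b acquisition scheme with NEX
  averaging, Rician-noise phantoms with voxel-level ground truth, and
  grade-labeled cohorts drawn from published group distributions
  (`defaultScheme`, `makePhantom`, `makeCohort`).
* **I/O and pipeline** — NIfTI volumes and masks (via RNifti), plain-text
  b-tables, CSV cohorts, JSON ROC results, a reproducibility manifest, an
  end-to-end `runPipeline`, and a thin CLI (`inst/cli/madmri.R`).

## Worked example

Fit a noiseless curve generated from the published low-grade group means
(fractions renormalized to unit sum) on the reference 12-b scheme:

```r
library(madmri)
fr4 <- renormalizeFractions(c(fr = 0.060, fh = 0.413, fui = 0.275,
                              ff = 0.219))
truth <- madParameters(Dr = 0.039, Dh = 1.360, Df = 15.012,
                       fr = fr4["fr"], fh = fr4["fh"], fui = fr4["fui"],
                       ff = fr4["ff"], alphaH = 0.872)
fitMAD(madSignalCurve(truth, defaultScheme()))
#> MADFitResult: converged (residual 8.55e-17, R^2 1.0000, 8 starts)
#> MADParameters
#>   diffusivities (um^2/ms): Dr=0.039 Dh=1.36 Dui=3 Df=15.01
#>   fractions: fr=0.06205 fh=0.4271 fui=0.2844 ff=0.2265 (sum 1.000000)
#>   alphaH=0.872
```

The fitter recovers the generating parameters to machine precision —
D_h = 1.36 μm²/ms, α_h = 0.872, D_f = 15.01 μm²/ms and all four
fractions.

Simulate a 30/24 cohort from the two grade distributions and run the
statistical stage:

```r
cohort <- makeCohort(30, 24, seed = 1)
summarizeComparisons(cohort)$table[, c("parameter", "test", "pValue",
                                       "cohensD", "significant")]
#>   parameter         test       pValue    cohensD significant
#> 1        Dr mann-whitney 7.494357e-01 0.20720434       FALSE
#> 2        Dh mann-whitney 6.230256e-04 1.06073272        TRUE
#> 4        fr mann-whitney 4.700945e-09 2.03461142        TRUE
#> 9       ADC mann-whitney 2.080018e-06 1.45303037        TRUE
#> ...

diagnosticTable(cohort)$table
#>           name sensitivity specificity accuracy   auc ciLow ciHigh
#> 1          ADC       0.958       0.767    0.852 0.857 0.750  0.964
#> 2           Dh       0.625       0.900    0.778 0.767 0.631  0.903
#> 3           fr       0.833       0.900    0.870 0.922 0.846  0.999
#> 4       alphaH       0.292       0.900    0.630 0.522 0.355  0.689
#> 5 Dh+fr+alphaH       0.833       0.933    0.889 0.943 0.886  1.000
```

Under these synthetic conditions the hindered diffusivity and restricted
fraction separate the grades (high-grade: lower D_h, higher f_r), and the
combined D_h + f_r + α_h logistic model outperforms every single
parameter — the qualitative ordering such studies report. One cohort draw
is one hypothetical study; p-values and AUCs vary seed to seed.

The same chain runs from files (NIfTI DWI + b-table + masks + labels) via
`runPipeline(pipelineConfig(mode = "real", subjectsPath = ...))`, or from
the shell:

```sh
Rscript inst/cli/madmri.R simulate --seed 1 --out results_dir
```

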