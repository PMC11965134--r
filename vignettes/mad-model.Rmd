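---
title: "Multimodal apparent diffusion modeling with madmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal apparent diffusion modeling with madmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madmri)
```

## The signal model

Diffusion-weighted MRI attenuates the water signal by an amount that grows
with the diffusion weighting $b$ and with the mobility of water in the
voxel. A single apparent diffusion coefficient (ADC) summarizes this decay
as mono-exponential, which is adequate for free, Gaussian diffusion but not
for tumor tissue, where intracellular restriction, tortuous extracellular
paths, free fluid and capillary flow coexist in one voxel.

The multimodal apparent diffusion (MAD) model decomposes the normalized
signal into four compartments:

$$\frac{S(b)}{S(0)} \;=\;
  f_r\,e^{-D_r b} \;+\; f_h\,e^{-D_h b^{\alpha_h}} \;+\;
  f_{ui}\,e^{-D_{ui} b} \;+\; f_f\,e^{-D_f b},$$

with restricted ($D_r < 0.2\ \mu m^2/ms$), hindered
($0.2 \le D_h \le 3$), unimpeded ($D_{ui} \approx 3$) and flow
($D_f \gg 3$) diffusivities, signal fractions summing to one, and a
stretching exponent $\alpha_h$ that lets the hindered compartment deviate
from mono-exponential decay ($\alpha_h < 1$ means a broad distribution of
hindered rates). Only the hindered term is stretched: the restricted,
unimpeded and flow pools are modeled as single rates, and the stretching
exponent is read as the heterogeneity of the hindered pool specifically.

Two modeling conventions are fixed in this package:

* **Units.** $b$ is stored in $ms/\mu m^2$ ($1\ ms/\mu m^2 =
  1000\ s/mm^2$), so every product $D b$ is dimensionless. The stretched
  term raises the *numeric value* of $b$ in these units to $\alpha_h$;
  $b^{\alpha_h}$ is not dimensionally clean in any convention, so the unit
  in which it is evaluated is part of the model definition and is fixed
  here once.
* **The unimpeded diffusivity is a constant**, $D_{ui} = 3\ \mu m^2/ms$
  (free water at body temperature). Fitting it would be collinear with the
  upper range of $D_h$ — the two compartments become the same exponential
  as $D_h \to 3,\ \alpha_h \to 1$ — so it is not a free parameter.

The mono-exponential ADC is computed alongside, by ordinary least squares
of $\log S$ on $b$ over all b-values. Using the full 0–3 $ms/\mu m^2$ range
mixes fast and slow pools into one number; that is deliberate, because a
fixed protocol-wide definition keeps ADC comparable across subjects.

## The reference acquisition

`defaultScheme()` encodes the reference protocol: 12 b-values 0, 20, 50,
100, 200, 500, 800, 1000, 1500, 2000, 2500, 3000 $s/mm^2$ with per-b
averaging counts (NEX) 1, 1, 1, 1, 1, 2, 3, 3, 4, 6, 8, 9. The dense low-b
sampling resolves the fast flow compartment; the heavy high-b averaging
compensates the low SNR where only the restricted pool retains signal.
Schemes must start at exactly $b = 0$ (the normalization point), be
strictly increasing, and offer at least 6 distinct b-values before the MAD
fit will run (8 free quantities need headroom).

## Fitting

`fitMAD()` performs bound-constrained Levenberg–Marquardt least squares
(via minpack.lm) over seven free parameters: $D_r, D_h, D_f, \alpha_h$ and
three fractions, with $f_f = 1 - f_r - f_h - f_{ui}$ as the remainder. A
penalty residual keeps the implied $f_f$ non-negative; the returned
fractions are renormalized so they sum to one within $10^{-9}$. Analytic
Jacobians are supplied for speed and stability.

Four-term exponential fitting has local minima, so the optimizer is
multistarted (`nMultistart = 8` by default): the first start is a
deterministic segmented log-linear heuristic — flow from the initial drop
($b \le 0.1$), hindered rate from the mid range ($0.2 \le b \le 1$), the
restricted fraction from the high-b plateau ($b \ge 2$) — and the rest are
seeded perturbations of it, alternating local jitter and box-uniform
draws. The whole start set derives once from the configuration seed, so a
fit is a pure function of (curve, config): re-runs are bit-identical and
volume fitting is independent of voxel visit order. The lowest residual
wins; ties break to the earliest start. Reproducibility is preferred over
elegance here.

Degenerate inputs have defined behaviour rather than surprises: a flat
curve fits as "no decay" with bound flags set; a curve that is not
normalized is rejected; optimizer failure on every start returns
`converged = FALSE` (such voxels become NaN in maps and are excluded from
ROI means) instead of throwing. ADC log-fits drop — never clamp — signals
at or below `minSignalFloor` (default $10^{-6}$ of $S(0)$), recording how
many points were used; negative ADC estimates are reported but flagged
unphysical.

```{r fit-example}
truth <- madParameters(Dr = 0.039, Dh = 1.360, Df = 15.012,
                       fr = 0.062, fh = 0.4271, fui = 0.2844, ff = 0.2265,
                       alphaH = 0.872)
fit <- fitMAD(madSignalCurve(truth, defaultScheme()))
round(paramVector(madParams(fit)), 4)
```

## What the synthetic data emulate — and what they do not

The generator reproduces the statistical structure the analysis assumes,
not kidney anatomy:

* **Group distributions.** `lowGradeDistribution()` and
  `highGradeDistribution()` hold per-parameter means and SDs of ROI-mean
  MAD parameters (plus ADC) for low- and high-grade clear cell renal cell
  carcinoma, e.g. $D_h$ 1.360 ± 0.112 vs 1.254 ± 0.134 $\mu m^2/ms$, $f_r$
  0.060 ± 0.005 vs 0.080 ± 0.009, $\alpha_h$ 0.872 ± 0.224 vs
  0.896 ± 0.393. Quantities published as median (IQR) ($D_r$, $f_{ui}$)
  are converted with the normal-theory rule SD ≈ IQR/1.349. Draws are
  independent truncated normals inside the physical bounds.
* **Fraction renormalization.** Published ROI-mean fractions sum to 0.967
  (low) and 0.992 (high), not 1 — each map is averaged independently, so
  the means need not close. For signal synthesis the four fractions must
  sum to one; `renormalizeFractions()` rescales proportionally, or holds
  one fraction at its printed value and rescales the rest when a test
  targets that specific value.
* **Noise.** `addRicianNoise()` draws per-b magnitudes
  $|S + \eta_1 + i\eta_2|$ with per-channel Gaussian noise and averages
  NEX independent draws, mirroring scanner magnitude averaging. SNR 50 at
  $b=0$ means $\sigma = 1/50$ of $S(0)$. A Gaussian debug mode exists.
* **Cohorts.** `makeCohort()` draws one ROI-mean vector per subject
  (default 30 low / 24 high, the reference study size). The subject-level
  draw stands in for ROI averaging: only ROI-level summaries are published,
  so voxel-level covariance within a subject is unknowable and is not
  modeled.

Known departures from real data, hence limits on what passing tests show:
parameters are drawn independently (no covariance between, say, $D_h$ and
$\alpha_h$); lesions are homogeneous in distribution with no partial
volume, necrosis, motion or eddy artifacts; and registration between
b-volumes is assumed perfect. Synthetic success is a check of the
estimation and statistics machinery, not evidence about scanner data.

## Identifiability: what a single voxel can and cannot tell you

Noiseless curves on the 12-b scheme are recovered essentially exactly (the
validation suite fits 50 random parameter sets drawn across the
physiologic interior — $D_h \in [0.7, 2.2]$, $\alpha_h \in [0.6, 1.3]$,
fractions near tissue-like proportions — and demands 2% relative
agreement). The interior restriction is principled, not cosmetic: at the
degenerate corner $D_h \to 3, \alpha_h \to 1$ the hindered and unimpeded
compartments are the *same* exponential and no fitter can apportion their
fractions.

Under noise a sharper limit appears. Profiling the least-squares surface
shows that doubling $f_r$ (with the other parameters re-optimized) changes
the best-achievable model curve by only a few times $10^{-4}$ rms per
point on this scheme: $f_r$ and $\alpha_h$ trade off along a nearly flat
ridge, and distinguishing positions on that ridge requires noise below
roughly $10^{-4}$–$10^{-3}$ of $S(0)$ — far beyond clinical SNR. At SNR 50
the single-voxel least-squares estimates of $f_r$ and $\alpha_h$ are
therefore strongly spread *and* median-biased (upward, toward the long arm
of the ridge), and $D_h$ is dragged part of the way with them; averaging
more voxels reduces variance but not this bias. This is a property of the
estimation problem, not of the optimizer: the fitted solutions have lower
residuals than the generating truth. The practical reading is that
voxel-wise $f_r$/$\alpha_h$ maps are qualitative at clinical noise levels,
while ROI-level contrasts of the kind the statistical stage tests remain
meaningful because they compare groups of subjects, not voxels against
truth. The package states this limitation rather than papering over it;
the corresponding phantom recovery check is intentionally strict and
documents the failure mode.

## Statistics

`compareGroups()` mirrors standard two-group practice: a one-sample
Kolmogorov–Smirnov check against a normal with estimated mean and SD per
group, an F-test for equal variances ($\alpha = 0.05$), then a pooled
two-sample t-test (summaries as mean ± SD) when both pass, otherwise a
two-sided Mann–Whitney U test (median with quartiles). Estimating the KS
parameters from the sample makes that gate conservative; this is the
common software behaviour and is accepted, not corrected. The F-test was
chosen because the variance condition needs *some* test; it sits isolated
behind the gate so it can be swapped. Cohen's d is always computed from
the group moments with the pooled-SD formula
$\lvert \bar x_1 - \bar x_2 \rvert / s_p$,
$s_p^2 = ((n_1{-}1)s_1^2 + (n_2{-}1)s_2^2)/(n_1+n_2-2)$. No
multiple-comparison correction is applied by default (nine exploratory
comparisons); `summarizeComparisons(..., adjust = "bonferroni")` or any
`p.adjust` method turns one on.

`clinicalSummary()` produces the standard characteristics table: counts
with percentages $100\,n/N$ per group, rounded to one decimal, plus age
median and range.

## Diagnostic evaluation

`rocCurve()` computes the empirical ROC over all distinct thresholds with
trapezoid AUC, auto-orienting so AUC ≥ 0.5 and recording the direction.
The operating point is Youden's $J = \text{sens} + \text{spec} - 1$, ties
broken toward higher specificity — the criterion is unstated in much of
the applied literature, and Youden is the field default; it is isolated in
`youdenPoint()` for substitution. AUC confidence intervals use the DeLong
variance (via pROC), clipped to [0, 1]. `evaluateCombined()` fits a
multiple logistic regression on the chosen parameters (default $D_h$,
$f_r$, $\alpha_h$), standardizing features internally and reporting
coefficients on the original scale, and scores its *in-sample* predicted
probabilities — matching the usual single-cohort evaluation; no
cross-validation is claimed. With 54 subjects and three features,
perfect separation can occur; the fit then falls back to a small ridge
penalty and is flagged (`converged = FALSE`, `ridged = TRUE`) rather than
returning infinite coefficients.

```{r cohort-example}
cohort <- makeCohort(30, 24, seed = 1)
summarizeComparisons(cohort)$table[, c("parameter", "test", "pValue",
                                       "cohensD", "significant")]
```

## Validation scale and reproducibility

The test suite works at sizes chosen to make each check sharp but cheap:
single curves and 50-set recovery suites for the fitter, a
10×10×2-voxel two-tissue phantom (100 voxels per tissue) for noisy
recovery, 100 seeded cohorts of 30/24 for the statistical-behaviour
checks, and 400 replicates of 500 + 500 binormal scores for DeLong
coverage. Every random stage takes an explicit seed, derived child seeds
stay below $2^{31}$, and generation, fitting and evaluation are
bit-reproducible from (seed, configuration); the output manifest records
the seed and a configuration hash so a run can be re-created from it.

## Limitations

Beyond the identifiability ceiling discussed above: no diffusion-tensor or
gradient-direction handling (trace-weighted DWI is assumed); no Rician
noise-floor correction during fitting; no spatial regularization across
voxels; no automated lesion segmentation (masks are inputs); and the
combined-model evaluation is in-sample by design. These are boundaries of
scope, each either inherited from the analysis being modeled or stated
here as a package decision.
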