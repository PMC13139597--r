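---
title: "Phenotyping dairy-cow heat-stress response from milk FT-MIR spectra"
author: "heatmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping dairy-cow heat-stress response from milk FT-MIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmir)
```

## The problem

Heat stress depresses dairy-cow welfare and production, but the direct
physiological readouts (body temperature) are impractical to record at
scale, while production losses are unspecific and require weather data to
interpret. Milk Fourier-transform mid-infrared (FT-MIR) spectra are
recorded routinely at every milk recording and respond to the
compositional changes that heat stress induces, so they are a candidate
proxy for an individual, routinely recordable heat-stress response
phenotype.

`heatmir` implements the full chain that turns this idea into a tested
pipeline:

1. **Heat load** — hourly THI from dry-bulb temperature and relative
   humidity, daily means, and the windowed value
   $\mathrm{THI}_{\overline{td-3d}}$ (rounded mean of the test day and the
   three preceding days) that captures the lag between heat load and its
   effect.
2. **Expectation model** — a single-trait random-regression test-day model
   solved by Henderson's mixed-model equations gives, for each milk trait,
   the residual of the observed value against what is expected for that
   cow, herd, season and lactation stage. Standardized residuals of
   protein % and Mg concentration are the milk-side stress indicators.
3. **Reference phenotype** — udder surface temperatures recorded during a
   heat-wave visit and a thermoneutral visit define, together with the
   residuals, three ordered reference classes (X0 non-affected, X0.5
   intermediate, X1 affected).
4. **Spectral calibration** — a gap-5 first derivative, selection of 212
   informative points, and a correlation pre-selection feed a PLS
   regression of surface temperature and a two-stage random-forest
   classifier of the three classes, both validated with cow-period
   grouped 5-fold cross-validation.
5. **Combination and population analysis** — the two predictions combine
   into a phenotype in {0, 0.5, 1} (value 1 requires a predicted
   temperature of at least 36 °C *and* class X1), which is Snell-scored
   and analysed at population scale with a second mixed model to profile
   susceptibility by lactation number, lactation stage and milk-yield
   class.

Because no public dataset accompanies this design, the package ships a
synthetic-data generator as a first-class, tested module; every stage of
the pipeline is exercised against data whose ground truth is known.

## The models

### THI

$$\mathrm{THI} = (1.8\,T + 32) - (0.55 - 0.0055\,\mathrm{RH})\,(1.8\,T - 26)$$

with $T$ in °C and RH in percent. The index is strictly increasing in $T$
(slope $1.8(0.45 + 0.0055\,\mathrm{RH})$), and increasing in RH exactly
above $T = 130/9 \approx 14.44$ °C, where the bracketed term changes
sign — both identities are asserted on a grid in the tests. Daily THI is
the mean of the 24 hourly values (strict completeness by default; a
lenient mode accepts ≥ 20 hours and reports the deviation);
`thiWindow()` rounds the 4-day mean half away from zero, a tie policy the
formula's provenance leaves open and which we fix and document here.

### Test-day model

For each trait (milk yield, fat %, protein %, Mg),

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Q}(\mathbf{Z}_1\mathbf{a} + \mathbf{Z}_2\mathbf{p}) + \mathbf{e}$$

with fixed effects herd × year, month of recording (12), lactation-number
class (1, 2, 3+) and 19 DIM classes; the printed DIM bins overlap at 305
("251–305, 305–365"), resolved here as 251–304 / 305–365. Each animal
carries three additive-genetic and three permanent-environment regression
coefficients on Legendre polynomials $P_0 = 1$, $P_1 = x$,
$P_2 = (3x^2-1)/2$ of standardized DIM
$x = 2(\mathrm{DIM}-5)/360 - 1$ capped at 1. The genetic coefficients have
covariance $G_a \otimes A$ with $A$ the numerator relationship matrix;
$A^{-1}$ is built directly from the pedigree by Henderson's rules
(inbreeding ignored — the generator mates unrelated animals, so the rules
are exact there, and the oracle tests enforce it).

The equations are assembled sparsely (`Matrix`) and solved by sparse
factorization rather than an iterative conjugate-gradient scheme: at the
problem sizes this package targets (≤ ~10^4 records, ≤ ~5·10^3 equations)
a direct sparse solve is exact, faster, and removes a tolerance knob. The
dense direct-inversion oracle remains in the test suite, where the sparse
path must agree to 10⁻⁸ relative error on hundreds of random instances.

No variance components are estimable from the design (none are reported
for it), so they are user-supplied; the default gives moderate shrinkage
($G_a = G_p = \mathrm{diag}(0.2, 0.02, 0.01)\,\sigma^2_y$,
$\sigma^2_e = 0.5\,\sigma^2_y$) and every fit records the components used.
Residuals are standardized by their population SD (the n convention; at
the intended n the difference from n − 1 is negligible).

### Reference classes and training set

With per-farm thermoneutral statistics (mean and sample SD of the visit's
mean udder temperatures), a heat-wave record is **X1** iff its
temperature exceeds mean + 3 SD *and* both standardized residuals
(protein %, Mg) are below −0.1; **X0** iff the temperature is below
mean + 2 SD *and* both residuals are at or above −0.1; otherwise
**X0.5**. All inequalities are strict, so records in the 2–3 SD gap or
exactly at −0.1 are intermediate by construction (property-tested). The
−0.1 margin absorbs normal trait fluctuation. The training set adds
seeded draws from historical records outside June–August with windowed
THI below 60 to balance the X0 class, and a seeded sample of
intermediates of size |X1|.

### Spectral calibration

The gap-5 first derivative subtracts the absorbance at point $i+2$ from
the absorbance at point $i-2$, following the operator's stated direction
(a global sign flip is irrelevant to PLS and forests and is available as
the conventional variant); 1,060 points give 1,056 derivative values on
points 3–1,058, of which the four informative regions (points 12–170,
210–218, 223–230, 495–530; 968.09–2,965.98 cm⁻¹) retain 212. Points whose
absolute Pearson correlation with the calibration temperatures reaches
0.3 enter the PLS ("at least 0.3" is read as |r| since the heat signature
plausibly has both signs); the pre-selection is redone inside each
cross-validation fold by default so that no validation information leaks
into the variable choice (the simpler once-globally variant is a flag).
PLS uses mixOmics with mean-centering and unit-variance scaling; R²cv
pools the out-of-fold predictions against the global mean. The forest
(ranger) uses 500 trees, mtry = ⌊√p⌋ of the actual feature count (the
commonly quoted 26 is ⌊√679⌋-specific), node size 1 and Gini splitting;
a first forest ranks impurity importance and the final forest keeps the
top 50 variables plus the month-risk dummy (April–September = 1), which
is force-included as a deliberate predictor.

Cross-validation groups by cow-temperature period, not cow: a cow may
legitimately appear in calibration under one thermal period and in
validation under the other, which exposes condition-dependent rather than
individual-specific signal; no (cow, period) key ever appears on both
sides of a fold, and the fitting code asserts this on every run.

### Combination, Snell scores, population model

A record combines to 1 iff predicted temperature ≥ 36 °C and predicted
class X1; to 0.5 iff ≥ 36 °C and X0.5; else 0 — monotone in both inputs.
For the population model, records keep DIM 5–365, milk yield ≥ 3 kg and
herd test-days (HTD) with ≥ 10 records (the HTD count is evaluated after
the record-level filters and re-checked once, making the filter
idempotent). The combined phenotype is transformed to Snell scores under
a standard-logistic liability: cumulative class proportions place the
boundaries at $t_k = \ln(P_k/(1-P_k))$ and each class scores the mean of
the logistic variable truncated to its interval. Several Snell-score
variants circulate in the animal-breeding literature (with different
liability assumptions and affine rescalings) and give different
numerical scores for the same frequencies, so the variant used here is
fixed and documented deliberately; any affine rescaling of the scores
leaves the mixed-model solution contrasts unchanged. The population model reuses the MME solver
with scalar animal (pedigree covariance) and permanent-environment
effects and variance ratios defaulting to 0.05 : 0.05 : 0.90 of the score
variance.

## What the generator emulates

`simulationConfig()` defines a temperate, Belgian-like study:

* **Weather** — seasonal (amplitude 6.5 °C around 8.5 °C, peak mid-July)
  plus diurnal (4 °C, peak 15:00) sinusoids with noise; RH anticorrelated
  with temperature, clipped to [5, 100] %. Thermoneutral summer days sit
  just below daily THI 60; each configured heat wave's bump is calibrated
  by root-finding so the peak day's daily THI equals the target (73 in
  June of odd study years, 75 in August of even years — real heat waves
  shift across the summer, and this staggering also keeps stressed
  records a small minority of every month-of-recording level, which is
  what lets the residual analysis see the depression rather than absorb
  it into the month effect).
* **Herds** — founder sires shared across farms, per-cow tolerance
  ~ N(0.3, 0.25²) clamped to [0, 1], staggered calvings, and two herd
  recording days per month (a frequent-recording scheme; it keeps
  desk-scale factor levels well populated).
* **Effective heat load** — one quantity drives everything:
  $\max(0, \mathrm{THI}_{\overline{td-3d}} - 60) \times (1-\text{tolerance})
  \times m_{\text{parity}} \times m_{\text{DIM}}$ with parity multipliers
  (0.75, 1, 1.25) and a Gaussian DIM susceptibility bump (peak 35 d,
  width 18 d, floor 0.3). Traits, spectra and surface temperatures all
  respond to this same load, so the pipeline's detection target is well
  defined and the population analysis has a planted parity ordering and
  an early-lactation susceptibility window to recover.
* **Traits** — Wilmink-type lactation curves; planted depressions per
  unit load of 0.03 % protein, 1.2 mg/L Mg (herd mean ≈ 100 mg/L — the
  unit is an explicit config convention, and only standardized residuals
  are used downstream, so the scale cancels), 0.25 kg milk scaled by
  yield level, and a near-zero 0.005 % for fat — reproducing the
  observed pattern that protein and Mg are the informative traits.
  On wave-day records these land at roughly −0.4 to −0.9 residual SD.
* **Spectra** — a fixed smooth baseline plus fat/protein/Mg band profiles
  scaled by the record's composition, plus a heat-stress signature
  (bands of both signs inside the informative regions, 0.003 absorbance
  per load unit) and i.i.d. noise (0.0015). With these
  signal-to-noise choices roughly 70–100 of the 212 points pass the
  |r| ≥ 0.3 pre-selection and cross-validated R² lands near 0.9.
* **Surface temperatures** — PM (visit-day afternoon THI) and AM
  (next-morning THI, cooler overnight) values at farm baseline 35.1 °C
  plus 0.3 °C per load unit and 0.35 °C noise; the stored record is the
  PM/AM mean, one per cow and visit. Visits happen twice in the final
  study year: on the peak day of the summer's strongest wave and on a
  thermoneutral October day.

What the generator does **not** emulate: instrument-family standardization
effects, scatter/water artefacts, culling and incomplete lactations,
seasonal calving policies, inbreeding, SCC-related udder pathology, or
any cold-side response — so passing tests demonstrate internal
consistency of the method under its own assumptions, not field
performance. Real-data headline numbers depend on private reference
records and are deliberately out of scope.

## Problem sizes and reproducibility

The bundled runs are sized for a desk machine: the residual-recovery
study uses 2 farms × 100 cows × 2 years (≈ 7,400 records, ≈ 2,800
equations) and the population run 3 farms × 60 cows × 2 years (≈ 7,000
predictions); both complete in well under a minute each. The THI-bin
summary suppresses bins under a configurable minimum (1,000 at
population scale, 50 in desk runs). One master seed derives fixed child
seeds per generator component, so identical configurations produce
byte-identical CSV exports; fold assignment, training-set draws and
forests take explicit seeds.

At these sizes the population analysis resolves the planted lactation
ordering and DIM peak, with one caveat stated plainly: the middle
lactation contrast (class 2 vs 1) is close to the desk-scale resolution
limit and can invert under an unlucky seed, while the 3+ vs 1 contrast
and the DIM-window peak are robust.

## Degenerate inputs and numerical choices

* Incomplete weather days error in strict mode and are tolerated to
  ≥ 20 h in lenient mode; a missing day inside a THI window names the
  missing dates.
* Zero-variance spectral columns are dropped before correlation
  pre-selection (undefined r); a constant temperature target errors.
* A factor level that would make the fixed-effect block singular (after
  the first-level-zero constraints) raises an error naming the
  confounding; single-level factors simply contribute nothing.
* PLS component counts are capped by the selected-feature count and
  calibration size with a warning; at full rank the fit equals ordinary
  least squares (tested to 10⁻⁸).
* The Snell construction requires all class frequencies positive; the
  pipeline falls back to the raw 0/0.5/1 values with a warning when a
  class is absent at small scale.
* Ties in THI rounding go half away from zero; exact hits of the
  classification thresholds fall to the intermediate class.

## A worked run

```{r pipeline, eval = FALSE}
res <- runHeatStressPipeline(populationConfig(seed = 42, nFarms = 3,
                                              nCowsPerFarm = 60, nYears = 2))
res$plsModel       # pre-selected points, components, R2cv / RMSEcv
res$rfModel        # out-of-fold confusion and accuracy
res$thiSummary     # mean combined phenotype per windowed-THI bin
solutionProfile(res$populationFit, "lactation")
```

The pipeline's interface is these composable exported functions; each
stage (`generateWeather()` … `thiBinnedMeans()`) can equally be run on
its own artifacts, and `runHeatStressPipeline(outdir = ...)` writes every
stage's CSV plus a plain-text manifest of the configuration and seeds.
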