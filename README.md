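# heatmir

Heat stress depresses dairy-cow welfare, milk yield and milk composition,
but the direct physiological readout — body temperature — cannot be
recorded routinely at population scale, and production losses alone are
unspecific. Milk Fourier-transform mid-infrared (FT-MIR) spectra are
already collected at every official milk recording and reflect the
compositional changes heat stress induces, so they can carry an
individual, routinely recordable **heat-stress response phenotype**.

`heatmir` implements that idea as a complete, tested pipeline for
quantitative geneticists and dairy scientists:

* **Heat load**: hourly temperature-humidity index
  `THI = (1.8T + 32) − (0.55 − 0.0055·RH)(1.8T − 26)`, daily means, and
  the windowed value THI_td-3d (rounded mean of the test day and the 3
  preceding days).
* **Expectation model**: the single-trait random-regression test-day
  model `y = Xb + Q(Z1·a + Z2·p) + e` (herd×year, month,
  lactation-class and 19 DIM-class fixed effects; second-degree Legendre
  random regressions with pedigree covariance `G_a ⊗ A`), solved by
  Henderson's sparse mixed-model equations with `A⁻¹` built directly
  from the pedigree. Standardized residuals of protein % and Mg flag
  milk-side stress.
* **Reference classes** from udder surface temperatures: X1 (affected)
  iff temperature > farm thermoneutral mean + 3 SD and both residuals
  < −0.1; X0 (non-affected) iff < mean + 2 SD and both ≥ −0.1; X0.5
  otherwise.
* **Spectral calibration**: gap-5 first derivative (1,060 → 1,056
  points), 212-point informative-region mask, |r| ≥ 0.3 pre-selection,
  then PLS regression of surface temperature and a two-stage
  random-forest classifier (500 trees, Gini, top-50 variables + a
  month-risk dummy), both under cow-period-grouped 5-fold
  cross-validation with a leakage assertion.
* **Combined phenotype**: 1 iff predicted temperature ≥ 36 °C and class
  X1, 0.5 iff ≥ 36 °C and X0.5, else 0 — then Snell scoring and a
  population mixed model profiling susceptibility by lactation number,
  DIM class and milk-yield class.
* **Synthetic studies**: a first-class generator (weather with
  calibrated heat waves, pedigree, lactation-curve traits with planted
  THI-dependent depressions, spectra with a planted heat signature,
  surface temperatures) so the whole chain is testable with no external
  data.

## A worked example

```r
library(heatmir)
res <- runHeatStressPipeline(populationConfig(seed = 42, nFarms = 3,
                                              nCowsPerFarm = 60, nYears = 2))
res$plsModel
#> PlsTemperatureModel: 3 latent variables on 78 pre-selected points (|r| >= 0.30)
#>   R2cv 0.927, RMSEcv 0.285 degrees C
res$rfModel
#> RfClassModel: 51 retained variables, out-of-fold accuracy 0.776
tail(res$thiSummary, 4)
#>    thi   n mean_combined mean_pred_temp
#> 26  61  97     0.0000000       35.21325
#> 27  67 132     0.2803030       36.00013
#> 28  68  79     0.3670886       36.15754
#> 31  71 100     0.6400000       36.60520
solutionProfile(res$populationFit, "lactation")
#>   level   estimate
#> 1     1 0.00000000
#> 2     2 0.01785654
#> 3     3 0.08579384
```

Reading the output: the PLS temperature model cross-validates at
R²cv 0.93 with an error of 0.29 °C on this synthetic study; the
classifier reaches 78 % out-of-fold accuracy on the three reference
classes; the combined phenotype averages exactly 0 in every windowed-THI
bin below 61 and climbs to 0.64 at THI 71 — the planted
threshold-and-rise pattern; and the population model recovers the
planted susceptibility ordering (lactation 3+ > 2 > 1, with the
DIM-solution peak in early lactation). `runHeatStressPipeline(outdir=)`
writes each stage's CSV artifact plus a run manifest; every stage is
also an exported function that can be composed directly.

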