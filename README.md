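# CaOxQuant

Quantitative phase analysis of calcium oxalate kidney stones in R.

Calcium oxalate stones are mixtures of two pseudo-polymorphs — the
stable monohydrate (COM) and the metastable dihydrate (COD) — and the
spatial COM/COD ratio across a stone records how it nucleated and grew.
CaOxQuant implements three complementary assays of that ratio, plus a
synthetic-data generator that makes every stage testable with known
ground truth:

* **FTIR, 780 cm⁻¹ peak decomposition** (the core method).  Both
  hydrates absorb at 780 cm⁻¹, but COD's band is much broader, so at
  ~800 cm⁻¹ only COD still absorbs.  A geometric construction splits
  the baseline-corrected peak height into a COM share
  M = |PR|/|PC| and a COD share D = 1 − M, and a two-branch linear
  calibration

  &nbsp;&nbsp;&nbsp;&nbsp;Y = M/D = a·(m/d) + b  (m < d),&nbsp;&nbsp;
  Y′ = D/M = a′·(d/m) + b′  (d < m)

  links the shares to the weight contents m, d.  The coefficients are
  instrument-dependent and fitted from standards measured in
  replicate; inversion reports wt% with propagated uncertainty.
* **Comparison FTIR analyses**: the 910/780 cm⁻¹ band ratio and the
  1324 cm⁻¹ C–O peak shift, re-calibrated on the same standards, with
  a side-by-side comparison table (`compareMethods()`).
* **Kramers-Kronig preprocessing** for reflection-mode microscopy:
  specular reflectance → absorption index via an FFT Hilbert phase
  (`kkTransform()`), plus atmospheric H₂O/CO₂ subtraction
  (`subtractAtmosphere()`).
* **Micro-CT phase mapping**: stone segmentation, attenuation-based
  COM/COD voxel classification (COM is denser, hence brighter), and
  per-ROI / whole-stone fractions at 50 µm scale (`classifyPhases()`,
  `roiFractions()`, `mapFractions()`).
* **PXRD phase identification**: peak detection and presence/absence
  calls against the characteristic triplets COD ~{14.3°, 20.1°, 32.2°}
  and COM ~{14.9°, 24.4°, 30.1°} (Cu Kα1), with Mo Kα1 support via
  Bragg conversion (`detectPeaks()`, `identifyPhases()`).

## Worked example

Calibrate from synthetic standards (11 levels × 6 replicates, noise SD
0.002), then quantify an "unknown" 30/70 mixture:

```r
library(CaOxQuant)

cfg <- generatorConfig(noiseSD = 0.002)
std <- makeCalibrationSet(seq(0, 1, 0.1), nReps = 6, config = cfg,
                          seed = 42)
cal <- fitCalibration(std)
cal
#> CalibrationModel (two-branch linear, Y = a X + b)
#>   COM-minor (m<d)  Y =M/D vs X =m/d: a = 1.2466, b = 0.0478 (R^2 = 0.99958, n = 36)
#>   COM-major (d<m)  Y'=D/M vs X'=d/m: a = 0.7645, b = 0.0066 (R^2 = 0.99974, n = 36)
#>   instrument: synthetic-ftir-v1, mode: absorbance

sample <- subtractAtmosphere(makeMixtureSpectrum(0.30, cfg, seed = 7))
quantify780(sample, cal)
#> MixtureResult: COM 29.6 wt% / COD 70.4 wt% (+/- 0.4 wt%) [minor]
```

The estimate recovers the true 30 wt% COM on the COM-minor branch; the
quoted ±0.4 wt% combines the calibration residual SD with the share
replicate SD.  A pure-COD diffraction pattern resolves to the expected
phase call:

```r
identifyPattern(makePXRDPattern("COD", seed = 1))
#>   phase score present n_matched
#> 1   COM     0   FALSE         0
#> 2   COD     1    TRUE         3
```

An end-to-end pipeline (simulate → calibrate → quantify, with a file
manifest and reproducible seeds) is available as `runSimulate()`,
`runCalibrate()`, `runQuantify()`, or from the shell via
`inst/scripts/caox-pipeline.R`.

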