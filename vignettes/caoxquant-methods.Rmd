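---
title: "Quantifying COM and COD in kidney stones: methods and design notes"
author: "CaOxQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying COM and COD in kidney stones: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaOxQuant)
```

## The problem

Calcium oxalate kidney stones are mixtures of two pseudo-polymorphs:
the monohydrate (COM, whewellite), the thermodynamically stable phase,
and the dihydrate (COD, weddellite), a metastable phase that nucleates
first at high supersaturation and later transforms to COM.  Where and in
what proportion the two phases occur across a stone records how the
stone grew, so a spatially resolved, quantitative COM/COD assay is the
measurement of interest.  The package implements three complementary
routes to that assay — infrared microspectroscopy, micro-CT attenuation
mapping, and powder-diffraction phase identification — together with a
synthetic-data module that generates all three kinds of input with known
ground truth, so that every stage of the analysis is testable without
access to patient material.

## The 780 cm^-1 decomposition (Analysis 1)

Both hydrates absorb at 780 cm^-1 (a C–H/O–C–O bending mode), but the
COD band is much broader than the COM band, so at about 800 cm^-1 only
COD still absorbs appreciably.  The decomposition turns that contrast
into a two-phase assay with a ruler-and-pencil construction on the
spectrum:

* P — the peak value at 780 cm^-1;
* O, Q — the bottoms of the valleys flanking the peak;
* the chord OQ — the local baseline; C is OQ evaluated at P's
  wavenumber;
* R′ — the measured value at 800 cm^-1; R is R′ carried to P's
  wavenumber along a parallel to OQ.

The COM share of the baseline-corrected peak height is M = |PR|/|PC|,
and the COD share is D = |RC|/|PC| = 1 − M.  Writing m and d for the
COM and COD contents of a specimen, the shares follow two linear
calibration branches,

\[ Y = M/D = a\,(m/d) + b \quad (m < d), \qquad
   Y' = D/M = a'\,(d/m) + b' \quad (d < m), \]

whose four coefficients depend on the instrument and are fitted from
standards of known composition, each measured six times
(`fitCalibration()`).  `estimateComposition()` inverts the branch
selected by the measured shares (ties go to the COM-minor branch; the
branches agree at the crossover to well under 1 wt%, so the choice is
immaterial) and reports weight percent with a one-sigma uncertainty
obtained by propagating, in quadrature, the branch residual SD and the
replicate SD of the shares through the inverse map.  The method's
overall confidence, verified by the parameter-recovery tests, is
±10 wt%.

### Numerical choices in the geometry

* **Valley location.** O and Q are the support points of the chord that
  stays below the spectrum across the peak — the bridging edge of the
  lower convex hull over the two valley windows (left 700–770, right
  810–900 cm^-1; the apex is searched in 770–790 cm^-1).  Support
  points of a convex hull are invariant under adding any linear
  function, so the decomposition is *exactly* baseline-immune: a ramp
  added to the spectrum changes M by less than 10^-9 in the test suite.
  A plain per-window minimum would lose this exactness whenever a
  tilted baseline slides the discrete argmin along a flat valley.
* **R′ at exactly 800 cm^-1** by linear interpolation; the offset is a
  configurable parameter (`rprimeAt`) because the reference point is
  conventional rather than fundamental.
* **Clamping.** Noise can push R outside the segment [C, P]; R is
  clamped into it, so M ∈ [0, 1] and M + D = 1 always.
* **Replicates** are aggregated by averaging shares, not spectra; the
  per-level share SD feeds the uncertainty.

### Mol versus weight fractions

Standards are conventionally mixed by mole while results are reported
by weight; `molToWeight()`/`weightToMol()` convert using molar masses
146.11 (COM) and 164.13 g/mol (COD).  Weight percent is the reporting
default throughout.

## The comparison analyses

Two published alternatives are re-implemented for side-by-side
comparison (`compareMethods()`), both *re-calibrated on the same
synthetic standards* rather than using any literature coefficients,
because all such coefficients are apparatus-dependent:

* **Analysis 2 — 910/780 band ratio** (`bandRatioQuant()`): the
  910 cm^-1 band belongs to COD only; the baseline-corrected height
  ratio A910/A780 falls monotonically with COM content and is inverted
  through a monotone piecewise-linear interpolant (no functional form
  is imposed, since none is established).
* **Analysis 3 — 1324 cm^-1 peak shift** (`peakShiftQuant()`): the C–O
  stretch sits near 1316 cm^-1 in COM and 1328 cm^-1 in COD; the merged
  band's apex position (quadratic interpolation through the three
  points around the discrete maximum) maps linearly to composition.

On clean two-phase mixtures all three analyses agree within ±10 wt%.
Their scientific difference appears when other stone components absorb
nearby: an organic-matrix-like interferent with amide-type bands
(1655/1545 cm^-1), an amide-III-type band at 1310 cm^-1 and a weak band
at 900 cm^-1 corrupts the 910 cm^-1 height and drags the C–O apex,
while leaving the 700–810 cm^-1 region essentially untouched.  Under
that interferent the 780 cm^-1 decomposition stays within its ±10 wt%
quote while Analyses 2 and 3 err by tens of weight percent — the
robustness contrast that motivates preferring Analysis 1.

## Reflectance spectra and the Kramers-Kronig transform

Reflection-mode microscopy measures specular reflectance R(ν), which is
distorted by anomalous dispersion of the refractive index and cannot be
used like an absorbance spectrum.  `kkTransform()` recovers the
absorption index k(ν): the reflection phase φ(ν) is the Kramers-Kronig
(Hilbert) transform of ln√R, computed by FFT after even-symmetric
extension about zero wavenumber, with ln√R extrapolated as a constant
below and above the measured range (the standard mitigation of
finite-range truncation); then ñ = (1 + √R e^{iφ})/(1 − √R e^{iφ}) and
k = Im ñ.  Normal incidence is assumed.  Small negative k excursions
are a truncation artefact and are clamped at zero, with a warning below
−0.01.  Against a Lorentz-oscillator ground truth
(`makeReflectanceSpectrum()`, which returns the closed-form k) the
recovered apex lands within 2 cm^-1 and 5% of height, and halving the
grid step changes the apex height by under 1%.

Which quantity a reflection-mode workflow should feed into the 780
cm^-1 geometry is a convention; the package treats the KK output as an
absorption-index spectrum behind an explicit `mode` tag, and
`quantify780()` enforces that samples and calibration share a mode, so
reflectance-derived samples are only ever quantified against a
calibration built from equally processed spectra.

## CT attenuation mapping

COM is denser than COD, so in micro-CT (default 0.005 mm/voxel) COM
attenuates more.  The pipeline is: `segmentStone()` (Otsu threshold
between background and stone, largest connected component, hole
filling), then `classifyPhases()`:

* voxels under the stone/background threshold inside the mask become
  void/resin;
* the COD/COM threshold is estimated by Otsu on an eroded stone core
  and refined to the midpoint of the two class means, which treats
  blurred domain-boundary voxels symmetrically;
* a surface ring (twice the PSF SD, default 2 voxels) is excluded from
  the map — those voxels blend stone and background attenuation and
  carry no phase information;
* contrast is accepted only if Otsu's separability (between-class over
  total variance) reaches 0.85 and the minority class holds at least 2%
  of the voxels; otherwise the map is single-phase, flagged
  `"no phase contrast"`.

Because all thresholds derive from the histogram shape, classification
is invariant to affine rescaling of intensities.  `roiFractions()`
reports COM% = COM/(COM+COD) per ROI (void voxels excluded from the
denominator — the package's resolution of an ambiguity in how such
percentages are conventionally quoted), with a default ROI of 10×10
voxels = a 50 µm square; `mapFractions()` tiles the stone and adds the
whole-stone aggregate.  CT phase mapping is only valid when crystal
domains are resolvable: phantoms whose domain size is at or below twice
the blur SD propagate a `"sub-resolution"` flag through to every ROI
row.

## PXRD phase identification

Diffraction is used for presence/absence only, not quantification.
`detectPeaks()` subtracts a rolling-median background, smooths lightly
(a 7-point boxcar, narrow relative to the 0.12° peak FWHM), and keeps
local maxima above max(2% of the largest peak, 5 robust SDs of the
corrected signal), refining positions by quadratic interpolation.
`identifyPhases()` scores each phase by the fraction of its
characteristic triplet matched within 0.15° — COD at ~14.3°, 20.1°,
32.2°; COM at ~14.9°, 24.4°, 30.1° (Cu Kα1) — and calls a phase present
at a score of 2/3.  Patterns measured with Mo Kα1 are matched after
converting the reference positions through the d-spacing (Bragg's law,
λ = 1.5406 Å vs 0.7093 Å); the conversion round-trips to < 0.01°.

## The synthetic-data generator

The generator exists so that every claim above is tested against known
truth.  Its defaults define the study conditions used throughout the
tests and the acceptance script:

* **Grid** 600–4000 cm^-1 at 1 cm^-1.
* **Band sets.** Versioned constants in `defaultCOMBands()` /
  `defaultCODBands()`.  Centers follow conventional assignments (O–H
  stretch 3200–3550, C=O stretch ~1620–1640, C–O stretch ~1316/1328,
  bending bands 661–910 cm^-1); heights and widths are design choices,
  not measured values.  Both bases are normalised to a unit 780 cm^-1
  apex.
* **The COD 780-complex** is a broad body (FWHM 96, centered 790
  cm^-1) plus a narrow apex sub-band at 780 cm^-1, so the COD basis
  peaks at 780 yet retains ~95% of its baseline-corrected apex value at
  800 cm^-1.  This encodes the decomposition's own modelling
  assumption — the 800 cm^-1 reading captures COD's full contribution
  while COM contributes under 5% of its apex there — and it is exactly
  what makes *both* calibration branches linear: with the 800/780
  response ratio r of the COD basis, the COM-minor branch is linear for
  any r, but the COM-major branch is linear only as r → 1.  Real COD
  bands are narrower (r further from 1), which is one reason the
  method's practical confidence is ±10 wt% rather than the sub-percent
  recovery seen on the idealised generator.
* **C–O bands** at 1316/1328 cm^-1 with equal normalised heights and
  FWHM 40, so the merged apex of a mixture traverses 1324 cm^-1 nearly
  linearly in composition — the condition under which a linear
  peak-shift calibration is well-posed.
* **Atmosphere**: a synthetic CO2 doublet at 2340/2361 cm^-1 and a
  deterministic comb of narrow H2O lines over 1300–1900 and 3500–3900
  cm^-1, scaled by 0.05/0.03 by default.  Only their subtraction
  behaviour matters: `subtractAtmosphere()` fits the CO2 scale by
  restricted least squares in 2300–2400 cm^-1 (where the sample is
  transparent) and the H2O scale on second differences inside the H2O
  windows, where the narrow lines dominate and broad sample bands
  vanish.  The H2O lines deliberately overlap the 1324 cm^-1 analysis
  region, so skipping the correction visibly degrades Analysis 3.
* **Noise** SD 0.002 absorbance units; six replicates per standard.
* **CT phantoms**: disc-shaped stone (512×512 default; the tests use
  128–256 to keep runtimes in seconds), square crystal domains of 8
  voxels by default, attenuation means 0.80/0.60/0.25/0.05 for
  COM/COD/resin/air, Gaussian PSF sigma 1 voxel, noise 5% of the
  COM–COD gap.  COM domains are drawn from a shuffled urn until the
  target voxel share is met, so the truth fraction matches the target
  to within one domain rather than with binomial scatter.
* **PXRD**: pseudo-Voigt peaks (FWHM 0.12°, η = 0.3) at the
  characteristic triplets plus minor peaks chosen not to collide with
  the other phase's triplet, a decaying background with fixed
  peak-to-background ratio, and optional Poisson counting noise.

What the generator does *not* emulate: other mineral phases (apatite,
brushite, urate), preferred orientation and texture in diffraction,
instrument line-shape functions, detector nonlinearity, beam hardening
or physically calibrated CT units, and the impurity of real laboratory
standards.  Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not instrument-grade validation on
real stones.

## Problem sizes and determinism

Every generator accepts a seed and restores the caller's RNG state;
identical seeds give bit-identical artefacts, including the files
written by `runSimulate()`.  The test suite and the acceptance script
use reduced problem sizes chosen for seconds-scale runtimes — CT
phantoms of 128–256 voxels per side instead of 512, 20–30 seeds per
stochastic check, 50 diffraction patterns — sizes at which the measured
quantities are already stable to well within the tolerances asserted.

## Known limitations

* The package quantifies the COM/COD pair only; other stone phases are
  out of scope, and spectra dominated by them will fail the geometry's
  sanity checks rather than produce numbers.
* The two-branch calibration is linear by construction; strongly
  nonlinear instrument responses would need a different model.
* CT phase mapping degrades as crystal size approaches the PSF scale;
  the sub-resolution flag marks, but does not correct, that regime.
* The minimal JCAMP-DX reader covers the AFFN `(X++(Y..Y))` form only.
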