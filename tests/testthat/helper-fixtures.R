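## Shared fixtures, built in code.  Small grids keep the suite fast; the
## analysis windows (700-960, 1290-1350 cm-1) are always covered.

quietConfig <- function(...) generatorConfig(noiseSD = 0, ...)

## noiseless, atmosphere-corrected mixture spectrum
cleanMixture <- function(w, config = quietConfig()) {
    subtractAtmosphere(makeMixtureSpectrum(w, config, noise = FALSE))
}

## noiseless standards at the default levels, one replicate
cleanStandards <- function(config = quietConfig(),
                           levels = seq(0, 1, by = 0.1)) {
    lapply(levels, cleanMixture, config = config)
}

## a bare Gaussian band on a chosen baseline, as a Spectrum
gaussianSpectrum <- function(center = 780, height = 1, fwhm = 12,
                             grid = seq(600, 1000, by = 1),
                             baseline = 0) {
    y <- height * exp(-4 * log(2) * ((grid - center) / fwhm)^2) + baseline
    Spectrum(grid, y, "absorbance")
}

## independent line-intersection oracle for the peak-decomposition
## shares: explicit two-point line equations, no shared code with
## locatePeakGeometry/computeShares
oracleShares <- function(P, O, Q, Rp) {
    ## baseline through O and Q
    sl <- (Q[2] - O[2]) / (Q[1] - O[1])
    C <- O[2] + sl * (P[1] - O[1])
    ## line through R' with the same slope, evaluated at P's wavenumber
    R <- Rp[2] + sl * (P[1] - Rp[1])
    R <- min(max(R, C), P[2])
    M <- (P[2] - R) / (P[2] - C)
    min(max(M, 0), 1)
}
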