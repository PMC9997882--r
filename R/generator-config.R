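#' Describe one spectral band
#'
#' A band is a symmetric line-shape profile: Gaussian, Lorentzian, or a
#' pseudo-Voigt blend \eqn{\eta L + (1-\eta) G} sharing one FWHM.
#'
#' @param center band center, cm^-1 (or degrees 2-theta for diffraction).
#' @param height apex height, absorbance units (nonnegative).
#' @param fwhm full width at half maximum, same axis units (positive).
#' @param shape \code{"gaussian"}, \code{"lorentzian"} or
#'   \code{"pseudo-voigt"}.
#' @param eta Lorentzian mixing fraction in [0, 1]; only used for
#'   \code{"pseudo-voigt"}.
#' @return a \code{spectralBand} list.
#' @examples
#' spectralBand(780, 1, 12)
#' @export
spectralBand <- function(center, height, fwhm,
                         shape = c("gaussian", "lorentzian", "pseudo-voigt"),
                         eta = 0.5) {
    shape <- match.arg(shape)
    stopifnot(is.finite(center), height >= 0, fwhm > 0,
              eta >= 0, eta <= 1)
    structure(list(center = center, height = height, fwhm = fwhm,
                   shape = shape, eta = eta),
              class = "spectralBand")
}

.evalBand <- function(band, x) {
    u <- (x - band$center) / band$fwhm
    g <- exp(-4 * log(2) * u^2)
    if (band$shape == "gaussian")
        return(band$height * g)
    l <- 1 / (1 + 4 * u^2)
    if (band$shape == "lorentzian")
        return(band$height * l)
    band$height * (band$eta * l + (1 - band$eta) * g)
}

.evalBands <- function(bands, x) {
    y <- numeric(length(x))
    for (b in bands) y <- y + .evalBand(b, x)
    y
}

## Versioned default band sets for the two calcium oxalate hydrates.
## Centers follow the conventional assignments (O-H stretch, C=O stretch,
## C-O stretch, C-H/O-C-O bends); heights and widths are generator choices
## made to satisfy the structural constraints the quantification methods
## rely on, not measured values:
##  * both hydrates peak at 780 cm-1, COM narrowly (FWHM 12), COD broadly;
##  * the COD 780-complex keeps ~95% of its baseline-corrected apex value
##    at 800 cm-1 (broad component centered 790, FWHM 96, plus a narrow
##    apex sub-band at 780), encoding the decomposition's assumption that
##    the 800 cm-1 reading carries COD's full peak contribution while COM
##    contributes essentially nothing there (< 5% of its apex);
##  * the 910 cm-1 band exists only in COD;
##  * the C-O stretch sits at 1316 (COM) vs 1328 (COD) so a mixture apex
##    traverses 1324 cm-1.
## Raw heights of the non-780 COD bands are scaled so that, after the
## 780-apex normalisation, their relative heights are conventional.

#' Default COM band set
#' @return list of [spectralBand()] objects.
#' @export
defaultCOMBands <- function() {
    list(
        spectralBand(3440, 0.90, 320),             # O-H stretch
        spectralBand(1618, 2.60, 60),              # C=O stretch
        spectralBand(1316, 1.20, 40),              # C-O stretch
        spectralBand(885,  0.35, 16),              # C-H / O-C-O bend
        spectralBand(780,  1.00, 12),              # the analytical peak
        spectralBand(661,  0.30, 14)               # O-C-O in-plane bend
    )
}

#' Default COD band set
#' @return list of [spectralBand()] objects.
#' @export
defaultCODBands <- function() {
    ## 780-complex apex evaluates to ~20.0 raw units; companion bands are
    ## pre-scaled by that factor so normalised relative heights are ~1.0
    ## (O-H), 2.4 (C=O), 1.1 (C-O), 0.35 (910).
    list(
        spectralBand(3470, 20.0, 280),             # O-H stretch
        spectralBand(1640, 48.0, 60),              # C=O stretch
        spectralBand(1328, 24.0, 40),              # C-O stretch
        spectralBand(910,  7.0, 18),               # COD-specific bend
        spectralBand(790, 19.53, 96),              # broad 780-complex body
        spectralBand(780,  1.00, 5)                # apex sub-band at 780
    )
}

#' Default interferent band set (organic matrix analogue)
#'
#' A non-oxalate component emulating the organic matrix of real stones:
#' strong amide-like bands at 1655/1545 cm^-1, an amide-III-like band at
#' 1310 cm^-1 that overlaps the C-O peak-shift analysis, and a weak band
#' at 900 cm^-1 that overlaps the 910 cm^-1 band-ratio analysis.  The
#' 700-810 cm^-1 region carries only negligible tails, which is what
#' leaves the 780 cm^-1 decomposition comparatively unaffected.
#' @return list of [spectralBand()] objects.
#' @export
defaultInterferentBands <- function() {
    list(
        spectralBand(1655, 1.80, 70),
        spectralBand(1545, 1.10, 65),
        spectralBand(1310, 0.80, 55),
        spectralBand(900,  0.30, 40)
    )
}

#' Assemble a synthetic-spectra generator configuration
#'
#' @param gridMin,gridMax,gridStep wavenumber grid, cm^-1.  The default
#'   600-4000 cm^-1 at 1 cm^-1 covers the usual mid-IR measurement range;
#'   the grid must cover 675-900 cm^-1 or the 780 cm^-1 geometry is
#'   undefined.
#' @param comBands,codBands band lists for the two pure phases.
#' @param noiseSD Gaussian noise standard deviation, absorbance units.
#' @param baseline numeric polynomial coefficients (intercept first),
#'   evaluated in the scaled variable (wavenumber/1000).
#' @param h2oScale,co2Scale default atmospheric contamination scales.
#' @param referenceHeight normalised 780 cm^-1 apex height of each basis.
#' @param interferentBands optional band list for a non-oxalate component.
#' @param interferentScale its weight relative to the oxalate signal.
#' @param instrument free-form tag recorded in every output; calibrations
#'   refuse to mix tags.
#' @return a \code{generatorConfig} list.
#' @examples
#' cfg <- generatorConfig(noiseSD = 0)
#' @export
generatorConfig <- function(gridMin = 600, gridMax = 4000, gridStep = 1,
                            comBands = defaultCOMBands(),
                            codBands = defaultCODBands(),
                            noiseSD = 0.002,
                            baseline = c(0.05, -0.01),
                            h2oScale = 0.03, co2Scale = 0.05,
                            referenceHeight = 1.0,
                            interferentBands = NULL,
                            interferentScale = 0,
                            instrument = "synthetic-ftir-v1") {
    stopifnot(gridMin < gridMax, gridStep > 0, noiseSD >= 0,
              referenceHeight > 0, interferentScale >= 0)
    if (gridMin > 675 || gridMax < 900)
        stop("grid must cover 675-900 cm-1; the 780 cm-1 peak geometry ",
             "is undefined otherwise")
    structure(list(
        grid = seq(gridMin, gridMax, by = gridStep),
        gridStep = gridStep,
        comBands = comBands, codBands = codBands,
        noiseSD = noiseSD, baseline = baseline,
        h2oScale = h2oScale, co2Scale = co2Scale,
        referenceHeight = referenceHeight,
        interferentBands = interferentBands,
        interferentScale = interferentScale,
        instrument = instrument
    ), class = "generatorConfig")
}

## Evaluate a polynomial baseline on a wavenumber grid (scaled variable
## keeps coefficients O(1)).
.evalBaseline <- function(coefs, grid) {
    if (is.null(coefs) || !length(coefs)) return(numeric(length(grid)))
    x <- grid / 1000
    y <- numeric(length(grid))
    for (i in seq_along(coefs)) y <- y + coefs[i] * x^(i - 1)
    y
}

## Run expr with a temporary RNG state seeded by `seed`; restores the
## caller's RNG so generators never perturb user randomness.
.withSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Molar masses of the calcium oxalate hydrates (g/mol)
#' @return named numeric: COM 146.11 (CaC2O4.H2O), COD 164.13
#'   (CaC2O4.2H2O).
#' @export
molarMasses <- function() c(COM = 146.11, COD = 164.13)

#' Convert between mol fraction and weight fraction of COM
#'
#' Standards are mixed by mole, results are reported by weight; these two
#' helpers reconcile the conventions.
#'
#' @param x mol fraction of COM in [0, 1].
#' @return weight fraction of COM.
#' @examples
#' molToWeight(0.5)      # 146.11 / 310.24
#' weightToMol(molToWeight(0.3))
#' @export
molToWeight <- function(x) {
    stopifnot(all(x >= 0 & x <= 1))
    mw <- molarMasses()
    x * mw[["COM"]] / (x * mw[["COM"]] + (1 - x) * mw[["COD"]])
}

#' @rdname molToWeight
#' @param w weight fraction of COM in [0, 1].
#' @export
weightToMol <- function(w) {
    stopifnot(all(w >= 0 & w <= 1))
    mw <- molarMasses()
    (w / mw[["COM"]]) / (w / mw[["COM"]] + (1 - w) / mw[["COD"]])
}
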