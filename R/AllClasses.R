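#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

.validLengths <- function(x, y, nx, ny) {
    if (length(x) != length(y))
        return(sprintf("'%s' and '%s' must have equal length", nx, ny))
    if (length(x) < 2L)
        return(sprintf("'%s' must contain at least two points", nx))
    if (any(!is.finite(x)))
        return(sprintf("'%s' must be finite", nx))
    if (any(diff(x) <= 0))
        return(sprintf("'%s' must be strictly increasing", nx))
    NULL
}

#' Spectrum: a sampled intensity-versus-wavenumber curve
#'
#' The central 1-D container of the package. A \code{Spectrum} holds a
#' strictly increasing wavenumber axis (cm\eqn{^{-1}}), the matching
#' intensity values, a \code{mode} tag saying what the values are
#' physically, and free-form metadata (seed, provenance, corrections
#' applied).  The mode tag is load-bearing: the 780 cm\eqn{^{-1}}
#' decomposition accepts absorbance or absorption-index spectra, the
#' Kramers-Kronig transform accepts reflectance only, and the pipeline
#' refuses to quantify a sample against a calibration built in a different
#' mode.
#'
#' @slot wavenumber numeric, strictly increasing, cm\eqn{^{-1}}.
#' @slot intensity numeric, same length as \code{wavenumber}.
#' @slot mode one of \code{"absorbance"}, \code{"reflectance"},
#'   \code{"absorption-index"}.  Reflectance values must lie in [0, 1].
#' @slot metadata named list.
#'
#' @seealso [Spectrum()] for the constructor, [readSpectrum()],
#'   [kkTransform()], [locatePeakGeometry()].
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        wavenumber = "numeric",
        intensity  = "numeric",
        mode       = "character",
        metadata   = "list"
    ),
    prototype(mode = "absorbance", metadata = list())
)

.SPECTRUM_MODES <- c("absorbance", "reflectance", "absorption-index")

setValidity("Spectrum", function(object) {
    msg <- .validLengths(object@wavenumber, object@intensity,
                         "wavenumber", "intensity")
    if (!is.null(msg)) return(msg)
    if (length(object@mode) != 1L || !object@mode %in% .SPECTRUM_MODES)
        return(sprintf("'mode' must be one of %s",
                       paste(sQuote(.SPECTRUM_MODES), collapse = ", ")))
    if (object@mode == "reflectance" &&
        (min(object@intensity) < 0 || max(object@intensity) > 1))
        return("reflectance values must lie in [0, 1]")
    TRUE
})

#' Powder X-ray diffraction pattern
#'
#' Intensity versus diffraction angle 2\eqn{\theta} (degrees), with a
#' radiation tag used to convert peak positions between anodes via Bragg's
#' law (d-spacings are radiation-independent).
#'
#' @slot twoTheta numeric, strictly increasing, degrees.
#' @slot intensity numeric counts, nonnegative.
#' @slot radiation \code{"CuKa1"} (default) or \code{"MoKa1"}.
#' @slot metadata named list.
#' @seealso [PXRDPattern()], [detectPeaks()], [identifyPhases()].
#' @exportClass PXRDPattern
setClass("PXRDPattern",
    representation(
        twoTheta  = "numeric",
        intensity = "numeric",
        radiation = "character",
        metadata  = "list"
    ),
    prototype(radiation = "CuKa1", metadata = list())
)

.RADIATION_WAVELENGTHS <- c(CuKa1 = 1.5406, MoKa1 = 0.7093) # Angstrom

setValidity("PXRDPattern", function(object) {
    msg <- .validLengths(object@twoTheta, object@intensity,
                         "twoTheta", "intensity")
    if (!is.null(msg)) return(msg)
    if (any(object@intensity < 0))
        return("intensities must be nonnegative")
    if (length(object@radiation) != 1L ||
        !object@radiation %in% names(.RADIATION_WAVELENGTHS))
        return(sprintf("'radiation' must be one of %s",
                       paste(sQuote(names(.RADIATION_WAVELENGTHS)),
                             collapse = ", ")))
    TRUE
})

#' Micro-CT slice image
#'
#' A 2-D grid of X-ray attenuation values (arbitrary CT units) with the
#' physical voxel size.  COM is denser than COD and attenuates more, which
#' is what makes attenuation-based phase mapping possible.
#'
#' @slot values numeric matrix of attenuation values.
#' @slot voxelSize voxel edge length in mm (default 0.005).
#' @slot metadata named list (acquisition settings, phantom ground truth).
#' @seealso [CTImage()], [segmentStone()], [classifyPhases()].
#' @exportClass CTImage
setClass("CTImage",
    representation(
        values    = "matrix",
        voxelSize = "numeric",
        metadata  = "list"
    ),
    prototype(voxelSize = 0.005, metadata = list())
)

setValidity("CTImage", function(object) {
    if (!is.numeric(object@values))
        return("'values' must be a numeric matrix")
    if (any(!is.finite(object@values)))
        return("'values' must be finite")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
        return("'voxelSize' must be a single positive number")
    TRUE
})

#' Per-voxel phase labels for a CT slice
#'
#' Result of [classifyPhases()]: an integer label matrix over the input
#' image (codes in \code{.PHASE_LEVELS}: background, void/resin, COD, COM),
#' the stone mask, and the thresholds that produced the labels.
#'
#' @slot labels integer matrix, same dimension as the source image.
#' @slot mask logical matrix, TRUE inside the stone.
#' @slot thresholds named numeric vector of the class boundaries used.
#' @slot voxelSize voxel edge length in mm.
#' @slot flags character vector, e.g. \code{"no phase contrast"},
#'   \code{"sub-resolution"}.
#' @slot metadata named list.
#' @seealso [roiFractions()], [mapFractions()].
#' @exportClass PhaseMap
setClass("PhaseMap",
    representation(
        labels     = "matrix",
        mask       = "matrix",
        thresholds = "numeric",
        voxelSize  = "numeric",
        flags      = "character",
        metadata   = "list"
    ),
    prototype(flags = character(), metadata = list(), voxelSize = 0.005)
)

.PHASE_LEVELS <- c(background = 0L, void = 1L, COD = 2L, COM = 3L)

setValidity("PhaseMap", function(object) {
    if (!all(dim(object@labels) == dim(object@mask)))
        return("'labels' and 'mask' must have identical dimensions")
    if (!all(object@labels %in% .PHASE_LEVELS))
        return("'labels' contains codes outside the phase level set")
    if (any(object@labels[!object@mask] %in%
            .PHASE_LEVELS[c("COD", "COM")]))
        return("phase labels must lie inside the stone mask")
    TRUE
})

#' Six-point geometry of the 780 cm-1 peak decomposition
#'
#' The construction that splits the 780 cm\eqn{^{-1}} peak height into COM
#' and COD contributions.  P is the apex; O and Q are the flanking valley
#' minima; the chord OQ is the local baseline; C is OQ evaluated at P's
#' wavenumber; R' is the measured value at 800 cm\eqn{^{-1}}; R lies at P's
#' wavenumber on the line through R' parallel to OQ.  Segment PR is the COM
#' contribution to the peak height and RC the COD contribution.
#'
#' @slot P,O,Q,Rprime,C,R numeric length-2 vectors \code{(wavenumber,
#'   value)}.
#' @slot lengths named numeric vector with elements \code{PR}, \code{RC},
#'   \code{PC} (all nonnegative; \code{PR + RC == PC} after clamping).
#' @seealso [locatePeakGeometry()], [computeShares()].
#' @exportClass PeakGeometry
setClass("PeakGeometry",
    representation(
        P = "numeric", O = "numeric", Q = "numeric",
        Rprime = "numeric", C = "numeric", R = "numeric",
        lengths = "numeric"
    )
)

setValidity("PeakGeometry", function(object) {
    pts <- list(P = object@P, O = object@O, Q = object@Q,
                Rprime = object@Rprime, C = object@C, R = object@R)
    for (nm in names(pts))
        if (length(pts[[nm]]) != 2L || any(!is.finite(pts[[nm]])))
            return(sprintf("point '%s' must be a finite (wavenumber, value) pair", nm))
    if (!(object@O[1L] < object@P[1L] && object@P[1L] < object@Q[1L]))
        return("wavenumber ordering O < P < Q violated")
    len <- object@lengths
    if (!all(c("PR", "RC", "PC") %in% names(len)))
        return("'lengths' must contain PR, RC and PC")
    if (any(len < 0))
        return("segment lengths must be nonnegative")
    if (abs(len[["PR"]] + len[["RC"]] - len[["PC"]]) > 1e-9 * max(len[["PC"]], 1))
        return("PR + RC must equal PC")
    TRUE
})

#' COM/COD absorption shares of the 780 cm-1 peak
#'
#' M is the fraction of the baseline-corrected 780 cm\eqn{^{-1}} peak
#' height attributed to COM, D the fraction attributed to COD;
#' M + D = 1 by construction.
#'
#' @slot M,D numeric in [0, 1], summing to 1.
#' @seealso [computeShares()], [fitCalibration()], [estimateComposition()].
#' @exportClass AbsorptionShares
setClass("AbsorptionShares",
    representation(M = "numeric", D = "numeric"))

setValidity("AbsorptionShares", function(object) {
    if (length(object@M) != 1L || length(object@D) != 1L)
        return("'M' and 'D' must be scalars")
    if (object@M < 0 || object@M > 1 || object@D < 0 || object@D > 1)
        return("'M' and 'D' must lie in [0, 1]")
    if (abs(object@M + object@D - 1) > 1e-9)
        return("M + D must equal 1")
    TRUE
})

#' Two-branch linear calibration for the 780 cm-1 decomposition
#'
#' Stores the instrument-dependent coefficients of the two calibration
#' lines: Y = M/D = a (m/d) + b on the COM-minor branch (m < d) and
#' Y' = D/M = a' (d/m) + b' on the COM-major branch (d < m), where m and d
#' are the COM and COD contents of the standards and M, D the measured
#' absorption shares.  Fit diagnostics (R-squared, residual SD, per-level
#' replicate SD) travel with the coefficients, as does an instrument tag:
#' the coefficients are apparatus-dependent and a model must never be
#' applied to spectra from a differently configured source.
#'
#' @slot minor named numeric \code{c(a, b)} for the m < d branch
#'   (\code{NA} if the branch could not be fitted).
#' @slot major named numeric \code{c(a, b)} for the d < m branch.
#' @slot diagnostics list with per-branch \code{r.squared},
#'   \code{sigma} (residual SD), \code{coef.se}, \code{n}, and per-level
#'   replicate SDs.
#' @slot instrument character tag of the generating instrument/generator.
#' @slot mode spectral mode the calibration was built from.
#' @slot seed integer seed recorded at creation (NA if none).
#' @seealso [fitCalibration()], [estimateComposition()],
#'   [writeCalibration()].
#' @exportClass CalibrationModel
setClass("CalibrationModel",
    representation(
        minor       = "numeric",
        major       = "numeric",
        diagnostics = "list",
        instrument  = "character",
        mode        = "character",
        seed        = "integer"
    ),
    prototype(instrument = "synthetic", mode = "absorbance",
              seed = NA_integer_)
)

setValidity("CalibrationModel", function(object) {
    for (br in c("minor", "major")) {
        co <- slot(object, br)
        if (length(co) != 2L || !all(c("a", "b") %in% names(co)))
            return(sprintf("branch '%s' must be a named numeric c(a, b)", br))
        if (!is.na(co[["a"]]) && co[["a"]] <= 0)
            return(sprintf("slope 'a' of branch '%s' must be positive", br))
    }
    TRUE
})

#' Estimated COM/COD composition of one sample
#'
#' @slot m COM content, weight percent.
#' @slot d COD content, weight percent (m + d = 100).
#' @slot branch which calibration branch produced the estimate
#'   (\code{"minor"} = COM-minor, \code{"major"} = COM-major), or the
#'   analysis name for the comparison methods.
#' @slot uncertainty one-sigma uncertainty in weight percent.
#' @slot flags character vector (e.g. \code{"clamped"}, \code{"no COD band"}).
#' @slot geometry the [PeakGeometry-class] snapshot, or NULL.
#' @seealso [estimateComposition()], [bandRatioQuant()], [peakShiftQuant()].
#' @exportClass MixtureResult
setClass("MixtureResult",
    representation(
        m = "numeric", d = "numeric",
        branch = "character",
        uncertainty = "numeric",
        flags = "character",
        geometry = "ANY"
    ),
    prototype(flags = character(), geometry = NULL,
              uncertainty = NA_real_))

setValidity("MixtureResult", function(object) {
    if (object@m < 0 || object@m > 100 || object@d < 0 || object@d > 100)
        return("'m' and 'd' must lie in [0, 100] wt%")
    if (abs(object@m + object@d - 100) > 1e-6)
        return("m + d must equal 100 wt%")
    if (!is.na(object@uncertainty) && object@uncertainty < 0)
        return("'uncertainty' must be nonnegative")
    TRUE
})
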