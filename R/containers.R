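#' Construct a Spectrum
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1).  A descending
#'   axis is reversed (together with \code{intensity}) and the reversal is
#'   noted in the metadata.
#' @param intensity numeric vector of the same length.
#' @param mode one of \code{"absorbance"}, \code{"reflectance"},
#'   \code{"absorption-index"}.
#' @param metadata named list of free-form metadata.
#' @return A [Spectrum-class] object with an ascending axis.
#' @examples
#' s <- Spectrum(600:4000, rexp(3401), "absorbance")
#' s
#' @export
Spectrum <- function(wavenumber, intensity, mode = "absorbance",
                     metadata = list()) {
    wavenumber <- as.numeric(wavenumber)
    intensity <- as.numeric(intensity)
    if (length(wavenumber) > 1L && all(diff(wavenumber) < 0)) {
        wavenumber <- rev(wavenumber)
        intensity <- rev(intensity)
        metadata$axis_reversed <- TRUE
    }
    new("Spectrum", wavenumber = wavenumber, intensity = intensity,
        mode = mode, metadata = metadata)
}

#' Construct a PXRDPattern
#'
#' @param twoTheta numeric vector of diffraction angles (degrees).
#' @param intensity numeric vector of counts.
#' @param radiation \code{"CuKa1"} or \code{"MoKa1"}.
#' @param metadata named list.
#' @return A [PXRDPattern-class].
#' @export
PXRDPattern <- function(twoTheta, intensity, radiation = "CuKa1",
                        metadata = list()) {
    new("PXRDPattern", twoTheta = as.numeric(twoTheta),
        intensity = as.numeric(intensity), radiation = radiation,
        metadata = metadata)
}

#' Construct a CTImage
#'
#' @param values numeric matrix of attenuation values (arbitrary CT units).
#' @param voxelSize voxel edge length in mm; default 0.005 mm/voxel.
#' @param metadata named list (e.g. acquisition settings).
#' @return A [CTImage-class].
#' @export
CTImage <- function(values, voxelSize = 0.005, metadata = list()) {
    new("CTImage", values = values, voxelSize = voxelSize,
        metadata = metadata)
}

## ---- accessors ----

#' @describeIn Spectrum wavenumber axis (cm^-1)
#' @param object,x a \code{Spectrum}
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname Spectrum-class
#' @export
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumber)

#' Intensity values of a spectral container
#' @param object a [Spectrum-class] or [PXRDPattern-class]
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "Spectrum", function(object) object@intensity)

#' @rdname intensities
#' @export
setMethod("intensities", "PXRDPattern", function(object) object@intensity)

#' Spectral mode tag ("absorbance", "reflectance", "absorption-index")
#' @param object a [Spectrum-class]
#' @export
setGeneric("specMode", function(object) standardGeneric("specMode"))

#' @rdname specMode
#' @export
setMethod("specMode", "Spectrum", function(object) object@mode)

#' Diffraction angle axis (degrees 2-theta)
#' @param object a [PXRDPattern-class]
#' @export
setGeneric("twoTheta", function(object) standardGeneric("twoTheta"))

#' @rdname twoTheta
#' @export
setMethod("twoTheta", "PXRDPattern", function(object) object@twoTheta)

#' Radiation tag of a diffraction pattern
#' @param object a [PXRDPattern-class]
#' @export
setGeneric("radiation", function(object) standardGeneric("radiation"))

#' @rdname radiation
#' @export
setMethod("radiation", "PXRDPattern", function(object) object@radiation)

#' Attenuation value matrix of a CT image
#' @param object a [CTImage-class] or [PhaseMap-class]
#' @export
setGeneric("ctValues", function(object) standardGeneric("ctValues"))

#' @rdname ctValues
#' @export
setMethod("ctValues", "CTImage", function(object) object@values)

#' Voxel size in mm/voxel
#' @param object a [CTImage-class] or [PhaseMap-class]
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "CTImage", function(object) object@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PhaseMap", function(object) object@voxelSize)

#' Per-voxel integer phase labels
#'
#' Codes: 0 background, 1 void/resin, 2 COD, 3 COM (see
#' \code{phaseLevels()}).
#' @param object a [PhaseMap-class]
#' @export
setGeneric("phaseLabels", function(object) standardGeneric("phaseLabels"))

#' @rdname phaseLabels
#' @export
setMethod("phaseLabels", "PhaseMap", function(object) object@labels)

#' Integer codes used in phase label matrices
#' @return named integer vector (background, void, COD, COM).
#' @export
phaseLevels <- function() .PHASE_LEVELS

#' Stone mask of a phase map
#' @param object a [PhaseMap-class]
#' @export
setGeneric("stoneMask", function(object) standardGeneric("stoneMask"))

#' @rdname stoneMask
#' @export
setMethod("stoneMask", "PhaseMap", function(object) object@mask)

#' Quality/validity flags attached to a result
#' @param object a [PhaseMap-class] or [MixtureResult-class]
#' @export
setGeneric("resultFlags", function(object) standardGeneric("resultFlags"))

#' @rdname resultFlags
#' @export
setMethod("resultFlags", "PhaseMap", function(object) object@flags)

#' @rdname resultFlags
#' @export
setMethod("resultFlags", "MixtureResult", function(object) object@flags)

#' COM/COD absorption shares
#' @param object an [AbsorptionShares-class] or [MixtureResult-class]
#' @export
setGeneric("comShare", function(object) standardGeneric("comShare"))

#' @rdname comShare
#' @export
setMethod("comShare", "AbsorptionShares", function(object) object@M)

#' @rdname comShare
#' @export
setGeneric("codShare", function(object) standardGeneric("codShare"))

#' @rdname comShare
#' @export
setMethod("codShare", "AbsorptionShares", function(object) object@D)

#' Estimated COM content in weight percent
#' @param object a [MixtureResult-class]
#' @export
setGeneric("comContent", function(object) standardGeneric("comContent"))

#' @rdname comContent
#' @export
setMethod("comContent", "MixtureResult", function(object) object@m)

#' @rdname comContent
#' @export
setGeneric("codContent", function(object) standardGeneric("codContent"))

#' @rdname comContent
#' @export
setMethod("codContent", "MixtureResult", function(object) object@d)

#' @importFrom S4Vectors metadata
#' @exportMethod metadata
setMethod("metadata", "Spectrum", function(x, ...) x@metadata)

#' @exportMethod metadata
setMethod("metadata", "PXRDPattern", function(x, ...) x@metadata)

#' @exportMethod metadata
setMethod("metadata", "CTImage", function(x, ...) x@metadata)

#' @exportMethod metadata
setMethod("metadata", "PhaseMap", function(x, ...) x@metadata)

#' @importFrom S4Vectors metadata<-
#' @exportMethod "metadata<-"
setReplaceMethod("metadata", "Spectrum", function(x, ..., value) {
    x@metadata <- value
    x
})

#' @exportMethod "metadata<-"
setReplaceMethod("metadata", "CTImage", function(x, ..., value) {
    x@metadata <- value
    x
})

## ---- show methods ----

setMethod("show", "Spectrum", function(object) {
    wn <- object@wavenumber
    cat(sprintf("Spectrum (%s): %d points, %.1f-%.1f cm-1\n",
                object@mode, length(wn), min(wn), max(wn)))
    md <- object@metadata
    if (length(md))
        cat("  metadata:", paste(names(md), collapse = ", "), "\n")
})

setMethod("show", "PXRDPattern", function(object) {
    tt <- object@twoTheta
    cat(sprintf("PXRDPattern (%s): %d points, %.2f-%.2f deg 2theta\n",
                object@radiation, length(tt), min(tt), max(tt)))
})

setMethod("show", "CTImage", function(object) {
    cat(sprintf("CTImage: %d x %d voxels at %.4g mm/voxel\n",
                nrow(object@values), ncol(object@values),
                object@voxelSize))
})

setMethod("show", "PhaseMap", function(object) {
    tab <- table(factor(object@labels, levels = .PHASE_LEVELS,
                        labels = names(.PHASE_LEVELS)))
    cat(sprintf("PhaseMap: %d x %d voxels\n",
                nrow(object@labels), ncol(object@labels)))
    cat("  voxels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
    if (length(object@thresholds))
        cat("  thresholds:",
            paste(sprintf("%s=%.4g", names(object@thresholds),
                          object@thresholds), collapse = ", "), "\n")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "PeakGeometry", function(object) {
    cat("PeakGeometry of the 780 cm-1 decomposition\n")
    pts <- rbind(P = object@P, O = object@O, Q = object@Q,
                 "R'" = object@Rprime, C = object@C, R = object@R)
    colnames(pts) <- c("wavenumber", "value")
    print(round(pts, 5))
    cat(sprintf("  |PR| = %.5g  |RC| = %.5g  |PC| = %.5g\n",
                object@lengths[["PR"]], object@lengths[["RC"]],
                object@lengths[["PC"]]))
})

setMethod("show", "AbsorptionShares", function(object) {
    cat(sprintf("AbsorptionShares: M = %.4f (COM), D = %.4f (COD)\n",
                object@M, object@D))
})

setMethod("show", "CalibrationModel", function(object) {
    cat("CalibrationModel (two-branch linear, Y = a X + b)\n")
    fmt <- function(br, lab) {
        co <- slot(object, br)
        dg <- object@diagnostics[[br]]
        if (is.na(co[["a"]])) {
            cat(sprintf("  %s: unusable\n", lab))
        } else {
            cat(sprintf("  %s: a = %.4f, b = %.4f (R^2 = %.5f, n = %d)\n",
                        lab, co[["a"]], co[["b"]],
                        dg$r.squared, dg$n))
        }
    }
    fmt("minor", "COM-minor (m<d)  Y =M/D vs X =m/d")
    fmt("major", "COM-major (d<m)  Y'=D/M vs X'=d/m")
    cat(sprintf("  instrument: %s, mode: %s\n",
                object@instrument, object@mode))
})

setMethod("show", "MixtureResult", function(object) {
    unc <- if (is.na(object@uncertainty)) ""
           else sprintf(" (+/- %.1f wt%%)", object@uncertainty)
    cat(sprintf("MixtureResult: COM %.1f wt%% / COD %.1f wt%%%s [%s]\n",
                object@m, object@d, unc, object@branch))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @export
#' @method as.data.frame MixtureResult
as.data.frame.MixtureResult <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
    data.frame(m = x@m, d = x@d, branch = x@branch,
               uncertainty = x@uncertainty,
               flags = paste(x@flags, collapse = ";"),
               stringsAsFactors = FALSE)
}

## ---- plotting ----

#' Plot a spectrum or diffraction pattern
#'
#' Base-graphics line plot with the conventional axis direction for IR
#' spectra (wavenumber decreasing to the right).
#'
#' @param x a [Spectrum-class] or [PXRDPattern-class]
#' @param y ignored
#' @param ... passed to [graphics::plot.default]
#' @importFrom graphics plot
#' @export
setMethod("plot", signature(x = "Spectrum", y = "missing"),
    function(x, y, ...) {
        ylab <- switch(x@mode, absorbance = "Absorbance",
                       reflectance = "Reflectance",
                       `absorption-index` = "Absorption index k")
        plot(x@wavenumber, x@intensity, type = "l",
             xlim = rev(range(x@wavenumber)),
             xlab = expression(Wavenumber ~ (cm^-1)), ylab = ylab, ...)
    })

#' @rdname plot-Spectrum-missing-method
#' @export
setMethod("plot", signature(x = "PXRDPattern", y = "missing"),
    function(x, y, ...) {
        plot(x@twoTheta, x@intensity, type = "l",
             xlab = expression(2*theta ~ (degrees)),
             ylab = "Intensity (counts)", ...)
    })
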