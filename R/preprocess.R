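.appendProvenance <- function(s, entry) {
    md <- metadata(s)
    md$provenance <- c(md$provenance, list(entry))
    metadata(s) <- md
    s
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; no extrapolation — the target grid must lie
#' within the spectrum's support.
#'
#' @param s a [Spectrum-class].
#' @param grid strictly increasing target wavenumbers, cm^-1.
#' @return the resampled [Spectrum-class] (same mode, provenance
#'   appended).
#' @export
resampleLinear <- function(s, grid) {
    stopifnot(is(s, "Spectrum"))
    wn <- wavenumbers(s)
    if (min(grid) < min(wn) || max(grid) > max(wn))
        stop("target grid extends beyond the spectrum's support; ",
             "refusing to extrapolate")
    y <- stats::approx(wn, intensities(s), xout = grid)$y
    out <- Spectrum(grid, y, specMode(s), metadata(s))
    .appendProvenance(out, list(op = "resampleLinear",
                                n = length(grid)))
}

#' Subtract atmospheric H2O and CO2 absorptions
#'
#' Removes \code{alpha * refH2O + beta * refCO2} from the spectrum, with
#' the scale factors fitted by least squares restricted to atmosphere-only
#' windows (2300-2400 cm^-1 for CO2; the 1300-1900 and 3500-3900 cm^-1
#' rotational-line regions for H2O).  Because the sample itself absorbs
#' inside the H2O windows (C=O stretch, O-H tail), the H2O scale is
#' fitted on second differences, where the narrow atmospheric lines
#' dominate and broad sample bands vanish.  Negative fitted scales are
#' clamped to zero with a warning (atmospheric absorption cannot be
#' added).  Fitted scales are recorded in the metadata, so a second pass
#' fits approximately zero.
#'
#' @param s an absorbance [Spectrum-class].
#' @param refH2O,refCO2 reference spectra; defaults are the synthetic
#'   [atmosphericReferences()] on \code{s}'s grid.  References on a
#'   different grid are resampled internally.
#' @param co2Window,h2oWindows fitting windows, cm^-1.
#' @return the corrected [Spectrum-class]; \code{metadata(s)$atmosphere}
#'   holds \code{alpha} (H2O) and \code{beta} (CO2).
#' @export
subtractAtmosphere <- function(s, refH2O = NULL, refCO2 = NULL,
                               co2Window = c(2300, 2400),
                               h2oWindows = list(c(1300, 1900),
                                                 c(3500, 3900))) {
    stopifnot(is(s, "Spectrum"))
    wn <- wavenumbers(s)
    if (is.null(refH2O) || is.null(refCO2)) {
        atm <- atmosphericReferences(wn)
        if (is.null(refH2O)) refH2O <- atm$h2o
        if (is.null(refCO2)) refCO2 <- atm$co2
    }
    onGrid <- function(r) {
        if (length(wavenumbers(r)) == length(wn) &&
            all(wavenumbers(r) == wn)) intensities(r)
        else stats::approx(wavenumbers(r), intensities(r), xout = wn,
                           rule = 2)$y
    }
    h2o <- onGrid(refH2O); co2 <- onGrid(refCO2)
    y <- intensities(s)

    inWin <- function(windows) {
        sel <- rep(FALSE, length(wn))
        for (w in windows) sel <- sel | (wn >= w[1] & wn <= w[2])
        sel
    }
    ## CO2: the sample is transparent in its window; plain restricted LS
    ## after removing a window-linear trend.
    selC <- inWin(list(co2Window))
    detrend <- function(v, sel) stats::resid(stats::lm(v[sel] ~ wn[sel]))
    beta <- 0
    if (sum(co2[selC]^2) > 0) {
        rc <- detrend(co2, selC)
        beta <- sum(detrend(y, selC) * rc) / sum(rc^2)
    }
    ## H2O: fit on second differences so broad sample bands drop out.
    selH <- inWin(h2oWindows)
    d2 <- function(v) diff(v, differences = 2)
    wH <- which(selH)
    alpha <- 0
    if (length(wH) > 4) {
        rh <- d2(h2o[wH]); ry <- d2(y[wH])
        if (sum(rh^2) > 0) alpha <- sum(ry * rh) / sum(rh^2)
    }
    ## absorption cannot be added: clamp negative scales, warning only
    ## when they are meaningfully negative (not numerical residue)
    if (alpha < 0) {
        if (alpha < -1e-3)
            warning("fitted H2O scale was negative; clamped to 0")
        alpha <- 0
    }
    if (beta < 0) {
        if (beta < -1e-3)
            warning("fitted CO2 scale was negative; clamped to 0")
        beta <- 0
    }
    out <- Spectrum(wn, y - alpha * h2o - beta * co2, specMode(s),
                    metadata(s))
    md <- metadata(out)
    md$atmosphere <- list(alpha = alpha, beta = beta)
    metadata(out) <- md
    .appendProvenance(out, list(op = "subtractAtmosphere",
                                alpha = alpha, beta = beta))
}
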