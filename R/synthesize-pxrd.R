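#' Characteristic diffraction angles of the calcium oxalate hydrates
#'
#' The three-peak fingerprints (degrees 2-theta, Cu K-alpha-1) used for
#' presence/absence phase calls: COD at ~14.3, 20.1 and 32.2 degrees, COM
#' at ~14.9, 24.4 and 30.1 degrees.  Versioned constants; the "~"
#' precision of these positions is reflected in the default matching
#' tolerance of [identifyPhases()].
#'
#' @return named list of numeric vectors (\code{COM}, \code{COD}).
#' @export
characteristicPeaks <- function() {
    list(COM = c(14.9, 24.4, 30.1),
         COD = c(14.3, 20.1, 32.2))
}

## Full synthetic peak tables: the characteristic triplets plus minor
## peaks (invented, configurable) that do not collide with the other
## phase's triplet.  Relative intensities are generator choices.
.pxrdPeakTable <- function(phase) {
    switch(phase,
        COM = data.frame(
            position = c(14.9, 24.4, 30.1, 35.9, 38.2),
            intensity = c(1.00, 0.70, 0.45, 0.12, 0.08)),
        COD = data.frame(
            position = c(14.3, 20.1, 32.2, 25.8, 37.3),
            intensity = c(1.00, 0.60, 0.40, 0.12, 0.08)),
        stop("unknown phase: ", phase))
}

#' Synthesize a powder diffraction pattern
#'
#' Places pseudo-Voigt peaks at the characteristic (plus minor) positions
#' of the requested phases, blends phases linearly by weight, adds a
#' slowly decaying background and, optionally, Poisson counting noise.
#' This is a peak-position simulator for exercising detection and phase
#' identification, not a structure-factor calculation.
#'
#' @param phases character subset of \code{c("COM", "COD")}.
#' @param weights nonnegative phase weights (sum > 0); normalised to 1.
#' @param gridMin,gridMax,gridStep 2-theta grid, degrees.
#' @param fwhm peak full width at half maximum, degrees.
#' @param eta pseudo-Voigt Lorentzian fraction.
#' @param countsScale peak-height scale in counts.
#' @param background add the decaying background? (logical)
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param radiation \code{"CuKa1"} or \code{"MoKa1"}; for Mo the peak
#'   positions are converted from the Cu table via Bragg's law.
#' @param seed integer seed (Poisson noise only).
#' @return a [PXRDPattern-class]; phase weights recorded in the metadata.
#' @examples
#' p <- makePXRDPattern("COD", noise = "none")
#' @export
makePXRDPattern <- function(phases, weights = rep(1, length(phases)),
                            gridMin = 5, gridMax = 40, gridStep = 0.02,
                            fwhm = 0.12, eta = 0.3, countsScale = 1e4,
                            background = TRUE,
                            noise = c("poisson", "none"),
                            radiation = "CuKa1", seed = NULL) {
    noise <- match.arg(noise)
    if (!length(phases)) stop("'phases' must name at least one phase")
    phases <- match.arg(phases, c("COM", "COD"), several.ok = TRUE)
    if (length(weights) != length(phases) || any(weights < 0) ||
        sum(weights) <= 0)
        stop("'weights' must be nonnegative with a positive sum")
    weights <- weights / sum(weights)
    tt <- seq(gridMin, gridMax, by = gridStep)
    y <- numeric(length(tt))
    for (i in seq_along(phases)) {
        tab <- .pxrdPeakTable(phases[i])
        pos <- convertTwoTheta(tab$position, from = "CuKa1",
                               to = radiation)
        for (j in seq_len(nrow(tab)))
            y <- y + weights[i] * countsScale *
                .evalBand(spectralBand(pos[j], tab$intensity[j], fwhm,
                                       "pseudo-voigt", eta = eta), tt)
    }
    if (background)   # fixed peak-to-background ratio across exposures
        y <- y + countsScale / 1e4 * (20 + 150 * exp(-(tt - gridMin) / 15))
    if (noise == "poisson")
        y <- .withSeed(seed, rpois(length(y), lambda = y))
    PXRDPattern(tt, y, radiation = radiation,
                metadata = list(
                    truth = list(phases = phases, weights = weights),
                    seed = if (is.null(seed)) NA_integer_
                           else as.integer(seed),
                    synthetic = TRUE))
}

#' Convert diffraction angles between radiation sources
#'
#' Positions map through the radiation-independent d-spacing: Bragg's law
#' gives \eqn{\sin\theta_2 = (\lambda_2/\lambda_1)\sin\theta_1}.
#' Wavelengths: Cu K-alpha-1 1.5406 A, Mo K-alpha-1 0.7093 A.
#'
#' @param twoTheta angles in degrees (2-theta).
#' @param from,to radiation tags (\code{"CuKa1"}, \code{"MoKa1"}).
#' @return converted angles, degrees.
#' @examples
#' convertTwoTheta(14.3, "CuKa1", "MoKa1")
#' @export
convertTwoTheta <- function(twoTheta, from = "CuKa1", to = "CuKa1") {
    wl <- .RADIATION_WAVELENGTHS
    if (!from %in% names(wl) || !to %in% names(wl))
        stop("unknown radiation tag; use one of ",
             paste(sQuote(names(wl)), collapse = ", "))
    if (from == to) return(twoTheta)
    s <- (wl[[to]] / wl[[from]]) * sin(twoTheta / 2 * pi / 180)
    if (any(s > 1))
        stop("angle not representable with target radiation")
    2 * asin(s) * 180 / pi
}
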