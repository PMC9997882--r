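#' Detect peaks in a powder diffraction pattern
#'
#' Local maxima of the background-corrected intensity exceeding a
#' prominence threshold.  The background is a rolling median (window
#' \code{bgWindow} degrees) robust to the peaks themselves; peak
#' positions are refined by quadratic interpolation through the three
#' points around each discrete maximum.
#'
#' @param p a [PXRDPattern-class] with at least 50 points.
#' @param minProminence minimum peak height above background, as a
#'   fraction of the largest background-corrected intensity.
#' @param bgWindow rolling-median window, degrees.
#' @return data.frame with columns \code{position} (degrees, refined),
#'   \code{height} (counts above background); zero rows when nothing
#'   exceeds the threshold.
#' @export
detectPeaks <- function(p, minProminence = 0.02, bgWindow = 2) {
    stopifnot(is(p, "PXRDPattern"))
    tt <- twoTheta(p); y <- intensities(p)
    if (length(tt) < 50L)
        stop("pattern too short: need at least 50 points")
    step <- stats::median(diff(tt))
    k <- max(3L, 2L * floor(bgWindow / step / 2) + 1L)
    bg <- stats::runmed(y, k, endrule = "median")
    ## light boxcar smoothing (narrow vs the peak FWHM) tames counting
    ## noise before the maxima search
    z <- stats::filter(y - bg, rep(1 / 7, 7), sides = 2)
    z[is.na(z)] <- 0
    z <- as.numeric(z)
    top <- max(z)
    if (top <= 0) return(data.frame(position = numeric(),
                                    height = numeric()))
    ## threshold: relative prominence floor, but never below 5 robust
    ## SDs of the background-corrected signal
    sigma <- 1.4826 * stats::mad(z)
    thr <- max(minProminence * top, 5 * sigma)
    n <- length(z)
    i <- which(z[-c(1L, n)] > z[-c(n - 1L, n)] &
               z[-c(1L, n)] >= z[-c(1L, 2L)]) + 1L
    i <- i[z[i] > thr]
    if (!length(i)) return(data.frame(position = numeric(),
                                      height = numeric()))
    ## collapse plateaus/adjacent grid maxima of the same peak
    keep <- c(TRUE, diff(i) > 1L)
    i <- i[keep]
    refine <- function(j) {
        y0 <- z[j - 1L]; y1 <- z[j]; y2 <- z[j + 1L]
        denom <- y0 - 2 * y1 + y2
        d <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
        tt[j] + d * step
    }
    data.frame(position = vapply(i, refine, 0), height = z[i])
}

#' Identify COM/COD phases from detected peaks
#'
#' Scores each phase by the fraction of its characteristic three-peak
#' fingerprint (see [characteristicPeaks()]) matched within
#' \code{tolerance}; a phase is called present when the score reaches
#' \code{minScore}.  Patterns measured with Mo K-alpha-1 are handled by
#' converting the (Cu-referenced) characteristic positions through the
#' d-spacing (Bragg's law) before matching.
#'
#' @param peaks a data.frame from [detectPeaks()] (or a numeric vector
#'   of peak positions in degrees).
#' @param tolerance matching tolerance in degrees (default 0.15,
#'   reflecting the approximate precision of the reference positions).
#' @param radiation radiation tag of the measured pattern.
#' @param minScore minimum matched fraction for a presence call
#'   (default 2/3).
#' @return data.frame with one row per phase: \code{phase},
#'   \code{score}, \code{present}, \code{n_matched}; matched positions
#'   and offsets in attribute \code{"matches"}.
#' @examples
#' identifyPhases(c(14.3, 20.1, 32.2))
#' @export
identifyPhases <- function(peaks, tolerance = 0.15, radiation = "CuKa1",
                           minScore = 2 / 3) {
    if (tolerance <= 0) stop("'tolerance' must be positive")
    if (!radiation %in% names(.RADIATION_WAVELENGTHS))
        stop("unknown radiation tag: ", radiation)
    pos <- if (is.data.frame(peaks)) peaks$position else as.numeric(peaks)
    ref <- characteristicPeaks()
    matches <- list()
    rows <- lapply(names(ref), function(ph) {
        expect <- convertTwoTheta(ref[[ph]], from = "CuKa1",
                                  to = radiation)
        off <- vapply(expect, function(e)
            if (length(pos)) min(abs(pos - e)) else Inf, 0)
        hit <- off <= tolerance
        matches[[ph]] <<- data.frame(expected = expect, offset = off,
                                     matched = hit)
        score <- mean(hit)
        data.frame(phase = ph, score = score,
                   present = score >= minScore,
                   n_matched = sum(hit), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "matches") <- matches
    out
}

#' One-call phase identification for a diffraction pattern
#'
#' [detectPeaks()] followed by [identifyPhases()], with the pattern's own
#' radiation tag.
#'
#' @inheritParams detectPeaks
#' @inheritParams identifyPhases
#' @return see [identifyPhases()].
#' @export
identifyPattern <- function(p, minProminence = 0.02, tolerance = 0.15,
                            minScore = 2 / 3) {
    identifyPhases(detectPeaks(p, minProminence),
                   tolerance = tolerance, radiation = radiation(p),
                   minScore = minScore)
}
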