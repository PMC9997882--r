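#' @describeIn bandRatioQuant calibration model for the 910/780 band
#'   ratio: monotone piecewise-linear map between the true COM weight
#'   fraction and the measured ratio.
#' @slot w_com,ratio calibration pairs (level means), ratio decreasing
#'   in w_com.
#' @slot noiseFloor heights of the 910 band below this are treated as
#'   "band absent".
#' @slot instrument instrument/generator tag.
#' @exportClass BandRatioModel
setClass("BandRatioModel",
    representation(w_com = "numeric", ratio = "numeric",
                   noiseFloor = "numeric", instrument = "character"))

#' @describeIn peakShiftQuant calibration model for the C-O apex
#'   position: linear map w_com = intercept + slope * apex.
#' @slot slope,intercept coefficients of the linear map.
#' @slot range apex-position validity range, cm^-1.
#' @slot instrument instrument/generator tag.
#' @exportClass PeakShiftModel
setClass("PeakShiftModel",
    representation(slope = "numeric", intercept = "numeric",
                   range = "numeric", instrument = "character"))

setValidity("PeakShiftModel", function(object) {
    if (object@slope == 0) return("'slope' must be nonzero")
    TRUE
})

## Baseline-corrected height of a band: apex = max inside searchWin,
## local baseline = line through the minima of the two flanking windows.
.bandHeight <- function(s, searchWin, leftWin, rightWin) {
    wn <- wavenumbers(s); y <- intensities(s)
    grab <- function(win, what) {
        sel <- which(wn >= win[1] & wn <= win[2])
        if (!length(sel)) stop("spectrum does not cover [",
                               win[1], ", ", win[2], "] cm-1")
        i <- sel[if (what == "max") which.max(y[sel])
                 else which.min(y[sel])]
        c(wn[i], y[i])
    }
    apex <- grab(searchWin, "max")
    l <- grab(leftWin, "min"); r <- grab(rightWin, "min")
    slope <- (r[2] - l[2]) / (r[1] - l[1])
    base <- l[2] + slope * (apex[1] - l[1])
    apex[2] - base
}

.ratio910 <- function(s) {
    h910 <- .bandHeight(s, c(900, 925), c(870, 890), c(935, 960))
    g <- locatePeakGeometry(s)
    h780 <- g@lengths[["PC"]]
    c(h910 = max(h910, 0), h780 = h780,
      ratio = max(h910, 0) / h780)
}

#' Calibrate the 910/780 cm-1 band-ratio analysis
#'
#' The 910 cm^-1 band belongs to COD only, so the baseline-corrected
#' height ratio A910/A780 falls monotonically with COM content.  No
#' functional form is imposed: level-mean ratios are connected by a
#' monotone piecewise-linear interpolant and inverted numerically.
#'
#' @param standards list of absorbance [Spectrum-class] standards with
#'   \code{metadata()$truth$w_com}.
#' @return a \code{BandRatioModel}.
#' @export
fitBandRatioModel <- function(standards) {
    w <- vapply(standards, function(s) metadata(s)$truth$w_com, 0)
    tags <- unique(vapply(standards, function(s)
        metadata(s)$instrument %||% "unknown", ""))
    if (length(tags) > 1L)
        stop("standards carry mixed instrument tags")
    meas <- t(vapply(standards, .ratio910, c(h910 = 0, h780 = 0,
                                             ratio = 0)))
    lev <- sort(unique(round(w, 10)))
    rat <- vapply(lev, function(l)
        mean(meas[round(w, 10) == l, "ratio"]), 0)
    ## enforce monotone (non-increasing in w) via isotonic regression on
    ## the reversed sequence; noise can produce local inversions
    iso <- stats::isoreg(lev, -rat)
    rat <- -iso$yf
    pureCom <- round(w, 10) == max(lev)
    nf <- if (sum(pureCom) > 1)
        3 * stats::sd(meas[pureCom, "h910"]) else 0
    new("BandRatioModel", w_com = lev, ratio = rat,
        noiseFloor = nf, instrument = tags)
}

#' Quantify COM/COD by the 910/780 cm-1 band ratio
#'
#' The comparison method using two band heights: the COD-only 910 cm^-1
#' band against the common 780 cm^-1 peak.  The measured ratio is pushed
#' through the monotone calibration; ratios outside the calibrated range
#' clamp to the nearest endpoint.  A 910 band below the model's noise
#' floor with a clear 780 peak returns pure COM, flagged
#' \code{"no COD band"}.
#'
#' @param s an absorbance [Spectrum-class] covering 700-960 cm^-1.
#' @param model a \code{BandRatioModel} from [fitBandRatioModel()].
#' @return a [MixtureResult-class] (branch \code{"analysis2"}).
#' @export
bandRatioQuant <- function(s, model) {
    stopifnot(is(s, "Spectrum"), is(model, "BandRatioModel"))
    tag <- metadata(s)$instrument
    if (!is.null(tag) && !identical(tag, model@instrument))
        stop("instrument mismatch between spectrum and band-ratio model")
    meas <- .ratio910(s)
    flags <- character()
    if (meas[["h910"]] <= model@noiseFloor && meas[["h780"]] > 0) {
        return(new("MixtureResult", m = 100, d = 0,
                   branch = "analysis2", flags = "no COD band"))
    }
    ## interpolate w on the monotone (ratio, w) curve
    ord <- order(model@ratio)
    w <- stats::approx(model@ratio[ord], model@w_com[ord],
                       xout = meas[["ratio"]], rule = 2, ties = mean)$y
    m <- min(max(100 * w, 0), 100)
    new("MixtureResult", m = m, d = 100 - m, branch = "analysis2",
        flags = flags)
}

## Apex position by quadratic interpolation through the three samples
## around the discrete maximum.
.apexPosition <- function(s, win) {
    wn <- wavenumbers(s); y <- intensities(s)
    sel <- which(wn >= win[1] & wn <= win[2])
    if (length(sel) < 3L) stop("window too narrow")
    i <- sel[which.max(y[sel])]
    if (i <= sel[1L] || i >= sel[length(sel)])
        stop("no interior maximum in [", win[1], ", ", win[2], "] cm-1")
    y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
    denom <- y0 - 2 * y1 + y2
    delta <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
    wn[i] + delta * (wn[i + 1L] - wn[i])
}

#' Calibrate the 1324 cm-1 peak-shift analysis
#'
#' The C-O stretch sits lower in COM than in COD, so the apex position of
#' the merged mixture band moves monotonically with composition through
#' 1324 cm^-1.  A straight line w_com = intercept + slope * apex is
#' fitted over the level-mean apex positions.
#'
#' @param standards list of absorbance [Spectrum-class] standards with
#'   \code{metadata()$truth$w_com}.
#' @param window apex search window, cm^-1.
#' @return a \code{PeakShiftModel}.
#' @export
fitPeakShiftModel <- function(standards, window = c(1290, 1350)) {
    w <- vapply(standards, function(s) metadata(s)$truth$w_com, 0)
    tags <- unique(vapply(standards, function(s)
        metadata(s)$instrument %||% "unknown", ""))
    if (length(tags) > 1L)
        stop("standards carry mixed instrument tags")
    apex <- vapply(standards, .apexPosition, 0, win = window)
    lev <- sort(unique(round(w, 10)))
    apx <- vapply(lev, function(l) mean(apex[round(w, 10) == l]), 0)
    fit <- stats::lm(lev ~ apx)
    new("PeakShiftModel",
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        range = range(apx), instrument = tags)
}

#' Quantify COM/COD by the C-O apex position near 1324 cm-1
#'
#' @param s an absorbance [Spectrum-class] covering 1290-1350 cm^-1.
#' @param model a \code{PeakShiftModel} from [fitPeakShiftModel()].
#' @param window apex search window, cm^-1.
#' @return a [MixtureResult-class] (branch \code{"analysis3"}).
#' @export
peakShiftQuant <- function(s, model, window = c(1290, 1350)) {
    stopifnot(is(s, "Spectrum"), is(model, "PeakShiftModel"))
    tag <- metadata(s)$instrument
    if (!is.null(tag) && !identical(tag, model@instrument))
        stop("instrument mismatch between spectrum and peak-shift model")
    apex <- .apexPosition(s, window)
    m <- min(max(100 * (model@intercept + model@slope * apex), 0), 100)
    new("MixtureResult", m = m, d = 100 - m, branch = "analysis3",
        flags = character())
}

#' Run the three FTIR analyses side by side
#'
#' Applies the 780 cm^-1 decomposition (Analysis 1), the 910/780 band
#' ratio (Analysis 2) and the 1324 cm^-1 peak shift (Analysis 3) to the
#' same spectrum and returns one row per analysis, ready to be written as
#' a comparison table.  All three models must carry the same instrument
#' tag as the spectrum — the coefficients are apparatus-dependent.
#'
#' @param s an absorbance [Spectrum-class].
#' @param cal a [CalibrationModel-class] (Analysis 1).
#' @param ratioModel a \code{BandRatioModel} (Analysis 2).
#' @param shiftModel a \code{PeakShiftModel} (Analysis 3).
#' @return data.frame with columns \code{analysis}, \code{com_wt_pct},
#'   \code{cod_wt_pct}, \code{branch}, \code{uncertainty_wt_pct},
#'   \code{flags}.
#' @export
compareMethods <- function(s, cal, ratioModel, shiftModel) {
    tags <- c(cal@instrument, ratioModel@instrument,
              shiftModel@instrument)
    if (length(unique(tags)) > 1L)
        stop("models carry mixed instrument tags: ",
             paste(unique(tags), collapse = ", "))
    res <- list(
        `analysis1 (780)` = quantify780(s, cal),
        `analysis2 (910/780)` = bandRatioQuant(s, ratioModel),
        `analysis3 (1324)` = peakShiftQuant(s, shiftModel))
    out <- do.call(rbind, lapply(res, as.data.frame))
    data.frame(analysis = names(res),
               com_wt_pct = out$m, cod_wt_pct = out$d,
               branch = out$branch,
               uncertainty_wt_pct = out$uncertainty,
               flags = out$flags,
               row.names = NULL, stringsAsFactors = FALSE)
}
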