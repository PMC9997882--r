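#' Construct the 780 cm-1 peak decomposition geometry
#'
#' Builds the six-point construction that splits the 780 cm^-1 absorption
#' peak into COM and COD contributions.  P is the grid maximum inside the
#' apex window.  O and Q are the bottoms of the flanking valleys, located
#' as the support points of the chord that stays below the spectrum
#' across the peak (the bridging edge of the lower convex hull over the
#' two valley windows); the chord OQ is the local baseline, giving C at
#' P's wavenumber.  R' is the value interpolated at exactly
#' \code{rprimeAt} cm^-1, and R is carried from R' to P's wavenumber
#' along a line parallel to OQ.  Hull support points and the parallel
#' transport both commute with adding a linear function, so the segment
#' lengths — and hence the shares — are exactly baseline-immune.
#'
#' @param s an absorbance or absorption-index [Spectrum-class] covering
#'   700-900 cm^-1.
#' @param windows named list of wavenumber windows: \code{apex}
#'   (default c(770, 790)), \code{left} valley (c(700, 770)), \code{right}
#'   valley (c(810, 900)).
#' @param rprimeAt wavenumber of the R' reading; 800 cm^-1 by default,
#'   where COM no longer absorbs but the broad COD peak still does.
#' @return a [PeakGeometry-class].
#' @examples
#' s <- makeMixtureSpectrum(0.5, generatorConfig(noiseSD = 0))
#' locatePeakGeometry(s)
#' @export
locatePeakGeometry <- function(s,
                               windows = list(apex = c(770, 790),
                                              left = c(700, 770),
                                              right = c(810, 900)),
                               rprimeAt = 800) {
    stopifnot(is(s, "Spectrum"))
    if (!specMode(s) %in% c("absorbance", "absorption-index"))
        stop("peak geometry requires an absorbance or absorption-index ",
             "spectrum (run kkTransform on reflectance data first)")
    wn <- wavenumbers(s)
    y <- intensities(s)
    need <- range(unlist(windows), rprimeAt)
    if (min(wn) > need[1] || max(wn) < need[2])
        stop("spectrum does not cover the analysis range ",
             sprintf("%g-%g cm-1", need[1], need[2]))

    selA <- which(wn >= windows$apex[1] & wn <= windows$apex[2])
    if (length(selA) < 3L)
        stop("apex window contains fewer than 3 grid points")
    iP <- selA[which.max(y[selA])]
    if (iP == selA[1L] || iP == selA[length(selA)])
        stop("no 780 peak: apex window maximum lies on the window ",
             "boundary")
    P <- c(wn[iP], y[iP])

    ## O and Q are the valley-bottom support points of the chord that
    ## stays below the spectrum across the peak (the bridging edge of
    ## the lower convex hull over the two valley windows).  Support
    ## points of a convex hull are invariant under adding any linear
    ## function, which is what makes the decomposition exactly
    ## baseline-immune.
    selL <- which(wn >= windows$left[1] & wn <= windows$left[2])
    selR <- which(wn >= windows$right[1] & wn <= windows$right[2])
    if (length(selL) < 3L || length(selR) < 3L)
        stop("valley window contains fewer than 3 grid points")
    br <- .hullBridge(wn, y, selL, selR)
    O <- br$O; Q <- br$Q

    slope <- (Q[2L] - O[2L]) / (Q[1L] - O[1L])
    Cv <- O[2L] + slope * (P[1L] - O[1L])
    if (P[2L] <= Cv)
        stop("inverted peak: apex lies below the valley baseline")
    RpV <- stats::approx(wn, y, xout = rprimeAt)$y
    Rv <- RpV + slope * (P[1L] - rprimeAt)

    ## clamp R into [C, P]: noise can push the 800 cm-1 reading outside
    ## the physically meaningful segment
    Rc <- min(max(Rv, Cv), P[2L])
    lengths <- c(PR = P[2L] - Rc, RC = Rc - Cv, PC = P[2L] - Cv)
    ## Class= named explicitly: the C slot would otherwise partially
    ## match new()'s Class argument
    new(Class = "PeakGeometry", P = P, O = O, Q = Q,
        Rprime = c(rprimeAt, RpV), C = c(P[1L], Cv), R = c(P[1L], Rv),
        lengths = lengths)
}

## Lower convex hull (Andrew monotone chain) of the points in the two
## valley windows; returns the edge bridging from the left window to the
## right one.
.hullBridge <- function(wn, y, selL, selR) {
    idx <- c(selL, selR)
    hull <- integer(0)
    for (i in idx) {
        while (length(hull) >= 2L) {
            a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
            ## drop b if it lies on or above segment a-i
            cross <- (wn[b] - wn[a]) * (y[i] - y[a]) -
                     (y[b] - y[a]) * (wn[i] - wn[a])
            if (cross <= 0) hull <- hull[-length(hull)] else break
        }
        hull <- c(hull, i)
    }
    gapEnd <- max(selL)
    j <- which(hull <= gapEnd)
    iO <- hull[j[length(j)]]
    iQ <- hull[j[length(j)] + 1L]
    list(O = c(wn[iO], y[iO]), Q = c(wn[iQ], y[iQ]))
}

#' Compute COM/COD absorption shares from a peak geometry
#'
#' M = |PR| / |PC| is the COM fraction of the baseline-corrected 780
#' cm^-1 peak height; D = |RC| / |PC| = 1 - M is the COD fraction.
#'
#' @param g a [PeakGeometry-class].
#' @return an [AbsorptionShares-class].
#' @export
computeShares <- function(g) {
    stopifnot(is(g, "PeakGeometry"))
    pc <- g@lengths[["PC"]]
    if (pc <= 0)
        stop("degenerate peak: |PC| = 0")
    M <- min(max(g@lengths[["PR"]] / pc, 0), 1)
    new("AbsorptionShares", M = M, D = 1 - M)
}

#' Measure absorption shares of one spectrum
#'
#' Convenience wrapper: [locatePeakGeometry()] then [computeShares()].
#'
#' @inheritParams locatePeakGeometry
#' @return an [AbsorptionShares-class].
#' @export
measureShares <- function(s, windows = list(apex = c(770, 790),
                                            left = c(700, 770),
                                            right = c(810, 900)),
                          rprimeAt = 800) {
    computeShares(locatePeakGeometry(s, windows, rprimeAt))
}

#' Fit the two-branch linear calibration
#'
#' Standards with known COM content m (and COD content d = 1 - m) are
#' assigned to a branch by their composition: COM-minor standards
#' (m < d) contribute points (X = m/d, Y = M/D), COM-major standards
#' (d < m) contribute (X' = d/m, Y' = D/M), and the 50/50 level
#' contributes to both.  Each branch is fitted by ordinary least squares
#' over all replicate points; R-squared, residual SD, coefficient
#' standard errors and per-level replicate SDs are stored.  If all levels
#' fall on one branch, the other is marked unusable.
#'
#' @param standards a data.frame with numeric columns \code{w_com} (true
#'   COM weight fraction in [0, 1]) and \code{M} (measured COM share, one
#'   row per replicate measurement), or a list of [Spectrum-class]
#'   objects carrying \code{metadata()$truth$w_com} (shares are then
#'   measured per replicate via [measureShares()]).
#' @param instrument instrument/generator tag stored with the model.
#' @param mode spectral mode the standards were measured in.
#' @param seed integer seed to record (bookkeeping only).
#' @return a [CalibrationModel-class].
#' @examples
#' std <- data.frame(w_com = rep(c(.2, .5, .8), each = 3))
#' std$M <- std$w_com         # fabricated identity-like shares
#' fitCalibration(std)
#' @export
fitCalibration <- function(standards, instrument = "synthetic-ftir-v1",
                           mode = "absorbance", seed = NA) {
    if (is.list(standards) && !is.data.frame(standards) &&
        all(vapply(standards, is, TRUE, "Spectrum"))) {
        w <- vapply(standards, function(s) metadata(s)$truth$w_com, 0)
        tags <- unique(vapply(standards, function(s)
            metadata(s)$instrument %||% instrument, ""))
        if (length(tags) > 1L)
            stop("standards carry mixed instrument tags: ",
                 paste(tags, collapse = ", "))
        instrument <- tags
        mode <- unique(vapply(standards, specMode, ""))[1L]
        M <- vapply(standards, function(s) comShare(measureShares(s)), 0)
        standards <- data.frame(w_com = w, M = M)
    }
    stopifnot(is.data.frame(standards),
              all(c("w_com", "M") %in% names(standards)))
    w <- standards$w_com
    M <- pmin(pmax(standards$M, 0), 1)
    D <- 1 - M

    fitBranch <- function(sel, X, Y) {
        lv <- unique(round(w[sel], 10))
        if (length(lv) < 3L)
            return(list(coef = c(a = NA_real_, b = NA_real_),
                        diag = list(r.squared = NA_real_,
                                    sigma = NA_real_,
                                    coef.se = c(a = NA_real_, b = NA_real_),
                                    n = sum(sel), levels = lv,
                                    level.sd = NULL,
                                    usable = FALSE)))
        fit <- stats::lm(Y ~ X, subset = sel)
        ## noiseless standards fit exactly; the perfect-fit summary
        ## warning is expected there
        sm <- suppressWarnings(summary(fit))
        lsd <- tapply(Y[sel], round(w[sel], 10), stats::sd)
        list(coef = c(a = unname(stats::coef(fit)[2L]),
                      b = unname(stats::coef(fit)[1L])),
             diag = list(r.squared = sm$r.squared, sigma = sm$sigma,
                         coef.se = c(a = sm$coefficients["X", 2L],
                                     b = sm$coefficients["(Intercept)", 2L]),
                         n = sum(sel), levels = lv,
                         level.sd = as.list(lsd), usable = TRUE))
    }
    eps <- 1e-12
    minorSel <- w <= 0.5 & D > eps          # m <= d
    majorSel <- w >= 0.5 & M > eps          # d <= m
    Xmin <- ifelse(D > eps, w / (1 - w), NA)
    Ymin <- ifelse(D > eps, M / D, NA)
    Xmaj <- ifelse(M > eps, (1 - w) / w, NA)
    Ymaj <- ifelse(M > eps, D / M, NA)
    minor <- fitBranch(minorSel, Xmin, Ymin)
    major <- fitBranch(majorSel, Xmaj, Ymaj)
    if (!minor$diag$usable && !major$diag$usable)
        stop("fewer than 3 composition levels on both branches; ",
             "cannot calibrate")
    new("CalibrationModel",
        minor = minor$coef, major = major$coef,
        diagnostics = list(minor = minor$diag, major = major$diag),
        instrument = instrument, mode = mode,
        seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}

#' Invert measured absorption shares to a COM/COD composition
#'
#' Routes by the measured shares: M <= D uses the COM-minor branch
#' (X = (Y - b)/a with Y = M/D, then m = X/(1+X)); M > D uses the
#' COM-major branch symmetrically.  X is clamped to [0, Inf) when noise
#' pushes it negative (flagged \code{"clamped"}).  The one-sigma
#' uncertainty combines, in quadrature, the branch residual SD and the
#' caller-supplied replicate SD of the shares, both propagated through
#' the inverse map.
#'
#' @param shares an [AbsorptionShares-class] (typically a replicate
#'   average).
#' @param cal a [CalibrationModel-class].
#' @param sharesSD optional SD of the COM share M over replicates.
#' @return a [MixtureResult-class] with m, d in weight percent.
#' @examples
#' cal <- fitCalibration(data.frame(w_com = rep(seq(.1, .9, .2), 2),
#'                                  M = rep(seq(.1, .9, .2), 2)))
#' estimateComposition(new("AbsorptionShares", M = 0.7, D = 0.3), cal)
#' @export
estimateComposition <- function(shares, cal, sharesSD = NA) {
    stopifnot(is(shares, "AbsorptionShares"), is(cal, "CalibrationModel"))
    M <- comShare(shares); D <- codShare(shares)
    flags <- character()
    branch <- if (M <= D) "minor" else "major"
    co <- slot(cal, branch)
    dg <- cal@diagnostics[[branch]]
    if (is.na(co[["a"]]) || !isTRUE(dg$usable))
        stop("calibration branch '", branch, "' is unusable")

    if (branch == "minor") {
        Y <- M / D                           # D >= 1/2 here, never 0
        dYdM <- 1 / D^2
    } else {
        Y <- D / M                           # M > 1/2 here, never 0
        dYdM <- -1 / M^2
        if (D == 0) flags <- c(flags, "pure-phase limit")
    }
    X <- (Y - co[["b"]]) / co[["a"]]
    if (X < 0) {
        X <- 0
        flags <- c(flags, "clamped")
    }
    frac <- X / (1 + X)                      # minor: m; major: d
    m <- if (branch == "minor") frac else 1 - frac

    ## uncertainty: quadrature of calibration residual SD and replicate
    ## SD (mapped to Y), through dX = dY/a and dm = dX/(1+X)^2
    sigY2 <- (dg$sigma %||% NA_real_)^2
    if (!is.na(sharesSD)) sigY2 <- sigY2 + (sharesSD * dYdM)^2
    unc <- if (is.na(sigY2)) NA_real_
           else 100 * sqrt(sigY2) / co[["a"]] / (1 + X)^2

    new("MixtureResult", m = 100 * m, d = 100 * (1 - m),
        branch = branch, uncertainty = unc, flags = flags,
        geometry = NULL)
}

#' Quantify COM/COD in a spectrum with the 780 cm-1 decomposition
#'
#' End-to-end single-sample path: geometry, shares, calibration
#' inversion.  The spectral mode must match the calibration's mode; a
#' reflectance spectrum is rejected with a pointer to [kkTransform()].
#'
#' @inheritParams locatePeakGeometry
#' @param cal a [CalibrationModel-class].
#' @param sharesSD optional replicate SD of M (see
#'   [estimateComposition()]).
#' @return a [MixtureResult-class] carrying the geometry snapshot.
#' @export
quantify780 <- function(s, cal, windows = list(apex = c(770, 790),
                                               left = c(700, 770),
                                               right = c(810, 900)),
                        rprimeAt = 800, sharesSD = NA) {
    stopifnot(is(s, "Spectrum"), is(cal, "CalibrationModel"))
    if (specMode(s) == "reflectance")
        stop("reflectance input: apply kkTransform() first, and use a ",
             "calibration built from absorption-index spectra")
    if (specMode(s) != cal@mode)
        stop(sprintf("mode mismatch: spectrum is '%s' but calibration %s",
                     specMode(s),
                     sprintf("was built from '%s' spectra", cal@mode)))
    tag <- metadata(s)$instrument
    if (!is.null(tag) && !identical(tag, cal@instrument))
        stop(sprintf("instrument mismatch: spectrum '%s' vs %s",
                     tag, sprintf("calibration '%s'; coefficients are apparatus-dependent",
                                  cal@instrument)))
    g <- locatePeakGeometry(s, windows, rprimeAt)
    res <- estimateComposition(computeShares(g), cal, sharesSD)
    res@geometry <- g
    res
}
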