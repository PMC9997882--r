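## Otsu threshold (maximize between-class variance) on a numeric vector,
## computed over a histogram spanning the data range, which makes the
## result invariant to affine intensity rescaling.
.otsuThreshold <- function(x, nbins = 256L) {
    r <- range(x)
    if (diff(r) <= 0) return(r[1L])
    br <- seq(r[1L], r[2L], length.out = nbins + 1L)
    h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
    mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
    w <- cumsum(h)
    mu <- cumsum(h * mids)
    tot <- w[nbins]; mtot <- mu[nbins]
    sel <- w > 0 & w < tot
    bc <- (mtot * w - tot * mu)^2 / (w * (tot - w))
    bc[!sel] <- -Inf
    mids[which.max(bc)]
}

#' Segment the stone in a CT slice
#'
#' Automatic two-class (Otsu) threshold between background/resin and
#' stone, followed by extraction of the largest connected component and
#' hole filling.  The threshold is recorded as an attribute so that
#' [classifyPhases()] can reuse it to split off interior void/resin
#' voxels.
#'
#' @param img a [CTImage-class].
#' @param minArea minimum stone area in voxels; smaller components are an
#'   error ("no stone found").
#' @return logical matrix mask (TRUE = stone), with attribute
#'   \code{"threshold"}.
#' @export
segmentStone <- function(img, minArea = 64) {
    stopifnot(is(img, "CTImage"))
    v <- ctValues(img)
    thr <- .otsuThreshold(as.vector(v))
    bin <- v > thr
    if (!any(bin)) stop("no stone found: nothing above threshold")
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    tab <- tabulate(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
    if (!length(tab) || max(tab) < minArea)
        stop("no stone found: largest component below ", minArea,
             " voxels")
    keep <- which.max(tab)
    mask <- EBImage::imageData(EBImage::fillHull(lab == keep)) > 0
    attr(mask, "threshold") <- thr
    mask
}

#' Classify stone voxels into COM, COD and void by attenuation
#'
#' Within the stone mask, voxels below the stone/background threshold are
#' split off as void/resin (interior holes admitted by hole-filling),
#' then a two-class Otsu threshold — estimated on an eroded stone core
#' and refined to the midpoint of the class means — separates COD (lower
#' attenuation) from COM (higher).  A surface ring of partial-volume
#' voxels is excluded from the map (see \code{surfaceMargin}).  If the masked
#' histogram carries no usable phase contrast — class means closer than
#' the pooled within-class spread, or a vanishing minority class — the
#' map is returned single-phase and flagged \code{"no phase contrast"}.
#'
#' All thresholds are recorded in the object.  Because the thresholds
#' derive from the histogram shape alone, the classification is invariant
#' to affine rescaling of the image intensities.
#'
#' @param img a [CTImage-class].
#' @param mask logical stone mask from [segmentStone()] (computed
#'   on the fly if missing).
#' @param mode \code{"auto"} (Otsu) or \code{"fixed"} (use
#'   \code{thresholds}); fixed thresholds keep a slice sequence on one
#'   common scale.
#' @param thresholds for \code{mode = "fixed"}: named numeric with
#'   \code{void} (below = void/resin) and \code{phase} (below = COD,
#'   above = COM).
#' @param minority minimum voxel share of the smaller phase class for the
#'   contrast to count as real.
#' @param surfaceMargin width (voxels) of the stone-surface ring excluded
#'   from the phase map: surface voxels blend stone and background
#'   attenuation through the point spread and carry no reliable phase
#'   signal.  Default: twice the phantom blur SD when known, else 2.
#' @return a [PhaseMap-class].  The phantom's \code{"sub-resolution"}
#'   flag is propagated from the image metadata when the crystal size is
#'   at or below twice the blur SD: CT values of blended sub-voxel
#'   domains no longer separate the phases.
#' @export
classifyPhases <- function(img, mask = NULL,
                           mode = c("auto", "fixed"),
                           thresholds = NULL, minority = 0.02,
                           surfaceMargin = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(img, "CTImage"))
    if (is.null(mask)) mask <- segmentStone(img)
    if (!any(mask)) stop("empty stone mask")
    v <- ctValues(img)
    lev <- phaseLevels()
    labels <- matrix(lev[["background"]], nrow(v), ncol(v))
    flags <- character()

    if (mode == "fixed") {
        if (is.null(thresholds) ||
            !all(c("void", "phase") %in% names(thresholds)))
            stop("mode='fixed' needs thresholds c(void=, phase=)")
        tVoid <- thresholds[["void"]]; tPhase <- thresholds[["phase"]]
    } else {
        tVoid <- attr(mask, "threshold") %||% -Inf
        ## estimate the COD/COM threshold on an eroded core: the
        ## stone-edge rim carries blurred stone/background values that
        ## fake a second mode on uniform stones
        core <- EBImage::imageData(EBImage::erode(
            EBImage::Image(mask * 1), EBImage::makeBrush(7, "disc"))) > 0
        sel <- core & v >= tVoid
        if (sum(sel) < 100L) sel <- mask & v >= tVoid
        crystal <- v[sel]
        tPhase <- .otsuThreshold(crystal)
        ## mean-midpoint (isodata) refinement symmetrises the treatment
        ## of blurred domain-boundary voxels around the threshold
        for (it in 1:50) {
            lo <- crystal[crystal <= tPhase]
            hi <- crystal[crystal > tPhase]
            if (!length(lo) || !length(hi)) break
            tNew <- (mean(lo) + mean(hi)) / 2
            if (abs(tNew - tPhase) < 1e-9) break
            tPhase <- tNew
        }
        lo <- crystal[crystal <= tPhase]; hi <- crystal[crystal > tPhase]
        ## contrast decision: Otsu separability (between-class over
        ## total variance; ~0.64 for a single Gaussian, near 1 for two
        ## real modes) plus a minimum minority share
        w1 <- length(lo) / length(crystal); w2 <- 1 - w1
        eta <- if (stats::var(crystal) > 0)
            w1 * w2 * (mean(hi) - mean(lo))^2 / stats::var(crystal)
        else 0
        if (!is.finite(eta) || eta < 0.85 ||
            min(w1, w2) < minority) {
            flags <- c(flags, "no phase contrast")
            tPhase <- -Inf                   # single phase: all -> COM
        }
    }
    if (!(tVoid < tPhase || !is.finite(tPhase)))
        if (is.finite(tPhase) && tVoid >= tPhase)
            stop("thresholds must be ordered void < phase")

    md <- metadata(img)
    if (is.null(surfaceMargin))
        surfaceMargin <- if (!is.null(md$blurSigma))
            ceiling(2 * md$blurSigma) else 2L
    if (surfaceMargin > 0) {
        inner <- EBImage::imageData(EBImage::erode(
            EBImage::Image(mask * 1),
            EBImage::makeBrush(2L * as.integer(surfaceMargin) + 1L,
                               "disc"))) > 0
        if (any(inner)) {
            thr0 <- attr(mask, "threshold")
            mask <- inner
            attr(mask, "threshold") <- thr0
        }
    }
    labels[mask] <- ifelse(v[mask] < tVoid, lev[["void"]],
                    ifelse(v[mask] <= tPhase, lev[["COD"]],
                           lev[["COM"]]))

    if (!is.null(md$crystalSize) && !is.null(md$blurSigma) &&
        md$crystalSize <= 2 * md$blurSigma)
        flags <- c(flags, "sub-resolution")

    new("PhaseMap", labels = labels, mask = mask,
        thresholds = c(void = unname(tVoid), phase = unname(tPhase)),
        voxelSize = voxelSize(img), flags = unique(flags),
        metadata = md)
}

#' COM/COD fractions inside square regions of interest
#'
#' For each ROI, counts COM and COD voxels inside the stone mask and
#' reports COM\% = COM / (COM + COD) * 100; void/resin voxels are
#' excluded from the denominator.  The default ROI side of 10 voxels is a
#' 50-micrometre square at the default 0.005 mm/voxel.
#'
#' @param pm a [PhaseMap-class].
#' @param rois data.frame with columns \code{x}, \code{y} (ROI origin,
#'   1-based voxel indices: row, column) and optionally \code{size}
#'   (side length in voxels, default 10).
#' @return data.frame with one row per ROI: origin, size, voxel counts
#'   per class, \code{com_pct}, \code{cod_pct}, and \code{flags}
#'   (\code{"outside stone"}, \code{"no classified voxels"},
#'   \code{"mostly void"}, \code{"sub-resolution"}).
#' @export
roiFractions <- function(pm, rois) {
    stopifnot(is(pm, "PhaseMap"))
    rois <- as.data.frame(rois)
    if (is.null(rois$size)) rois$size <- 10L
    lev <- phaseLevels()
    lab <- pm@labels
    subres <- "sub-resolution" %in% pm@flags
    out <- lapply(seq_len(nrow(rois)), function(i) {
        x0 <- rois$x[i]; y0 <- rois$y[i]; sz <- rois$size[i]
        xs <- x0:min(x0 + sz - 1L, nrow(lab))
        ys <- y0:min(y0 + sz - 1L, ncol(lab))
        block <- lab[xs, ys]
        inMask <- pm@mask[xs, ys]
        flags <- character()
        nCom <- sum(block == lev[["COM"]])
        nCod <- sum(block == lev[["COD"]])
        nVoid <- sum(block == lev[["void"]])
        if (!any(inMask)) flags <- c(flags, "outside stone")
        if (nCom + nCod == 0L) {
            flags <- c(flags, "no classified voxels")
            com <- NA_real_; cod <- NA_real_
        } else {
            com <- 100 * nCom / (nCom + nCod)
            cod <- 100 - com
            if (nVoid > nCom + nCod) flags <- c(flags, "mostly void")
        }
        if (subres) flags <- c(flags, "sub-resolution")
        data.frame(roi = i, x = x0, y = y0, size = sz,
                   n_com = nCom, n_cod = nCod, n_void = nVoid,
                   com_pct = com, cod_pct = cod,
                   flags = paste(flags, collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Tile the stone with ROIs and aggregate whole-stone fractions
#'
#' Applies [roiFractions()] on a regular tiling of the mask's bounding
#' box and adds the whole-stone aggregate, which by construction equals
#' the voxel-count fraction of the phase map.
#'
#' @param pm a [PhaseMap-class].
#' @param step tile side length in voxels (>= 1), default 10.
#' @return list with \code{tiles} (the [roiFractions()] data.frame,
#'   tiles intersecting the stone only) and \code{aggregate} (named list:
#'   \code{com_pct}, \code{cod_pct}, counts).
#' @export
mapFractions <- function(pm, step = 10L) {
    stopifnot(is(pm, "PhaseMap"))
    if (step < 1) stop("'step' must be at least one voxel")
    lev <- phaseLevels()
    idx <- which(pm@mask, arr.ind = TRUE)
    xr <- range(idx[, 1L]); yr <- range(idx[, 2L])
    grid <- expand.grid(x = seq(xr[1L], xr[2L], by = step),
                        y = seq(yr[1L], yr[2L], by = step))
    grid$size <- as.integer(step)
    tiles <- roiFractions(pm, grid)
    tiles <- tiles[tiles$n_com + tiles$n_cod + tiles$n_void > 0, ]
    nCom <- sum(pm@labels == lev[["COM"]])
    nCod <- sum(pm@labels == lev[["COD"]])
    agg <- list(
        com_pct = if (nCom + nCod > 0) 100 * nCom / (nCom + nCod)
                  else NA_real_,
        cod_pct = if (nCom + nCod > 0) 100 * nCod / (nCom + nCod)
                  else NA_real_,
        n_com = nCom, n_cod = nCod,
        n_void = sum(pm@labels == lev[["void"]]))
    list(tiles = tiles, aggregate = agg)
}
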