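#' Synthesize a two-phase micro-CT slice phantom
#'
#' Builds a disc-shaped "stone" tiled with square COM/COD crystal domains
#' of configurable size, embedded in a low-attenuation background, then
#' applies a Gaussian point-spread blur and additive noise.  Attenuation
#' is ordered COM > COD > resin > air, mirroring the density ordering that
#' makes CT-value phase mapping possible.  Ground-truth labels are taken
#' before blurring.
#'
#' COM domains are assigned by drawing whole domains from a shuffled urn
#' until the target COM voxel share is met, so the achieved truth fraction
#' tracks the target to within a single domain's voxel count rather than
#' with binomial scatter.
#'
#' @param size image side length in voxels (square image).
#' @param voxelSize voxel edge length, mm (default 0.005 mm/voxel).
#' @param crystalSize crystal-domain edge length in voxels (>= 1).
#' @param fraction target COM voxel fraction of the stone, in [0, 1].
#' @param attenuation named numeric means, must satisfy
#'   COM > COD > resin > air.
#' @param noiseSD additive Gaussian noise SD, same units as attenuation.
#'   The default is 5\% of the COM-COD gap.
#' @param blurSigma Gaussian PSF sigma in voxels (0 = no blur).
#' @param nVoids number of small resin-filled voids punched into the
#'   stone (truth label \code{void}).
#' @param seed integer seed.
#' @return list with elements \code{image} (a [CTImage-class]) and
#'   \code{truth} (integer label matrix, codes as in [phaseLevels()]).
#'   Image metadata records the achieved fraction and, when
#'   \code{crystalSize <= 2 * blurSigma}, the \code{"sub-resolution"}
#'   flag: domains at or below the PSF scale blend and their CT values no
#'   longer separate the phases.
#' @examples
#' ph <- makeCTPhantom(size = 128, fraction = 0.8, seed = 1)
#' @export
makeCTPhantom <- function(size = 512, voxelSize = 0.005, crystalSize = 8,
                          fraction = 0.5,
                          attenuation = c(COM = 0.80, COD = 0.60,
                                          resin = 0.25, air = 0.05),
                          noiseSD = 0.01, blurSigma = 1, nVoids = 0,
                          seed = NULL) {
    if (is.na(fraction) || fraction < 0 || fraction > 1)
        stop("'fraction' must lie in [0, 1]")
    stopifnot(crystalSize >= 1, size >= 16, noiseSD >= 0, blurSigma >= 0)
    att <- attenuation
    if (!all(c("COM", "COD", "resin", "air") %in% names(att)))
        stop("'attenuation' needs named means COM, COD, resin, air")
    if (!(att[["COM"]] > att[["COD"]] && att[["COD"]] > att[["resin"]] &&
          att[["resin"]] > att[["air"]]))
        stop("attenuation ordering COM > COD > resin > air violated")
    .withSeed(seed, {
        ctr <- (size + 1) / 2
        radius <- 0.42 * size
        ix <- matrix(seq_len(size), size, size)
        iy <- matrix(seq_len(size), size, size, byrow = TRUE)
        stone <- (ix - ctr)^2 + (iy - ctr)^2 <= radius^2

        ## domain grid; urn assignment of COM domains to hit the target
        ## voxel share
        cellRow <- (ix - 1L) %/% crystalSize
        cellCol <- (iy - 1L) %/% crystalSize
        cellId <- cellRow + cellCol * (size %/% crystalSize + 1L) + 1L
        stoneCells <- cellId[stone]
        counts <- table(stoneCells)
        ids <- as.integer(names(counts))
        ord <- sample(length(ids))
        cum <- cumsum(as.integer(counts)[ord])
        target <- fraction * sum(stone)
        nCom <- sum(cum <= target)
        ## take one more domain if that lands closer to the target
        if (nCom < length(ids)) {
            overshoot <- cum[nCom + 1L] - target
            undershoot <- target - if (nCom > 0) cum[nCom] else 0
            if (overshoot < undershoot) nCom <- nCom + 1L
        }
        comIds <- ids[ord[seq_len(nCom)]]

        lev <- phaseLevels()
        truth <- matrix(lev[["background"]], size, size)
        truth[stone] <- ifelse(cellId[stone] %in% comIds,
                               lev[["COM"]], lev[["COD"]])
        if (nVoids > 0) {
            vr <- max(2, crystalSize)
            for (v in seq_len(nVoids)) {
                vx <- runif(1, ctr - 0.6 * radius, ctr + 0.6 * radius)
                vy <- runif(1, ctr - 0.6 * radius, ctr + 0.6 * radius)
                hole <- (ix - vx)^2 + (iy - vy)^2 <= vr^2 & stone
                truth[hole] <- lev[["void"]]
            }
        }
        achieved <- sum(truth == lev[["COM"]]) /
            sum(truth %in% c(lev[["COM"]], lev[["COD"]]))

        vals <- matrix(att[["air"]], size, size)
        vals[truth == lev[["void"]]] <- att[["resin"]]
        vals[truth == lev[["COD"]]] <- att[["COD"]]
        vals[truth == lev[["COM"]]] <- att[["COM"]]
        if (blurSigma > 0)
            vals <- .gaussianBlur(vals, blurSigma)
        if (noiseSD > 0)
            vals <- vals + matrix(rnorm(size^2, 0, noiseSD), size, size)

        flags <- character()
        if (crystalSize <= 2 * blurSigma) flags <- "sub-resolution"
        img <- CTImage(vals, voxelSize = voxelSize,
                       metadata = list(
                           crystalSize = crystalSize,
                           blurSigma = blurSigma,
                           targetFraction = fraction,
                           achievedFraction = achieved,
                           attenuation = as.list(att),
                           noiseSD = noiseSD, flags = flags,
                           seed = if (is.null(seed)) NA_integer_
                                  else as.integer(seed),
                           synthetic = TRUE))
        list(image = img, truth = truth)
    })
}

## Gaussian blur of a plain matrix via EBImage, preserving edges by
## replication padding (EBImage's filter2 wraps circularly otherwise).
.gaussianBlur <- function(m, sigma) {
    pad <- ceiling(4 * sigma)
    n1 <- nrow(m); n2 <- ncol(m)
    big <- m[c(rep(1, pad), seq_len(n1), rep(n1, pad)),
             c(rep(1, pad), seq_len(n2), rep(n2, pad))]
    sm <- EBImage::gblur(EBImage::Image(big), sigma = sigma)
    EBImage::imageData(sm)[pad + seq_len(n1), pad + seq_len(n2)]
}
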