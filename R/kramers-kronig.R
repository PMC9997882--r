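#' Kramers-Kronig transform of a specular reflectance spectrum
#'
#' Recovers the absorption-index spectrum k(nu) from normal-incidence
#' specular reflectance R(nu).  The reflection phase phi(nu) is obtained
#' from the Kramers-Kronig relation applied to ln sqrt(R), evaluated as an
#' FFT-based discrete Hilbert transform after (i) constant extrapolation
#' of ln sqrt(R) below and above the measured range (standard mitigation
#' of finite-range truncation) and (ii) even-symmetric extension about
#' zero wavenumber.  The complex amplitude r = sqrt(R) exp(i phi) then
#' gives the refractive index n = (1 + r) / (1 - r) and k = Im(n).
#'
#' Small negative excursions of k are an expected finite-range artefact;
#' they are clamped to zero, with a warning when they fall below -0.01.
#'
#' @param r a reflectance [Spectrum-class] on a uniform grid, with
#'   R strictly inside (0, 1).
#' @param padFactor total padded axis length as a multiple of the
#'   measured length (larger = less truncation bias).
#' @return an absorption-index [Spectrum-class] on the same grid.
#' @examples
#' refl <- makeReflectanceSpectrum(
#'     data.frame(center = 1600, strength = 0.08, damping = 30))
#' k <- kkTransform(refl)
#' @export
kkTransform <- function(r, padFactor = 8) {
    stopifnot(is(r, "Spectrum"))
    if (specMode(r) != "reflectance")
        stop("kkTransform requires a reflectance spectrum")
    wn <- wavenumbers(r)
    R <- intensities(r)
    step <- diff(wn)
    if (diff(range(step)) > 1e-8 * mean(step))
        stop("kkTransform requires a uniform wavenumber grid")
    if (min(R) <= 0 || max(R) >= 1)
        stop("reflectance touching 0 or 1; log/ratio singular")
    h <- step[1L]
    n <- length(wn)
    g <- log(sqrt(R))

    ## pad: [0, wn[1]) with g[1]; beyond wn[n] with g[n], to a power of two
    nLow <- max(0L, as.integer(round(wn[1L] / h)))
    nTot <- 2^ceiling(log2(max(padFactor * n, 2 * (nLow + n))))
    gFull <- c(rep(g[1L], nLow), g, rep(g[n], nTot - nLow - n))

    phiFull <- .hilbertEven(gFull)
    phi <- phiFull[nLow + seq_len(n)]

    rho <- sqrt(R) * exp(1i * phi)
    nc <- (1 + rho) / (1 - rho)
    k <- Im(nc)
    if (min(k) < -0.01)
        warning(sprintf("recovered k reaches %.4f; finite-range %s",
                        min(k), "truncation artefact, clamped at 0"))
    k[k < 0] <- 0
    out <- Spectrum(wn, k, "absorption-index", metadata(r))
    .appendProvenance(out, list(op = "kkTransform",
                                padFactor = padFactor))
}

## Discrete Hilbert transform H[x](t) = (1/pi) PV int x(s)/(t-s) ds of a
## sequence sampled on 0..(N-1), computed on its even-symmetric extension
## (the input represents an even function of the axis).  Returns the
## transform on the original indices.
.hilbertEven <- function(x) {
    N <- length(x)
    xe <- c(x, rev(x[2:(N - 1L)]))          # even extension, length L
    L <- length(xe)
    X <- stats::fft(xe)
    m <- complex(real = rep(0, L), imaginary = rep(0, L))
    m[2:(L / 2)] <- -1i
    m[(L / 2 + 2):L] <- 1i
    Re(stats::fft(X * m, inverse = TRUE)) / L
}
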