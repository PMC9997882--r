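#' Synthesize the pure-phase COM and COD reference spectra
#'
#' Evaluates the configured band sets on the grid and normalises each
#' spectrum so its 780 cm^-1 apex (maximum over 770-790 cm^-1) equals
#' \code{config$referenceHeight}.  The COM basis is essentially transparent
#' at 800 cm^-1 (< 5\% of its apex) while the COD basis retains most of its
#' apex value there; this contrast is what the geometric peak decomposition
#' exploits.
#'
#' @param config a [generatorConfig()].
#' @return named list of two absorbance [Spectrum-class] objects,
#'   \code{COM} and \code{COD}.
#' @examples
#' b <- makeBasisSpectra(generatorConfig())
#' @export
makeBasisSpectra <- function(config = generatorConfig()) {
    grid <- config$grid
    mk <- function(bands, phase) {
        y <- .evalBands(bands, grid)
        apexWin <- grid >= 770 & grid <= 790
        apex <- max(y[apexWin])
        if (apex > 0) y <- y * (config$referenceHeight / apex)
        Spectrum(grid, y, "absorbance",
                 metadata = list(phase = phase,
                                 instrument = config$instrument,
                                 synthetic = TRUE))
    }
    list(COM = mk(config$comBands, "COM"),
         COD = mk(config$codBands, "COD"))
}

#' Synthetic atmospheric reference spectra
#'
#' Fixed-shape H2O and CO2 absorption references on a given grid: the CO2
#' antisymmetric-stretch doublet near 2349 cm^-1 and a deterministic comb
#' of narrow rotational H2O lines over 1300-1900 and 3500-3900 cm^-1.
#' These are synthesized shapes, not measured atmospheric spectra; only
#' their subtraction behaviour matters.
#'
#' @param grid wavenumber grid, cm^-1.
#' @return named list of two unit-peak absorbance [Spectrum-class]
#'   objects, \code{h2o} and \code{co2}.
#' @export
atmosphericReferences <- function(grid) {
    co2 <- .evalBands(list(spectralBand(2361, 1.0, 9),
                           spectralBand(2340, 0.8, 9)), grid)
    lines <- c(seq(1320, 1880, by = 16), seq(3520, 3880, by = 14))
    h2o <- numeric(length(grid))
    for (i in seq_along(lines)) {
        h <- 0.3 + 0.7 * abs(sin(7.3 * i))   # deterministic line strengths
        h2o <- h2o + .evalBand(spectralBand(lines[i], h, 4), grid)
    }
    norm <- function(y) if (max(y) > 0) y / max(y) else y
    list(h2o = Spectrum(grid, norm(h2o), "absorbance",
                        metadata = list(species = "H2O", synthetic = TRUE)),
         co2 = Spectrum(grid, norm(co2), "absorbance",
                        metadata = list(species = "CO2", synthetic = TRUE)))
}

#' Synthesize one mixture spectrum with known ground truth
#'
#' Beer-Lambert additive mixing: \code{wCom} times the COM basis plus
#' \code{1 - wCom} times the COD basis, plus (optionally) a polynomial
#' baseline, scaled atmospheric H2O/CO2 bands, an interferent component,
#' and iid Gaussian noise.  The true composition, the seed and the
#' instrument tag are recorded in the metadata.
#'
#' @param wCom COM weight fraction in [0, 1].
#' @param config a [generatorConfig()].
#' @param seed integer seed for the noise draw (optional; the caller's RNG
#'   state is left untouched).
#' @param noise,baseline,atmosphere logical switches for the additive
#'   components.
#' @return an absorbance [Spectrum-class]; ground truth in
#'   \code{metadata(s)$truth}.
#' @examples
#' s <- makeMixtureSpectrum(0.3, generatorConfig(), seed = 1)
#' metadata(s)$truth$w_com
#' @export
makeMixtureSpectrum <- function(wCom, config = generatorConfig(),
                                seed = NULL, noise = TRUE,
                                baseline = TRUE, atmosphere = TRUE) {
    if (length(wCom) != 1L || is.na(wCom) || wCom < 0 || wCom > 1)
        stop("'wCom' must be a single weight fraction in [0, 1]")
    basis <- makeBasisSpectra(config)
    grid <- config$grid
    y <- wCom * intensities(basis$COM) +
        (1 - wCom) * intensities(basis$COD)
    if (config$interferentScale > 0 && !is.null(config$interferentBands))
        y <- y + config$interferentScale *
            .evalBands(config$interferentBands, grid)
    if (baseline)
        y <- y + .evalBaseline(config$baseline, grid)
    if (atmosphere && (config$h2oScale > 0 || config$co2Scale > 0)) {
        atm <- atmosphericReferences(grid)
        y <- y + config$h2oScale * intensities(atm$h2o) +
            config$co2Scale * intensities(atm$co2)
    }
    if (noise && config$noiseSD > 0)
        y <- y + .withSeed(seed, rnorm(length(grid), 0, config$noiseSD))
    Spectrum(grid, y, "absorbance",
             metadata = list(
                 truth = list(w_com = wCom, w_cod = 1 - wCom,
                              x_com = weightToMol(wCom)),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 instrument = config$instrument,
                 synthetic = TRUE))
}

#' Synthesize a calibration-standard set
#'
#' Mimics the preparation of mixed COM/COD standards measured repeatedly:
#' \code{length(levels) * nReps} spectra with independent noise draws,
#' each carrying its true composition.  The default of six replicates per
#' level follows the standard practice of measuring each standard at least
#' six times.
#'
#' @param levels COM weight fractions of the standards; default 0, 0.1,
#'   ..., 1.0.
#' @param nReps replicate measurements per level (>= 1), default 6.
#' @param config a [generatorConfig()].
#' @param seed master seed; per-spectrum seeds are derived from it.
#' @return list of [Spectrum-class] objects (length
#'   \code{length(levels) * nReps}).
#' @export
makeCalibrationSet <- function(levels = seq(0, 1, by = 0.1), nReps = 6,
                               config = generatorConfig(), seed = NULL) {
    if (!length(levels))
        stop("'levels' must contain at least one weight fraction")
    stopifnot(all(levels >= 0 & levels <= 1), nReps >= 1)
    n <- length(levels) * nReps
    seeds <- if (is.null(seed)) rep(list(NULL), n)
             else as.list(.withSeed(seed, sample.int(.Machine$integer.max, n)))
    out <- vector("list", n)
    k <- 0L
    for (w in levels) for (r in seq_len(nReps)) {
        k <- k + 1L
        s <- makeMixtureSpectrum(w, config, seed = seeds[[k]])
        md <- metadata(s)
        md$replicate <- r
        md$level <- w
        metadata(s) <- md
        out[[k]] <- s
    }
    out
}

#' Synthesize a specular reflectance spectrum from a Lorentz-oscillator
#' dielectric model
#'
#' Models the anomalous dispersion that distorts reflection-mode IR
#' measurements: \deqn{\epsilon(\nu) = n_\infty^2 + \sum_j S_j \nu_j^2 /
#' (\nu_j^2 - \nu^2 - i \gamma_j \nu)} with complex refractive index
#' \eqn{\tilde n = \sqrt\epsilon} (root with \eqn{Im\,\tilde n \ge 0}) and
#' normal-incidence reflectance \eqn{R = |(\tilde n - 1)/(\tilde n +
#' 1)|^2}.  The true absorption index \eqn{k = Im\,\tilde n} is attached
#' as ground truth so a Kramers-Kronig inversion can be validated against
#' the closed form.
#'
#' @param oscillators data.frame (or matrix) with columns \code{center}
#'   (cm^-1), \code{strength} (dimensionless, >= 0), \code{damping}
#'   (cm^-1, > 0).  Zero rows give a band-free dielectric.
#' @param nInf high-frequency refractive index background.
#' @param grid wavenumber grid, cm^-1.
#' @return a reflectance [Spectrum-class]; \code{metadata(s)$k_true} holds
#'   the ground-truth absorption index.
#' @examples
#' r <- makeReflectanceSpectrum(
#'     data.frame(center = 780, strength = 0.05, damping = 20))
#' @export
makeReflectanceSpectrum <- function(oscillators, nInf = 1.5,
                                    grid = seq(600, 4000, by = 1)) {
    osc <- as.data.frame(oscillators)
    if (nrow(osc)) {
        stopifnot(all(c("center", "strength", "damping") %in% names(osc)),
                  all(osc$strength >= 0), all(osc$damping > 0))
    }
    eps <- complex(real = rep(nInf^2, length(grid)), imaginary = 0)
    for (j in seq_len(nrow(osc)))
        eps <- eps + osc$strength[j] * osc$center[j]^2 /
            (osc$center[j]^2 - grid^2 - 1i * osc$damping[j] * grid)
    n <- sqrt(eps)
    flip <- Im(n) < 0                       # physical root: Im(n) >= 0
    n[flip] <- -n[flip]
    R <- Mod((n - 1) / (n + 1))^2
    Spectrum(grid, R, "reflectance",
             metadata = list(k_true = Im(n), n_true = Re(n),
                             n_inf = nInf, synthetic = TRUE))
}
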