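test_that("basis spectra realise the COM-narrow / COD-broad contrast", {
    cfg <- quietConfig()
    b <- makeBasisSpectra(cfg)
    wn <- wavenumbers(b$COM)
    apexOf <- function(s) max(intensities(s)[wn >= 770 & wn <= 790])
    at800 <- function(s) intensities(s)[wn == 800]

    expect_equal(apexOf(b$COM), 1.0)
    expect_equal(apexOf(b$COD), 1.0)
    ## COM is transparent at 800 cm-1 ...
    expect_lt(at800(b$COM) / apexOf(b$COM), 0.05)
    ## ... while COD keeps most of its apex value there; the generator
    ## must match the configured profile evaluated analytically at 800
    raw <- CaOxQuant:::.evalBands(cfg$codBands, c(780, 800))
    expect_gt(at800(b$COD) / apexOf(b$COD), 0.30)
    expect_equal(at800(b$COD) / intensities(b$COD)[wn == 780],
                 raw[2] / raw[1], tolerance = 1e-12)

    ## COD-specific 910 band, absent in COM
    sel910 <- wn >= 900 & wn <= 925
    expect_gt(max(intensities(b$COD)[sel910]) -
              min(intensities(b$COD)[wn >= 870 & wn <= 890]), 0.1)

    ## zero band heights give flat zero spectra
    z <- lapply(defaultCOMBands(), function(b)
        spectralBand(b$center, 0, b$fwhm))
    bz <- makeBasisSpectra(generatorConfig(comBands = z, codBands = z,
                                           noiseSD = 0))
    expect_equal(max(abs(intensities(bz$COM))), 0)
})

test_that("generator rejects a grid that misses the 780 region", {
    expect_error(generatorConfig(gridMin = 1000), "675-900")
})

test_that("mixtures are exact convex combinations of the bases", {
    cfg <- quietConfig()
    b <- makeBasisSpectra(cfg)
    pure <- makeMixtureSpectrum(1, cfg, noise = FALSE, baseline = FALSE,
                                atmosphere = FALSE)
    expect_equal(intensities(pure), intensities(b$COM))
    half <- makeMixtureSpectrum(0.5, cfg, noise = FALSE,
                                baseline = FALSE, atmosphere = FALSE)
    expect_equal(intensities(half),
                 (intensities(b$COM) + intensities(b$COD)) / 2)
    ## property: convex combination at every grid point, several weights
    for (w in c(0.1, 0.37, 0.82)) {
        s <- makeMixtureSpectrum(w, cfg, noise = FALSE, baseline = FALSE,
                                 atmosphere = FALSE)
        expect_equal(intensities(s),
                     w * intensities(b$COM) +
                     (1 - w) * intensities(b$COD))
    }
    expect_error(makeMixtureSpectrum(1.2, cfg), "\\[0, 1\\]")
})

test_that("identical seeds reproduce bit-identical spectra", {
    cfg <- generatorConfig(noiseSD = 0.002)
    a <- makeMixtureSpectrum(0.3, cfg, seed = 1)
    b <- makeMixtureSpectrum(0.3, cfg, seed = 1)
    c <- makeMixtureSpectrum(0.3, cfg, seed = 2)
    expect_identical(intensities(a), intensities(b))
    expect_false(identical(intensities(a), intensities(c)))
    expect_equal(metadata(a)$truth$w_com, 0.3)
    expect_equal(metadata(a)$truth$w_cod, 0.7)
})

test_that("calibration sets have the right size and replicate structure", {
    cfg <- quietConfig()
    set <- makeCalibrationSet(c(0, 0.5, 1), nReps = 6, config = cfg,
                              seed = 4)
    expect_length(set, 18)
    ## noiseless replicates within a level are identical
    lv <- vapply(set, function(s) metadata(s)$level, 0)
    reps <- set[lv == 0.5]
    for (r in reps[-1])
        expect_identical(intensities(r), intensities(reps[[1]]))
    expect_error(makeCalibrationSet(numeric(0)), "at least one")
    ## default replicate count is six
    expect_identical(formals(makeCalibrationSet)$nReps, 6)
})

test_that("reflectance generator matches its closed dielectric form", {
    ## no oscillators: R = ((n-1)/(n+1))^2 = 0.04 for n = 1.5, k = 0
    r0 <- makeReflectanceSpectrum(data.frame(center = numeric(),
                                             strength = numeric(),
                                             damping = numeric()),
                                  nInf = 1.5)
    expect_equal(unique(round(intensities(r0), 12)), 0.04)
    expect_equal(max(abs(metadata(r0)$k_true)), 0)

    ## one oscillator: independent evaluation of eps -> n -> R as oracle
    grid <- seq(600, 2000, by = 1)
    r <- makeReflectanceSpectrum(
        data.frame(center = 780, strength = 0.05, damping = 20),
        nInf = 1.5, grid = grid)
    eps <- 1.5^2 + 0.05 * 780^2 / (780^2 - grid^2 - 1i * 20 * grid)
    n <- sqrt(eps); n[Im(n) < 0] <- -n[Im(n) < 0]
    Roracle <- Mod((n - 1) / (n + 1))^2
    expect_equal(intensities(r), Roracle, tolerance = 1e-12)
    expect_true(all(intensities(r) > 0 & intensities(r) < 1))
    expect_true(all(metadata(r)$k_true >= 0))
    ## asymmetric dispersion shape peaking near the oscillator
    expect_lt(abs(grid[which.max(intensities(r))] - 780), 15)
})
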