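test_that("a lone Gaussian on a flat baseline decomposes as pure COM", {
    s <- gaussianSpectrum(780, 1, 12)
    g <- locatePeakGeometry(s)
    expect_equal(g@P[1], 780)
    expect_lt(abs(g@O[2]), 1e-6)
    expect_lt(abs(g@Q[2]), 1e-6)
    expect_lt(abs(g@C[2]), 1e-6)
    ## R carries the (tiny) 800 cm-1 value; shares are essentially 1/0
    sh <- computeShares(g)
    expect_gt(comShare(sh), 0.999)
    expect_equal(comShare(sh) + codShare(sh), 1)
})

test_that("geometry is immune to linear baselines by construction", {
    base <- makeMixtureSpectrum(0.35, quietConfig(), noise = FALSE,
                                baseline = FALSE, atmosphere = FALSE)
    M0 <- comShare(measureShares(base))
    for (co in list(c(0.3, 0), c(0, 5e-4), c(-0.2, 1e-3))) {
        ramp <- Spectrum(wavenumbers(base),
                         intensities(base) + co[1] +
                             co[2] * wavenumbers(base))
        expect_lt(abs(comShare(measureShares(ramp)) - M0), 1e-9)
    }
})

test_that("the COD basis peaks at 780 within one grid step", {
    b <- makeBasisSpectra(quietConfig())
    g <- locatePeakGeometry(b$COD)
    expect_lte(abs(g@P[1] - 780), 1)
    g2 <- locatePeakGeometry(b$COM)
    expect_lte(abs(g2@P[1] - 780), 1)
})

test_that("degenerate and malformed peaks are rejected", {
    ## apex on the window boundary: monotone rise through the window
    s <- Spectrum(600:1000, seq(0, 1, length.out = 401))
    expect_error(locatePeakGeometry(s), "no 780 peak")
    ## inverted peak: a valley at 780
    v <- Spectrum(600:1000, 1 - exp(-((600:1000 - 780) / 12)^2))
    expect_error(locatePeakGeometry(v), "no 780 peak|inverted")
    ## insufficient coverage
    short <- gaussianSpectrum(grid = seq(750, 850, 1))
    expect_error(locatePeakGeometry(short), "cover")
    ## reflectance mode refused
    r <- Spectrum(600:1000, rep(0.1, 401), "reflectance")
    expect_error(locatePeakGeometry(r), "kkTransform")
})

test_that("shares match an independent line-intersection oracle", {
    ## 1000 randomized single-peak spectra; the oracle recomputes M from
    ## the located points with explicit two-point line equations
    set.seed(42)
    grid <- seq(650, 950, by = 1)
    worst <- 0
    n <- 0
    for (i in 1:1000) {
        apexC <- runif(1, 773, 787)
        s <- Spectrum(grid,
            runif(1, 0.5, 2) *
                exp(-4 * log(2) * ((grid - apexC) / runif(1, 8, 60))^2) +
            runif(1, 0, 0.8) *
                exp(-4 * log(2) * ((grid - runif(1, 795, 830)) /
                                   runif(1, 15, 70))^2) +
            runif(1, -1, 1) + runif(1, -1e-3, 1e-3) * grid)
        g <- tryCatch(locatePeakGeometry(s), error = function(e) NULL)
        if (is.null(g)) next
        n <- n + 1
        M <- comShare(computeShares(g))
        Mo <- oracleShares(g@P, g@O, g@Q, g@Rprime)
        worst <- max(worst, abs(M - Mo))
    }
    expect_gt(n, 900)
    expect_lt(worst, 1e-12)
})

test_that("share conservation and clamping hold on noisy spectra", {
    cfg <- generatorConfig(noiseSD = 0.01)
    for (seed in 1:25) {
        s <- makeMixtureSpectrum(runif(1), cfg, seed = seed)
        sh <- measureShares(s)
        expect_equal(comShare(sh) + codShare(sh), 1)
        expect_true(comShare(sh) >= 0 && comShare(sh) <= 1)
    }
})

test_that("M rises monotonically with COM content (noiseless)", {
    cfg <- quietConfig()
    w <- seq(0, 1, by = 0.1)
    M <- vapply(w, function(x)
        comShare(measureShares(makeMixtureSpectrum(x, cfg,
                                                   noise = FALSE))), 0)
    expect_true(all(diff(M) > 0))
})
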