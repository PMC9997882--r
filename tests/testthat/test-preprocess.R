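test_that("resampling is exact on its own grid and on linear input", {
    s <- gaussianSpectrum()
    same <- resampleLinear(s, wavenumbers(s))
    expect_equal(intensities(same), intensities(s))
    ramp <- Spectrum(600:1000, 2 + 0.01 * (600:1000))
    fine <- resampleLinear(ramp, seq(600.5, 999.5, by = 1))
    expect_equal(intensities(fine), 2 + 0.01 * seq(600.5, 999.5, by = 1))
    expect_error(resampleLinear(s, seq(500, 900, 1)), "support")
})

test_that("resampling error obeys the second-order interpolation bound", {
    ## Gaussian band, step 1 -> 0.5; max error <= h^2 max|f''| / 8
    fwhm <- 12; c0 <- 780
    f <- function(x) exp(-4 * log(2) * ((x - c0) / fwhm)^2)
    s <- Spectrum(seq(700, 860, by = 1), f(seq(700, 860, by = 1)))
    grid <- seq(700, 860, by = 0.5)
    r <- resampleLinear(s, grid)
    maxf2 <- 8 * log(2) / fwhm^2             # |f''| at the apex
    expect_lt(max(abs(intensities(r) - f(grid))), maxf2 / 8)
})

test_that("provenance and metadata survive preprocessing", {
    s <- makeMixtureSpectrum(0.5, quietConfig(), noise = FALSE)
    out <- subtractAtmosphere(resampleLinear(s, seq(650, 3900, 1)))
    expect_equal(metadata(out)$truth$w_com, 0.5)
    ops <- vapply(metadata(out)$provenance, `[[`, "", "op")
    expect_identical(ops, c("resampleLinear", "subtractAtmosphere"))
})

test_that("atmospheric subtraction recovers constructed scale factors", {
    cfg <- quietConfig()
    clean <- makeMixtureSpectrum(0.5, cfg, noise = FALSE,
                                 atmosphere = FALSE)
    atm <- atmosphericReferences(wavenumbers(clean))
    ## no atmospheric content: scales ~ 0, output ~ input
    nothing <- subtractAtmosphere(clean)
    expect_lt(abs(metadata(nothing)$atmosphere$alpha), 0.01)
    expect_lt(abs(metadata(nothing)$atmosphere$beta), 0.01)
    expect_lt(max(abs(intensities(nothing) - intensities(clean))), 0.01)

    ## constructed contamination: beta recovered to 0.01
    dirty <- Spectrum(wavenumbers(clean),
                      intensities(clean) + 0.7 * intensities(atm$co2) +
                          0.45 * intensities(atm$h2o), "absorbance")
    fixed <- subtractAtmosphere(dirty)
    expect_equal(metadata(fixed)$atmosphere$beta, 0.7, tolerance = 0.01)
    expect_equal(metadata(fixed)$atmosphere$alpha, 0.45,
                 tolerance = 0.02)
    wn <- wavenumbers(fixed)
    win <- wn >= 2300 & wn <= 2400
    expect_lt(max(abs(intensities(fixed)[win] -
                      intensities(clean)[win])), 1e-6)
})

test_that("subtracting a pure reference empties its window", {
    grid <- seq(600, 4000, 1)
    atm <- atmosphericReferences(grid)
    co2only <- Spectrum(grid, intensities(atm$co2), "absorbance")
    out <- subtractAtmosphere(co2only)
    win <- grid >= 2300 & grid <= 2400
    expect_lt(max(abs(intensities(out)[win])), 1e-8)
})

test_that("atmospheric subtraction is idempotent", {
    s <- makeMixtureSpectrum(0.3, generatorConfig(noiseSD = 0),
                             noise = FALSE)     # atmosphere included
    once <- subtractAtmosphere(s)
    twice <- subtractAtmosphere(once)
    expect_lt(abs(metadata(twice)$atmosphere$alpha), 1e-6)
    expect_lt(abs(metadata(twice)$atmosphere$beta), 1e-6)
})

test_that("negative fitted scales clamp to zero with a warning", {
    grid <- seq(600, 4000, 1)
    atm <- atmosphericReferences(grid)
    s <- Spectrum(grid, 1 - 0.5 * intensities(atm$co2), "absorbance")
    expect_warning(out <- subtractAtmosphere(s), "clamped")
    expect_equal(metadata(out)$atmosphere$beta, 0)
})
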