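test_that("an exact identity relation is fitted at machine precision", {
    ## shares equal to the true COM fraction make Y = X on both branches
    std <- data.frame(w_com = rep(seq(0, 1, 0.1), 2))
    std$M <- std$w_com
    cal <- fitCalibration(std)
    expect_equal(unname(cal@minor[["a"]]), 1, tolerance = 1e-10)
    expect_equal(unname(cal@minor[["b"]]), 0, tolerance = 1e-10)
    expect_equal(unname(cal@major[["a"]]), 1, tolerance = 1e-10)
    expect_equal(unname(cal@major[["b"]]), 0, tolerance = 1e-10)
    expect_equal(cal@diagnostics$minor$r.squared, 1)
})

test_that("noiseless generator standards calibrate linearly on both branches", {
    cal <- fitCalibration(cleanStandards())
    expect_gt(cal@diagnostics$minor$r.squared, 0.999)
    expect_gt(cal@diagnostics$major$r.squared, 0.999)
})

test_that("noisy replicates yield finite coefficient standard errors", {
    std <- makeCalibrationSet(seq(0.1, 0.9, 0.2), nReps = 6,
                              config = generatorConfig(noiseSD = 0.002),
                              seed = 5)
    cal <- fitCalibration(lapply(std, subtractAtmosphere))
    for (br in c("minor", "major")) {
        se <- cal@diagnostics[[br]]$coef.se
        expect_true(all(is.finite(se)))
        expect_true(all(se > 0))
        expect_gt(length(cal@diagnostics[[br]]$level.sd), 0)
    }
})

test_that("single-branch standards leave the other branch unusable", {
    std <- data.frame(w_com = rep(c(0.1, 0.2, 0.3, 0.4), 2))
    std$M <- std$w_com
    cal <- fitCalibration(std)
    expect_true(cal@diagnostics$minor$usable)
    expect_false(cal@diagnostics$major$usable)
    expect_error(estimateComposition(
        new("AbsorptionShares", M = 0.8, D = 0.2), cal), "unusable")
})

test_that("closed-form inversions hit the pure and 70/30 limits", {
    idcal <- fitCalibration({
        d <- data.frame(w_com = rep(seq(0, 1, 0.1), 2)); d$M <- d$w_com; d
    })
    r <- estimateComposition(new("AbsorptionShares", M = 1, D = 0), idcal)
    expect_equal(comContent(r), 100)
    expect_equal(codContent(r), 0)
    r2 <- estimateComposition(new("AbsorptionShares", M = 0.7, D = 0.3),
                              idcal)
    ## identity branch: D/M = d/m -> m = 70 wt%
    expect_equal(comContent(r2), 70, tolerance = 1e-9)
    expect_identical(r2@branch, "major")
    r3 <- estimateComposition(new("AbsorptionShares", M = 0.3, D = 0.7),
                              idcal)
    expect_equal(comContent(r3), 30, tolerance = 1e-9)
    expect_identical(r3@branch, "minor")
})

test_that("noiseless composition recovery is sub-percent", {
    cfg <- quietConfig()
    cal <- fitCalibration(cleanStandards(cfg))
    for (w in seq(0, 1, 0.1)) {
        r <- quantify780(cleanMixture(w, cfg), cal)
        expect_lt(abs(comContent(r) - 100 * w), 1)
    }
})

test_that("both branches agree at the 50/50 crossover", {
    ## invert the same measured shares through each branch's equation
    cfg <- quietConfig()
    cal <- fitCalibration(cleanStandards(cfg))
    sh <- measureShares(cleanMixture(0.5, cfg))
    Y <- comShare(sh) / codShare(sh)
    X <- (Y - cal@minor[["b"]]) / cal@minor[["a"]]
    mMinor <- 100 * X / (1 + X)
    Yp <- codShare(sh) / comShare(sh)
    Xp <- (Yp - cal@major[["b"]]) / cal@major[["a"]]
    mMajor <- 100 / (1 + Xp)
    expect_lt(abs(mMinor - mMajor), 1)
})

test_that("uncertainty is reported and nonnegative", {
    cfg <- generatorConfig(noiseSD = 0.002)
    std <- lapply(makeCalibrationSet(seq(0, 1, 0.1), 6, cfg, seed = 2),
                  subtractAtmosphere)
    cal <- fitCalibration(std)
    s <- subtractAtmosphere(makeMixtureSpectrum(0.4, cfg, seed = 9))
    r <- quantify780(s, cal, sharesSD = 0.01)
    expect_true(is.finite(r@uncertainty))
    expect_gte(r@uncertainty, 0)
})

test_that("guards: instrument tags, spectral modes, reflectance input", {
    cfg <- quietConfig()
    cal <- fitCalibration(cleanStandards(cfg))
    other <- generatorConfig(noiseSD = 0, instrument = "other-box")
    expect_error(quantify780(cleanMixture(0.2, other), cal),
                 "instrument mismatch")
    refl <- makeReflectanceSpectrum(
        data.frame(center = 780, strength = 0.03, damping = 15))
    expect_error(quantify780(refl, cal), "kkTransform")
    mixed <- c(cleanStandards(cfg)[1:3],
               lapply(c(0.6, 0.8, 1), cleanMixture, config = other))
    expect_error(fitCalibration(mixed), "mixed instrument")
})

test_that("mol/weight conversion matches arithmetic and round-trips", {
    expect_equal(molToWeight(0), 0)
    expect_equal(molToWeight(1), 1)
    expect_equal(molToWeight(0.5), 146.11 / 310.24, tolerance = 1e-12)
    x <- seq(0, 1, 0.05)
    expect_lt(max(abs(weightToMol(molToWeight(x)) - x)), 1e-12)
    expect_error(molToWeight(1.2))
})
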