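## shared fixtures for the comparison analyses: noiseless standards and
## the three calibrated models
altFixtures <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- quietConfig()
            std <- cleanStandards(cfg)
            cache <<- list(
                cfg = cfg, std = std,
                cal = fitCalibration(std),
                ratio = fitBandRatioModel(std),
                shift = fitPeakShiftModel(std))
        }
        cache
    }
})

test_that("the band-ratio analysis hits the pure-phase limits", {
    fx <- altFixtures()
    expect_equal(comContent(bandRatioQuant(cleanMixture(1, fx$cfg),
                                           fx$ratio)), 100)
    expect_equal(comContent(bandRatioQuant(cleanMixture(0, fx$cfg),
                                           fx$ratio)), 0)
})

test_that("the band-ratio analysis recovers a 50/50 mixture", {
    fx <- altFixtures()
    r <- bandRatioQuant(cleanMixture(0.5, fx$cfg), fx$ratio)
    expect_lt(abs(comContent(r) - 50), 2)
})

test_that("a missing 910 band with a clear 780 peak reads as pure COM", {
    fx <- altFixtures()
    model <- fx$ratio
    model@noiseFloor <- 0.02            # force the absent-band path
    r <- bandRatioQuant(cleanMixture(1, fx$cfg), model)
    expect_equal(comContent(r), 100)
    expect_true("no COD band" %in% resultFlags(r))
})

test_that("the peak-shift analysis tracks the C-O apex", {
    fx <- altFixtures()
    ## pure phases: apex at the configured band centers
    expect_equal(CaOxQuant:::.apexPosition(cleanMixture(1, fx$cfg),
                                           c(1290, 1350)), 1316,
                 tolerance = 0.2)
    expect_equal(CaOxQuant:::.apexPosition(cleanMixture(0, fx$cfg),
                                           c(1290, 1350)), 1328,
                 tolerance = 0.2)
    ## endpoints recover (near-)pure compositions through the linear map
    expect_gt(comContent(peakShiftQuant(cleanMixture(1, fx$cfg),
                                        fx$shift)), 97.5)
    expect_lt(comContent(peakShiftQuant(cleanMixture(0, fx$cfg),
                                        fx$shift)), 2.5)
    ## 50/50: apex strictly between the centers, recovery within 5 wt%
    apx <- CaOxQuant:::.apexPosition(cleanMixture(0.5, fx$cfg),
                                     c(1290, 1350))
    expect_gt(apx, 1316); expect_lt(apx, 1328)
    expect_lt(abs(comContent(peakShiftQuant(cleanMixture(0.5, fx$cfg),
                                            fx$shift)) - 50), 5)
    ## no interior maximum -> rejection
    flat <- Spectrum(600:4000, rep(1, 3401))
    expect_error(peakShiftQuant(flat, fx$shift), "interior maximum")
})

test_that("all three analyses agree on clean mixtures", {
    fx <- altFixtures()
    for (w in c(0, 0.3, 0.5, 0.8, 1)) {
        tab <- compareMethods(cleanMixture(w, fx$cfg), fx$cal, fx$ratio,
                              fx$shift)
        expect_equal(nrow(tab), 3)
        expect_true(all(abs(tab$com_wt_pct - 100 * w) <= 10))
        expect_equal(tab$com_wt_pct + tab$cod_wt_pct, rep(100, 3))
    }
})

test_that("a pure COD spectrum reads 0% COM / 100% COD in the table", {
    fx <- altFixtures()
    tab <- compareMethods(cleanMixture(0, fx$cfg), fx$cal, fx$ratio,
                          fx$shift)
    a1 <- tab[tab$analysis == "analysis1 (780)", ]
    expect_lt(a1$com_wt_pct, 1)          # 0% at the printed precision
    expect_gt(a1$cod_wt_pct, 99)
})

test_that("the comparison table serializes in the method-by-phase layout", {
    fx <- altFixtures()
    tab <- compareMethods(cleanMixture(0.7, fx$cfg), fx$cal, fx$ratio,
                          fx$shift)
    f <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(tab, f, row.names = FALSE)
    back <- utils::read.csv(f)
    expect_identical(names(back)[1:3],
                     c("analysis", "com_wt_pct", "cod_wt_pct"))
    expect_equal(nrow(back), 3)
})

test_that("mixed instrument tags across models are refused", {
    fx <- altFixtures()
    other <- generatorConfig(noiseSD = 0, instrument = "other-box")
    shift2 <- fitPeakShiftModel(cleanStandards(other))
    expect_error(compareMethods(cleanMixture(0.5, fx$cfg), fx$cal,
                                fx$ratio, shift2), "mixed instrument")
    expect_error(bandRatioQuant(cleanMixture(0.5, other), fx$ratio),
                 "instrument mismatch")
})

test_that("interfering bands break the comparison methods but not the 780 analysis", {
    fx <- altFixtures()
    cfgI <- generatorConfig(noiseSD = 0,
                            interferentBands = defaultInterferentBands(),
                            interferentScale = 0.5)
    for (w in c(0.2, 0.5, 0.8)) {
        tab <- compareMethods(cleanMixture(w, cfgI), fx$cal, fx$ratio,
                              fx$shift)
        err <- abs(tab$com_wt_pct - 100 * w)
        expect_lt(err[1], 10)            # analysis 1 stays reliable
        expect_gt(max(err[2:3]), err[1]) # the others drift further
        expect_gt(max(err[2:3]), 10)
    }
})
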