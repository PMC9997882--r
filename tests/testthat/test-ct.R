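test_that("a noiseless disc segments exactly", {
    ph <- makeCTPhantom(size = 96, fraction = 1, noiseSD = 0,
                        blurSigma = 0, seed = 1)
    mask <- segmentStone(ph$image)
    truthMask <- ph$truth != phaseLevels()[["background"]]
    expect_true(all(mask == truthMask))
    expect_true(is.numeric(attr(mask, "threshold")))
})

test_that("segmentation survives noise at 5% of the contrast gap", {
    for (seed in 1:5) {
        ph <- makeCTPhantom(size = 96, fraction = 0.7,
                            noiseSD = 0.05 * (0.6 - 0.05),
                            blurSigma = 1, seed = seed)
        mask <- segmentStone(ph$image)
        truthMask <- ph$truth != phaseLevels()[["background"]]
        dice <- 2 * sum(mask & truthMask) / (sum(mask) + sum(truthMask))
        expect_gte(dice, 0.98)
    }
})

test_that("a blank image has no stone", {
    blank <- CTImage(matrix(0.05, 64, 64))
    expect_error(segmentStone(blank), "no stone found")
})

test_that("phase classification recovers an 80/20 mosaic", {
    ph <- makeCTPhantom(size = 256, fraction = 0.8, crystalSize = 8,
                        blurSigma = 1, noiseSD = 0, seed = 2)
    pm <- classifyPhases(ph$image)
    lev <- phaseLevels()
    ## accuracy over voxels given a phase call (the surface ring of
    ## partial-volume voxels is excluded from the map by design)
    called <- phaseLabels(pm) %in% c(lev[["COM"]], lev[["COD"]])
    acc <- mean(phaseLabels(pm)[called] == ph$truth[called])
    expect_gte(acc, 0.95)
    expect_gt(mean(called), 0.4)
    expect_false("no phase contrast" %in% resultFlags(pm))
})

test_that("a uniform stone is flagged as single-phase", {
    ph <- makeCTPhantom(size = 96, fraction = 1, noiseSD = 0.005,
                        blurSigma = 1, seed = 3)
    pm <- classifyPhases(ph$image)
    expect_true("no phase contrast" %in% resultFlags(pm))
    lev <- phaseLevels()
    lab <- phaseLabels(pm)[stoneMask(pm)]
    expect_true(all(lab %in% c(lev[["COM"]], lev[["void"]])))
})

test_that("sub-resolution crystals are flagged through to the phase map", {
    ph <- makeCTPhantom(size = 96, crystalSize = 1, blurSigma = 2,
                        seed = 4)
    pm <- classifyPhases(ph$image)
    expect_true("sub-resolution" %in% resultFlags(pm))
    roi <- roiFractions(pm, data.frame(x = 40, y = 40))
    expect_match(roi$flags, "sub-resolution")
})

test_that("classification is invariant to affine intensity rescaling", {
    ph <- makeCTPhantom(size = 128, fraction = 0.6, seed = 5)
    pm1 <- classifyPhases(ph$image)
    scaled <- CTImage(3.7 * ctValues(ph$image) + 11,
                      metadata = metadata(ph$image))
    pm2 <- classifyPhases(scaled)
    expect_identical(phaseLabels(pm1), phaseLabels(pm2))
})

test_that("fixed thresholds are honoured and validated", {
    ph <- makeCTPhantom(size = 96, fraction = 0.5, noiseSD = 0,
                        blurSigma = 0, seed = 6)
    mask <- segmentStone(ph$image)
    pm <- classifyPhases(ph$image, mask, mode = "fixed",
                         thresholds = c(void = 0.4, phase = 0.7))
    expect_equal(unname(pm@thresholds), c(0.4, 0.7))
    expect_error(classifyPhases(ph$image, mask, mode = "fixed",
                                thresholds = c(void = 0.8, phase = 0.7)),
                 "ordered")
    expect_error(classifyPhases(ph$image, mask, mode = "fixed"),
                 "thresholds")
})

test_that("ROI fractions count voxels correctly", {
    ## hand-built phase map: left half COM, right half COD
    lev <- phaseLevels()
    lab <- matrix(lev[["COM"]], 40, 40)
    lab[, 21:40] <- lev[["COD"]]
    msk <- matrix(TRUE, 40, 40)
    pm <- new("PhaseMap", labels = lab, mask = msk,
              thresholds = c(void = 0, phase = 0.5), voxelSize = 0.005)
    rois <- data.frame(x = c(5, 5, 16), y = c(5, 28, 16))
    out <- roiFractions(pm, rois)
    expect_equal(out$com_pct, c(100, 0, 50))
    expect_equal(out$n_com + out$n_cod, rep(100, 3))

    ## ROI outside the mask is undefined with a reason
    msk2 <- msk; msk2[1:15, 1:15] <- FALSE
    lab2 <- lab; lab2[1:15, 1:15] <- lev[["background"]]
    pm2 <- new("PhaseMap", labels = lab2, mask = msk2,
               thresholds = c(void = 0, phase = 0.5), voxelSize = 0.005)
    out2 <- roiFractions(pm2, data.frame(x = 1, y = 1, size = 10))
    expect_true(is.na(out2$com_pct))
    expect_match(out2$flags, "outside stone|no classified voxels")
})

test_that("an 80/20 phantom ROI reads 80/20 within 3 points", {
    ph <- makeCTPhantom(size = 256, fraction = 0.8, crystalSize = 8,
                        blurSigma = 1, noiseSD = 0, seed = 7)
    pm <- classifyPhases(ph$image)
    mf <- mapFractions(pm, step = 10)
    expect_lt(abs(mf$aggregate$com_pct - 80), 3)
})

test_that("map aggregate equals the phase-map voxel fraction exactly", {
    ph <- makeCTPhantom(size = 128, fraction = 0.6, seed = 8)
    pm <- classifyPhases(ph$image)
    mf <- mapFractions(pm)
    lev <- phaseLevels()
    nCom <- sum(phaseLabels(pm) == lev[["COM"]])
    nCod <- sum(phaseLabels(pm) == lev[["COD"]])
    expect_identical(mf$aggregate$com_pct, 100 * nCom / (nCom + nCod))
    expect_error(mapFractions(pm, step = 0), "at least one")
})

test_that("a two-half stone aggregates to 50 percent", {
    ## build values directly: left half COM level, right half COD level
    v <- matrix(0.05, 120, 120)
    ix <- matrix(seq_len(120), 120, 120)
    iy <- t(ix)
    disc <- (ix - 60.5)^2 + (iy - 60.5)^2 <= 50^2
    v[disc & iy <= 60] <- 0.80
    v[disc & iy > 60] <- 0.60
    img <- CTImage(v)
    pm <- classifyPhases(img)
    mf <- mapFractions(pm)
    expect_lt(abs(mf$aggregate$com_pct - 50), 1)
})

test_that("mosaic aggregates are unbiased across seeds", {
    err <- vapply(1:10, function(seed) {
        ph <- makeCTPhantom(size = 128, fraction = 0.65, crystalSize = 8,
                            blurSigma = 1, noiseSD = 0.005, seed = seed)
        pm <- classifyPhases(ph$image)
        mapFractions(pm)$aggregate$com_pct / 100 - 0.65
    }, 0)
    expect_lt(abs(mean(err)), 0.02)
})
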