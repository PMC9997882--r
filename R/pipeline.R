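## Orchestration layer: reproducible simulate -> calibrate -> quantify
## runs driven by a generator config and a seed.  Every artefact is
## listed in a manifest with its ground truth, so downstream stages never
## guess.

#' Simulate a full fixture directory
#'
#' Writes calibration-standard and mixture-sample FTIR spectra (CSV), a
#' CT phantom (16-bit TIFF plus truth-label TIFF), and pure/mixed PXRD
#' patterns (CSV), together with a \code{manifest.json} listing every
#' file with its class, ground truth and seed.  Identical config and seed
#' reproduce every artefact byte for byte.
#'
#' @param outDir output directory (created if needed).
#' @param config a [generatorConfig()].
#' @param levels calibration levels (COM weight fractions).
#' @param nReps replicates per level.
#' @param sampleWcom COM weight fractions of the mixture "unknowns".
#' @param ctFraction COM fraction of the CT phantom.
#' @param ctSize CT phantom side length, voxels.
#' @param seed master seed; all stage seeds derive from it.
#' @return path of the manifest JSON, invisibly.
#' @export
runSimulate <- function(outDir, config = generatorConfig(),
                        levels = seq(0, 1, by = 0.1), nReps = 6,
                        sampleWcom = c(0.0, 0.3, 0.7, 1.0),
                        ctFraction = 0.8, ctSize = 256,
                        seed = 1) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seeds <- .withSeed(seed, sample.int(.Machine$integer.max, 4))
    entries <- list()
    add <- function(file, class, truth, s)
        entries[[length(entries) + 1L]] <<- list(
            file = file, class = class, truth = truth, seed = s)

    std <- makeCalibrationSet(levels, nReps, config, seed = seeds[1])
    for (i in seq_along(std)) {
        md <- metadata(std[[i]])
        f <- sprintf("standard_w%03d_rep%d.csv",
                     round(100 * md$level), md$replicate)
        writeSpectrum(std[[i]], file.path(outDir, f))
        add(f, "ftir-standard", md$truth, md$seed)
    }
    sseeds <- .withSeed(seeds[2],
                        sample.int(.Machine$integer.max,
                                   length(sampleWcom)))
    for (i in seq_along(sampleWcom)) {
        s <- makeMixtureSpectrum(sampleWcom[i], config, seed = sseeds[i])
        f <- sprintf("sample_w%03d.csv", round(100 * sampleWcom[i]))
        writeSpectrum(s, file.path(outDir, f))
        add(f, "ftir-sample", metadata(s)$truth, sseeds[i])
    }
    ph <- makeCTPhantom(size = ctSize, fraction = ctFraction,
                        seed = seeds[3])
    writeCTImage(ph$image, file.path(outDir, "ct_phantom.tif"))
    truthImg <- CTImage(ph$truth / max(phaseLevels()),
                        voxelSize = voxelSize(ph$image))
    writeCTImage(truthImg, file.path(outDir, "ct_phantom_truth.tif"))
    add("ct_phantom.tif", "ct-slice",
        metadata(ph$image)[c("targetFraction", "achievedFraction",
                             "crystalSize", "blurSigma")],
        seeds[3])

    pseeds <- .withSeed(seeds[4], sample.int(.Machine$integer.max, 3))
    pat <- list(
        pxrd_com = makePXRDPattern("COM", seed = pseeds[1]),
        pxrd_cod = makePXRDPattern("COD", seed = pseeds[2]),
        pxrd_mix = makePXRDPattern(c("COM", "COD"), c(0.5, 0.5),
                                   seed = pseeds[3]))
    for (nm in names(pat)) {
        f <- paste0(nm, ".csv")
        writePXRD(pat[[nm]], file.path(outDir, f))
        add(f, "pxrd", metadata(pat[[nm]])$truth, metadata(pat[[nm]])$seed)
    }

    manifest <- list(
        created = "CaOxQuant::runSimulate", seed = seed,
        instrument = config$instrument,
        n_entries = length(entries), entries = entries)
    mpath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(mpath)
}

.readManifest <- function(dir) {
    mpath <- file.path(dir, "manifest.json")
    if (!file.exists(mpath)) stop("no manifest.json in ", dir)
    jsonlite::read_json(mpath)
}

#' Calibrate all three FTIR analyses from a simulated standards directory
#'
#' Reads the manifest written by [runSimulate()], measures every
#' \code{ftir-standard} spectrum, fits the 780 cm^-1 two-branch
#' calibration, the 910/780 band-ratio model and the 1324 cm^-1
#' peak-shift model, and (optionally) writes the 780-calibration JSON.
#' Standards carrying mixed instrument tags are refused.
#'
#' @param dir fixture directory with \code{manifest.json}.
#' @param out optional path for the calibration JSON.
#' @return list with \code{cal} ([CalibrationModel-class]),
#'   \code{ratioModel}, \code{shiftModel}.
#' @export
runCalibrate <- function(dir, out = NULL) {
    manifest <- .readManifest(dir)
    ent <- Filter(function(e) e$class == "ftir-standard",
                  manifest$entries)
    if (length(ent) < 3L) stop("fewer than 3 standard spectra in manifest")
    spectra <- lapply(ent, function(e)
        subtractAtmosphere(readSpectrum(file.path(dir, e$file))))
    tags <- unique(vapply(spectra, function(s)
        metadata(s)$instrument %||% "unknown", ""))
    if (length(tags) > 1L)
        stop("standards carry mixed instrument tags: ",
             paste(tags, collapse = ", "))
    cal <- fitCalibration(spectra, seed = manifest$seed %||% NA)
    if (!is.null(out)) writeCalibration(cal, out)
    list(cal = cal,
         ratioModel = fitBandRatioModel(spectra),
         shiftModel = fitPeakShiftModel(spectra))
}

#' Quantify the simulated unknowns of a fixture directory
#'
#' Routes every manifest entry by class: FTIR samples go through all
#' three analyses ([compareMethods()]); the CT slice is segmented,
#' classified and tiled ([mapFractions()]); PXRD patterns get phase
#' calls ([identifyPattern()]).
#'
#' @param dir fixture directory with \code{manifest.json}.
#' @param models list from [runCalibrate()].
#' @param outCsv optional path for the FTIR comparison table CSV.
#' @return list with \code{ftir} (comparison data.frame, one block per
#'   sample with its true composition), \code{ct} (the [mapFractions()]
#'   result), \code{pxrd} (phase-call data.frame).
#' @export
runQuantify <- function(dir, models, outCsv = NULL) {
    manifest <- .readManifest(dir)
    cls <- vapply(manifest$entries, `[[`, "", "class")

    ftir <- NULL
    for (e in manifest$entries[cls == "ftir-sample"]) {
        s <- readSpectrum(file.path(dir, e$file))
        s <- subtractAtmosphere(s)
        tab <- compareMethods(s, models$cal, models$ratioModel,
                              models$shiftModel)
        tab <- cbind(sample = e$file,
                     true_com_wt_pct = 100 * e$truth$w_com, tab)
        ftir <- rbind(ftir, tab)
    }
    if (!is.null(outCsv) && !is.null(ftir))
        utils::write.csv(ftir, outCsv, row.names = FALSE)

    ct <- NULL
    ctEnt <- manifest$entries[cls == "ct-slice"]
    if (length(ctEnt)) {
        img <- readCTImage(file.path(dir, ctEnt[[1L]]$file))
        pm <- classifyPhases(img)
        ct <- mapFractions(pm)
        ct$truth <- ctEnt[[1L]]$truth
    }

    pxrd <- NULL
    for (e in manifest$entries[cls == "pxrd"]) {
        p <- readPXRD(file.path(dir, e$file))
        calls <- identifyPattern(p)
        calls <- cbind(pattern = e$file, calls,
                       truth = paste(unlist(e$truth$phases),
                                     collapse = "+"))
        pxrd <- rbind(pxrd, calls)
    }
    list(ftir = ftir, ct = ct, pxrd = pxrd)
}
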