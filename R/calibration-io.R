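#' Serialize / restore a calibration model as JSON
#'
#' Coefficients, diagnostics, instrument tag, spectral mode and creation
#' seed round-trip losslessly.
#'
#' @param cal a [CalibrationModel-class].
#' @param path JSON file path.
#' @return \code{path} invisibly ([writeCalibration()]); a
#'   [CalibrationModel-class] ([readCalibration()]).
#' @export
writeCalibration <- function(cal, path) {
    stopifnot(is(cal, "CalibrationModel"))
    obj <- list(type = "CaOxQuant-calibration", version = 1L,
                minor = as.list(cal@minor), major = as.list(cal@major),
                diagnostics = cal@diagnostics,
                instrument = cal@instrument, mode = cal@mode,
                seed = cal@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "CaOxQuant-calibration"))
        stop("not a calibration JSON file")
    num <- function(x) {
        v <- unlist(x)
        vapply(v, function(e) if (is.null(e) || is.na(e)) NA_real_
               else as.numeric(e), 0)
    }
    fixDiag <- function(d) {
        d$r.squared <- if (is.null(d$r.squared)) NA_real_
                       else as.numeric(d$r.squared)
        d$sigma <- if (is.null(d$sigma)) NA_real_ else as.numeric(d$sigma)
        d$usable <- isTRUE(d$usable)
        d
    }
    new("CalibrationModel",
        minor = num(obj$minor), major = num(obj$major),
        diagnostics = lapply(obj$diagnostics, fixDiag),
        instrument = obj$instrument, mode = obj$mode,
        seed = if (is.null(obj$seed) || is.na(obj$seed)) NA_integer_
               else as.integer(obj$seed))
}
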