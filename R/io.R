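#' Write a spectrum as a two-column CSV with a metadata header
#'
#' Header lines are \code{# key=value}; scalar metadata entries (and the
#' mode) round-trip through [readSpectrum()].
#'
#' @param s a [Spectrum-class] (or [PXRDPattern-class] for
#'   [writePXRD()]).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(s, path) {
    stopifnot(is(s, "Spectrum"))
    md <- metadata(s)
    md$mode <- specMode(s)
    .writeTwoColumn(wavenumbers(s), intensities(s),
                    c("wavenumber", "intensity"), md, path)
}

#' @rdname writeSpectrum
#' @export
writePXRD <- function(s, path) {
    stopifnot(is(s, "PXRDPattern"))
    md <- metadata(s)
    md$radiation <- radiation(s)
    .writeTwoColumn(twoTheta(s), intensities(s),
                    c("two_theta", "intensity"), md, path)
}

.writeTwoColumn <- function(x, y, cols, md, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(md)) {
        v <- md[[nm]]
        if (is.atomic(v) && length(v) == 1L && !is.na(v))
            writeLines(sprintf("# %s=%s", nm, format(v, digits = 17)), con)
        else if (!is.null(v) && !is.atomic(v))
            writeLines(sprintf("# %s=%s", nm,
                               jsonlite::toJSON(v, auto_unbox = TRUE,
                                                digits = NA)), con)
    }
    writeLines(paste(cols, collapse = ","), con)
    writeLines(sprintf("%.17g,%.17g", x, y), con)
    invisible(path)
}

.readHeader <- function(lines) {
    hdr <- grep("^#", lines, value = TRUE)
    md <- list()
    for (h in hdr) {
        kv <- sub("^#\\s*", "", h)
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq < 0) next
        key <- substr(kv, 1, eq - 1)
        val <- substr(kv, eq + 1, nchar(kv))
        md[[key]] <- if (grepl("^[\\[{]", val))
            jsonlite::fromJSON(val) else type.convert(val, as.is = TRUE)
    }
    md
}

#' Read a spectrum from CSV or a minimal JCAMP-DX subset
#'
#' CSV: two numeric columns (wavenumber, intensity), optional \code{# key
#' = value} header lines, optional column-name line.  JCAMP-DX: the AFFN
#' \code{##XYDATA=(X++(Y..Y))} form with \code{##XUNITS=1/CM},
#' \code{##XFACTOR}/\code{##YFACTOR}, \code{##FIRSTX}/\code{##LASTX}/
#' \code{##NPOINTS}.  A descending axis is reversed; without a declared
#' mode the spectrum defaults to absorbance with a warning.
#'
#' @param path input file.
#' @param format \code{"auto"} (by content), \code{"csv"} or
#'   \code{"jcamp"}.
#' @return a [Spectrum-class] with ascending wavenumbers.
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "jcamp")) {
    format <- match.arg(format)
    lines <- readLines(path, warn = FALSE)
    if (format == "auto")
        format <- if (any(grepl("^##", lines[seq_len(min(5, length(lines)))])))
            "jcamp" else "csv"
    if (format == "jcamp") return(.readJcamp(lines))
    md <- .readHeader(lines)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(body) && grepl("[A-Za-z]", body[1L])) body <- body[-1L]
    parts <- strsplit(body, "[,;\t ]+")
    x <- as.numeric(vapply(parts, `[`, "", 1L))
    y <- as.numeric(vapply(parts, `[`, "", 2L))
    if (anyNA(x) || anyNA(y)) stop("could not parse two numeric columns")
    if (!is.null(md$radiation))
        return(PXRDPattern(x, y, radiation = md$radiation,
                           metadata = md[names(md) != "radiation"]))
    mode <- md$mode
    md$mode <- NULL
    if (is.null(mode)) {
        warning("no mode declared; defaulting to absorbance")
        mode <- "absorbance"
    }
    ord <- order(x)
    dup <- duplicated(x[ord])
    x <- x[ord][!dup]; y <- y[ord][!dup]
    if (any(diff(x) <= 0)) stop("non-monotonic wavenumber axis")
    Spectrum(x, y, mode = mode, metadata = md)
}

#' @rdname readSpectrum
#' @export
readPXRD <- function(path) {
    p <- readSpectrum(path)
    if (!is(p, "PXRDPattern"))
        stop("file does not carry a radiation tag; not a PXRD pattern")
    p
}

.jcampField <- function(lines, key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^##", key, "=\\s*"), "", hit[1L])
}

.readJcamp <- function(lines) {
    xunits <- .jcampField(lines, "XUNITS")
    if (!is.null(xunits) && !grepl("1/CM", xunits, ignore.case = TRUE))
        stop("only XUNITS=1/CM JCAMP-DX files are supported")
    xf <- as.numeric(.jcampField(lines, "XFACTOR") %||% "1")
    yf <- as.numeric(.jcampField(lines, "YFACTOR") %||% "1")
    firstx <- as.numeric(.jcampField(lines, "FIRSTX"))
    lastx <- as.numeric(.jcampField(lines, "LASTX"))
    npoints <- as.integer(.jcampField(lines, "NPOINTS"))
    yunits <- toupper(.jcampField(lines, "YUNITS") %||% "")
    mode <- if (grepl("REFLECT", yunits)) "reflectance" else "absorbance"
    start <- grep("^##XYDATA=", lines)
    if (!length(start)) stop("no ##XYDATA block found")
    form <- sub("^##XYDATA=\\s*", "", lines[start[1L]])
    if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
        stop("only XYDATA=(X++(Y..Y)) is supported")
    end <- grep("^##END", lines)
    end <- if (length(end)) end[end > start][1L] else length(lines) + 1L
    body <- lines[(start + 1L):(end - 1L)]
    ys <- lapply(strsplit(trimws(body), "[ \t]+"), function(v)
        as.numeric(v[-1L]))                     # first token per line is X
    y <- unlist(ys) * yf
    if (is.na(firstx) || is.na(lastx))
        stop("FIRSTX/LASTX required")
    n <- if (!is.na(npoints)) npoints else length(y)
    if (length(y) != n)
        stop(sprintf("NPOINTS=%d but %d y-values read", n, length(y)))
    x <- seq(firstx * xf, lastx * xf, length.out = n)
    if (x[1L] > x[n]) { x <- rev(x); y <- rev(y) }
    Spectrum(x, y, mode = mode,
             metadata = list(source = "jcamp-dx"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a CT slice as a 16-bit grayscale TIFF
#'
#' Attenuation values are affinely mapped to the 16-bit range; the scale
#' and offset are not stored in the TIFF, so absolute CT units do not
#' round-trip — only their ordering and ratios of differences do, which
#' is all the histogram-shape-based classification needs.
#'
#' @param img a [CTImage-class].
#' @param path TIFF file path.
#' @param lo,hi value range mapped to [0, 1] on writing.
#' @return \code{path} ([writeCTImage()]) or a [CTImage-class]
#'   ([readCTImage()]).
#' @export
writeCTImage <- function(img, path, lo = 0, hi = 1) {
    stopifnot(is(img, "CTImage"))
    v <- (ctValues(img) - lo) / (hi - lo)
    v[v < 0] <- 0; v[v > 1] <- 1
    EBImage::writeImage(EBImage::Image(v), path, type = "tiff",
                        bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeCTImage
#' @param voxelSize voxel size (mm) to attach on reading.
#' @export
readCTImage <- function(path, voxelSize = 0.005) {
    v <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(v)) > 2L) v <- v[, , 1L]
    CTImage(as.matrix(v), voxelSize = voxelSize,
            metadata = list(source = path))
}
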