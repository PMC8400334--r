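## ENVI raster I/O: a flat binary raster plus a plain-text .hdr companion.
## Supported interleaves: BIL (native to push-broom line cameras, the
## default), BIP and BSQ. Supported data types follow the ENVI codes.

.ENVI_DTYPES <- data.frame(
    code = c(1L, 2L, 3L, 4L, 5L, 12L),
    name = c("uint8", "int16", "int32", "float32", "float64", "uint16"),
    size = c(1L, 2L, 4L, 4L, 8L, 2L),
    stringsAsFactors = FALSE)

.dtypeByName <- function(name) {
    i <- match(name, .ENVI_DTYPES$name)
    if (is.na(i)) stop("unsupported data type: ", name)
    .ENVI_DTYPES[i, ]
}

.dtypeByCode <- function(code) {
    i <- match(code, .ENVI_DTYPES$code)
    if (is.na(i)) stop("unsupported ENVI data type code: ", code)
    .ENVI_DTYPES[i, ]
}

.headerPath <- function(path) {
    if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
}

.rasterPath <- function(path) {
    if (grepl("\\.hdr$", path)) sub("\\.hdr$", "", path) else path
}

# Parse an ENVI header into a named list; brace-delimited values (which may
# span lines) are returned as character vectors split on commas.
.readENVIHeader <- function(hdrPath) {
    if (!file.exists(hdrPath))
        stop("ENVI header not found: ", hdrPath)
    txt <- readLines(hdrPath, warn = FALSE)
    if (length(txt) == 0L || !grepl("^ENVI", txt[1L]))
        stop("not an ENVI header (missing ENVI magic): ", hdrPath)
    body <- paste(txt[-1L], collapse = "\n")
    out <- list()
    # key = { multi, line, value } | key = value
    pat <- "([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
    m <- gregexpr(pat, body, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(out)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
        item <- substr(body, starts[k], starts[k] + lens[k] - 1L)
        eq <- regexpr("=", item, fixed = TRUE)
        key <- tolower(trimws(substr(item, 1L, eq - 1L)))
        val <- trimws(substr(item, eq + 1L, nchar(item)))
        if (startsWith(val, "{")) {
            val <- gsub("^\\{|\\}$", "", val)
            val <- trimws(strsplit(val, ",")[[1L]])
        }
        out[[key]] <- val
    }
    out
}

.readRaster <- function(rasterPath, hdr) {
    samples <- as.integer(hdr$samples)
    lines <- as.integer(hdr$lines)
    bands <- as.integer(hdr$bands)
    if (anyNA(c(samples, lines, bands)))
        stop("ENVI header lacks samples/lines/bands")
    dt <- .dtypeByCode(as.integer(hdr[["data type"]]))
    interleave <- tolower(hdr$interleave %||% "bil")
    if (!interleave %in% c("bil", "bip", "bsq"))
        stop("unsupported interleave: ", interleave)
    n <- samples * lines * bands
    endian <- if (identical(hdr[["byte order"]], "1")) "big" else "little"
    con <- file(rasterPath, "rb")
    on.exit(close(con))
    offset <- as.integer(hdr[["header offset"]] %||% "0")
    if (offset > 0L) seek(con, offset)
    raw <- switch(dt$name,
        uint8 = readBin(con, integer(), n, size = 1L, signed = FALSE,
            endian = endian),
        int16 = readBin(con, integer(), n, size = 2L, signed = TRUE,
            endian = endian),
        uint16 = readBin(con, integer(), n, size = 2L, signed = FALSE,
            endian = endian),
        int32 = readBin(con, integer(), n, size = 4L, endian = endian),
        float32 = readBin(con, double(), n, size = 4L, endian = endian),
        float64 = readBin(con, double(), n, size = 8L, endian = endian))
    if (length(raw) != n)
        stop("raster truncated: expected ", n, " values, read ", length(raw))
    arr <- switch(interleave,
        bil = aperm(array(raw, c(samples, bands, lines)), c(3L, 1L, 2L)),
        bip = aperm(array(raw, c(bands, samples, lines)), c(3L, 2L, 1L)),
        bsq = aperm(array(raw, c(samples, lines, bands)), c(2L, 1L, 3L)))
    storage.mode(arr) <- "double"
    arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ENVI-format hypercube
#'
#' Reads the flat binary raster named by \code{path} together with its
#' \code{.hdr} companion. All three interleaves (BIL, BIP, BSQ) and ENVI
#' data types 1, 2, 3, 4, 5 and 12 are accepted; band order is preserved
#' and per-band wavelengths are taken from the header.
#'
#' @param path raster file path (or the \code{.hdr} path).
#' @return a [HyperCube-class]
#' @seealso [writeENVI()], [readENVIFrame()]
#' @export
readENVI <- function(path) {
    hdrPath <- .headerPath(path)
    hdr <- .readENVIHeader(hdrPath)
    rasterPath <- .rasterPath(path)
    if (!file.exists(rasterPath))
        stop("ENVI raster not found: ", rasterPath)
    arr <- .readRaster(rasterPath, hdr)
    wl <- suppressWarnings(as.numeric(hdr$wavelength))
    if (is.null(hdr$wavelength) || anyNA(wl))
        stop("ENVI header lacks a parseable wavelength block")
    if (length(wl) != dim(arr)[3L])
        stop("header declares ", length(wl), " wavelengths but raster has ",
            dim(arr)[3L], " bands")
    meta <- list()
    if (!is.null(hdr[["line rate"]]))
        meta$lineRate <- as.numeric(hdr[["line rate"]])
    HyperCube(arr, wl, meta = meta)
}

.writeRaster <- function(arr, rasterPath, interleave, dt) {
    vec <- switch(interleave,
        bil = as.vector(aperm(arr, c(2L, 3L, 1L))),
        bip = as.vector(aperm(arr, c(3L, 2L, 1L))),
        bsq = as.vector(aperm(arr, c(2L, 1L, 3L))))
    con <- file(rasterPath, "wb")
    on.exit(close(con))
    if (dt$name %in% c("float32", "float64")) {
        writeBin(as.double(vec), con, size = dt$size, endian = "little")
    } else {
        writeBin(as.integer(round(vec)), con, size = dt$size,
            endian = "little")
    }
    invisible(rasterPath)
}

.autoDtype <- function(arr) {
    if (all(arr == round(arr)) && max(arr) <= 65535 && min(arr) >= 0)
        "uint16" else "float64"
}

#' Write a cube as an ENVI raster
#'
#' Writes a binary raster plus \code{.hdr} companion recording dimensions,
#' interleave, data type and wavelengths; the pair round-trips bit-exactly
#' through [readENVI()] for integer data and 64-bit floats.
#'
#' @param cube a [SpectralCube-class]
#' @param path raster file path to create (header at \code{<path>.hdr}).
#' @param interleave \code{"bil"} (default, native to line cameras),
#'   \code{"bip"} or \code{"bsq"}.
#' @param dtype \code{"auto"} (unsigned 16-bit for integer DN, 64-bit float
#'   otherwise) or one of \code{uint8, int16, int32, float32, float64,
#'   uint16}.
#' @return \code{path}, invisibly
#' @export
writeENVI <- function(cube, path, interleave = c("bil", "bip", "bsq"),
                      dtype = "auto") {
    interleave <- match.arg(interleave)
    validObject(cube)
    arr <- cube@data
    if (identical(dtype, "auto")) dtype <- .autoDtype(arr)
    dt <- .dtypeByName(dtype)
    dirp <- dirname(path)
    if (!dir.exists(dirp))
        stop("directory does not exist: ", dirp)
    .writeRaster(arr, path, interleave, dt)
    d <- dim(arr)
    hdr <- c("ENVI",
        "file type = ENVI Standard",
        paste0("samples = ", d[2L]),
        paste0("lines = ", d[1L]),
        paste0("bands = ", d[3L]),
        "header offset = 0",
        paste0("data type = ", dt$code),
        paste0("interleave = ", interleave),
        "byte order = 0",
        "wavelength units = Nanometers",
        paste0("wavelength = {",
            paste(format(cube@wavelengths, trim = TRUE, digits = 15),
                collapse = ", "), "}"))
    if (!is.null(cube@meta$lineRate))
        hdr <- c(hdr, paste0("line rate = ", cube@meta$lineRate))
    writeLines(hdr, .headerPath(path))
    invisible(path)
}

#' Read or write a calibration reference frame as a single-line ENVI raster
#'
#' @param path raster path
#' @param kind \code{"dark_current"} or \code{"white_reference"}
#' @return \code{readENVIFrame}: a [ReferenceFrame-class]
#' @export
readENVIFrame <- function(path, kind = c("dark_current",
                                         "white_reference")) {
    kind <- match.arg(kind)
    cube <- readENVI(path)
    if (nLines(cube) != 1L)
        stop("reference frame rasters must have exactly 1 line")
    ReferenceFrame(cube@data[1L, , , drop = TRUE], kind = kind)
}

#' @rdname readENVIFrame
#' @param frame a [ReferenceFrame-class]
#' @param wavelengths band-center wavelengths for the header
#' @export
writeENVIFrame <- function(frame, path, wavelengths) {
    v <- frame@values
    arr <- array(v, c(1L, nrow(v), ncol(v)))
    writeENVI(HyperCube(arr, wavelengths), path)
}
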