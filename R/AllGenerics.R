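#' Accessors for spectral cubes
#'
#' \code{cubeData} returns the raw 3-D array (line, sample, band);
#' \code{wavelengths} the band-center wavelengths in nm; \code{nLines},
#' \code{nSamples} and \code{nBands} the axis extents; \code{lineSlice}
#' one acquisition line as a (samples x bands) matrix, supporting the
#' streaming contract of the detector.
#'
#' @param x a [SpectralCube-class]
#' @param i line index (1-based, acquisition order)
#' @return see description
#' @name cube-accessors
#' @examples
#' cube <- HyperCube(array(1, c(2, 3, 4)), wavelengths = c(400, 600, 800, 1000))
#' nBands(cube)
#' dim(lineSlice(cube, 1))
NULL

#' @rdname cube-accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname cube-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname cube-accessors
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @rdname cube-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname cube-accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname cube-accessors
#' @export
setGeneric("lineSlice", function(x, i) standardGeneric("lineSlice"))

#' @rdname cube-accessors
#' @export
setMethod("cubeData", "SpectralCube", function(x) x@data)

#' @rdname cube-accessors
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @rdname cube-accessors
#' @export
setMethod("nLines", "SpectralCube", function(x) dim(x@data)[1L])

#' @rdname cube-accessors
#' @export
setMethod("nSamples", "SpectralCube", function(x) dim(x@data)[2L])

#' @rdname cube-accessors
#' @export
setMethod("nBands", "SpectralCube", function(x) dim(x@data)[3L])

#' @rdname cube-accessors
#' @export
setMethod("lineSlice", "SpectralCube", function(x, i) {
    stopifnot(length(i) == 1L, i >= 1L, i <= nLines(x))
    x@data[i, , , drop = TRUE]
})

#' Spectral binning by band decimation
#'
#' Keeps every \code{n}-th band starting at the first (phase 1), discarding
#' the rest: decimation, not averaging. This halves (n = 2) or quarters
#' (n = 4) the data stream while preserving band positions, e.g. 224 bands
#' become 112 or 56. The band count must be divisible by \code{n}.
#'
#' @param x a [HyperCube-class] or [CalibratedCube-class]
#' @param n decimation factor: 1, 2 or 4
#' @param phase index of the band kept within each group of \code{n}
#'   (default 1, i.e. the first; available for sensitivity checks)
#' @return an object of the same class with \code{nBands(x) / n} bands
#' @export
setGeneric("spectralBin", function(x, n, phase = 1L)
    standardGeneric("spectralBin"))

setMethod("show", "SpectralCube", function(object) {
    d <- dim(object@data)
    cat(class(object), ": ", d[1L], " lines x ", d[2L], " samples x ",
        d[3L], " bands\n", sep = "")
    wl <- object@wavelengths
    cat(sprintf("  wavelengths: %.2f-%.2f nm\n", min(wl), max(wl)))
    if (is(object, "CalibratedCube"))
        cat("  method: ", object@method, " (binning 1/",
            object@binning, ")\n", sep = "")
    invisible(object)
})

setMethod("show", "ReferenceProfile", function(object) {
    cat("ReferenceProfile '", object@className, "': ",
        length(object@mu), " bands, n = ", object@nPixels, " pixels\n",
        sep = "")
    cat(sprintf("  envelope: [%.2f, %.2f] z (band-wise extremes)\n",
        min(object@envLow), max(object@envHigh)))
    invisible(object)
})

setMethod("show", "SubtractionConfig", function(object) {
    cat("SubtractionConfig\n")
    cat(sprintf("  visible pair: bands %d-%d; seaweed [%g, %g], belt [%g, %g]\n",
        object@visiblePair[1L], object@visiblePair[2L],
        object@visibleIntervals$seaweed[1L], object@visibleIntervals$seaweed[2L],
        object@visibleIntervals$belt[1L], object@visibleIntervals$belt[2L]))
    cat(sprintf("  NIR pair:     bands %d-%d; seaweed [%g, %g], belt [%g, %g]\n",
        object@nirPair[1L], object@nirPair[2L],
        object@nirIntervals$seaweed[1L], object@nirIntervals$seaweed[2L],
        object@nirIntervals$belt[1L], object@nirIntervals$belt[2L]))
    invisible(object)
})

setMethod("show", "SheetVerdict", function(object) {
    cat("SheetVerdict: ", toupper(object@decision), " (",
        object@foreignPixelCount, " foreign pixels in ",
        object@foreignComponents, " regions; stage 1: ",
        object@stage1Count, ", stage 2: ", object@stage2Count, ")\n",
        sep = "")
    invisible(object)
})

setMethod("show", "ClassMap", function(object) {
    tab <- table(factor(object@labels,
        levels = c("seaweed", "belt", "foreign")))
    cat("ClassMap ", nrow(object@labels), " x ", ncol(object@labels),
        ": ", paste(names(tab), tab, sep = "=", collapse = ", "),
        " (", sum(object@ignored), " ignored)\n", sep = "")
    invisible(object)
})
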