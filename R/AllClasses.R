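#' @import methods
NULL

# FX-10e sensor limits (maximum band count and spatial samples per line)
.FX10E_MAX_BANDS <- 224L
.FX10E_MAX_SAMPLES <- 1024L

#' SpectralCube: common raster model for hyperspectral line-scan data
#'
#' Virtual parent of [HyperCube-class] and [CalibratedCube-class]. The raster
#' is a 3-D array with axes (line, sample, band): one spatial line per camera
#' frame, the second spatial axis coming from conveyor motion.
#'
#' @slot data 3-D numeric array, dim = (lines, samples, bands).
#' @slot wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @slot meta list of acquisition descriptors (e.g. \code{lineRate} in
#'   lines/s, \code{bitDepth}).
#'
#' @name SpectralCube-class
#' @aliases SpectralCube
#' @exportClass SpectralCube
setClass("SpectralCube",
    representation("VIRTUAL",
        data = "array",
        wavelengths = "numeric",
        meta = "list"))

.validSpectralCube <- function(object) {
    msg <- NULL
    d <- object@data
    if (length(dim(d)) != 3L)
        msg <- c(msg, "'data' must be a 3-D array (line, sample, band)")
    else {
        if (length(object@wavelengths) != dim(d)[3L])
            msg <- c(msg, sprintf(
                "wavelength count (%d) does not match band axis (%d)",
                length(object@wavelengths), dim(d)[3L]))
    }
    if (length(object@wavelengths) > 1L &&
        any(diff(object@wavelengths) <= 0))
        msg <- c(msg, "'wavelengths' must be strictly increasing")
    if (is.null(msg)) TRUE else msg
}
setValidity("SpectralCube", .validSpectralCube)

#' HyperCube: raw digital-number hypercube
#'
#' Raw sensor counts (digital numbers, DN) straight off a push-broom VNIR
#' camera, before any calibration. DN values are non-negative; the band and
#' sample extents respect the FX-10e limits (at most 224 bands and 1024
#' spatial samples per line).
#'
#' @slot data,wavelengths,meta see [SpectralCube-class].
#'
#' @seealso [HyperCube()] constructor, [readENVI()], [perNorm()]
#' @name HyperCube-class
#' @aliases HyperCube-class
#' @exportClass HyperCube
setClass("HyperCube", contains = "SpectralCube")

setValidity("HyperCube", function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) == 3L) {
        if (d[3L] > .FX10E_MAX_BANDS)
            msg <- c(msg, sprintf("band count %d exceeds sensor maximum %d",
                d[3L], .FX10E_MAX_BANDS))
        if (d[2L] > .FX10E_MAX_SAMPLES)
            msg <- c(msg, sprintf("sample count %d exceeds sensor maximum %d",
                d[2L], .FX10E_MAX_SAMPLES))
    }
    if (any(object@data < 0))
        msg <- c(msg, "raw DN values must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' CalibratedCube: normalized hypercube
#'
#' A hypercube after dark-current removal and one of the three normalization
#' schemes. \code{method} is one of \code{"per_norm"} (per-pixel min-max to
#' \[0, 100\]), \code{"max_norm"} (per-pixel division by the maximum, scaled
#' to 100) or \code{"reflectance_norm"} (band-wise division by the
#' dark-corrected white reference). \code{binning} records the spectral
#' decimation factor applied (1, 2 or 4).
#'
#' @slot method character, the normalization scheme.
#' @slot binning integer decimation factor.
#' @slot degenerate logical matrix (lines x samples) flagging pixels whose
#'   spectrum was constant after dark removal (set to 0 and flagged).
#' @slot data,wavelengths,meta see [SpectralCube-class].
#'
#' @name CalibratedCube-class
#' @aliases CalibratedCube-class
#' @exportClass CalibratedCube
setClass("CalibratedCube", contains = "SpectralCube",
    representation(method = "character", binning = "integer",
        degenerate = "matrix"),
    prototype(method = "per_norm", binning = 1L,
        degenerate = matrix(logical(0), 0, 0)))

setValidity("CalibratedCube", function(object) {
    ok <- c("per_norm", "max_norm", "reflectance_norm")
    msg <- NULL
    if (length(object@method) != 1L || !object@method %in% ok)
        msg <- c(msg, sprintf("'method' must be one of: %s",
            paste(ok, collapse = ", ")))
    if (!object@binning %in% c(1L, 2L, 4L))
        msg <- c(msg, "'binning' must be 1, 2 or 4")
    if (is.null(msg)) TRUE else msg
})

#' ReferenceFrame: dark-current or white-reference calibration frame
#'
#' @slot kind \code{"dark_current"} or \code{"white_reference"}.
#' @slot values numeric matrix (samples x bands), or a per-band vector stored
#'   as a 1 x bands matrix when spatially constant.
#'
#' @name ReferenceFrame-class
#' @aliases ReferenceFrame-class
#' @exportClass ReferenceFrame
setClass("ReferenceFrame",
    representation(kind = "character", values = "matrix"))

setValidity("ReferenceFrame", function(object) {
    msg <- NULL
    if (!object@kind %in% c("dark_current", "white_reference"))
        msg <- c(msg, "'kind' must be 'dark_current' or 'white_reference'")
    if (any(object@values < 0))
        msg <- c(msg, "reference DN values must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' ReferenceProfile: per-class spectral reference statistics
#'
#' Band-wise mean and (population) standard deviation of a labeled reference
#' pixel set in Per-Norm units, plus the standardized envelope: the band-wise
#' minimum and maximum z-score observed over the reference set. The envelope
#' always brackets 0 because the mean pixel standardizes to the zero vector.
#'
#' @slot className \code{"seaweed"} or \code{"belt"}.
#' @slot mu,sigma numeric per-band mean and population sd (Per-Norm units).
#' @slot envLow,envHigh numeric per-band standardized envelope bounds
#'   (z units).
#' @slot nPixels integer, reference pixels used.
#' @slot wavelengths numeric, band-center nm (may be empty).
#'
#' @seealso [buildProfile()], [standardize()], [stage2Inspect()]
#' @name ReferenceProfile-class
#' @aliases ReferenceProfile-class
#' @exportClass ReferenceProfile
setClass("ReferenceProfile",
    representation(className = "character", mu = "numeric", sigma = "numeric",
        envLow = "numeric", envHigh = "numeric", nPixels = "integer",
        wavelengths = "numeric"))

setValidity("ReferenceProfile", function(object) {
    msg <- NULL
    n <- length(object@mu)
    if (length(object@sigma) != n || length(object@envLow) != n ||
        length(object@envHigh) != n)
        msg <- c(msg, "mu, sigma, envLow, envHigh must have equal length")
    if (any(object@sigma <= 0))
        msg <- c(msg, "sigma must be > 0 at every band")
    if (any(object@envLow > 0) || any(object@envHigh < 0))
        msg <- c(msg, "envelope must satisfy envLow <= 0 <= envHigh")
    if (is.null(msg)) TRUE else msg
})

.intervalsOverlap <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]

#' SubtractionConfig: band pairs and class intervals for stage-1 segmentation
#'
#' Two band pairs (one in the visible range, one in the near-infrared) and,
#' per range, the acceptance interval of the subtraction value for each of
#' the two background classes. Band indices are 1-based into the (binned)
#' cube, matching the "26th band" counting convention.
#'
#' @slot visiblePair,nirPair integer length-2 (low band, high band).
#' @slot visibleIntervals,nirIntervals named lists with elements
#'   \code{seaweed} and \code{belt}, each a numeric \code{c(lo, hi)} in
#'   Per-Norm difference units.
#' @slot visibleRangeNm,nirRangeNm numeric length-2 nm ranges.
#'
#' @seealso [subtractionConfig()], [defaultSubtractionConfig()],
#'   [stage1Classify()]
#' @name SubtractionConfig-class
#' @aliases SubtractionConfig-class
#' @exportClass SubtractionConfig
setClass("SubtractionConfig",
    representation(visiblePair = "integer", nirPair = "integer",
        visibleIntervals = "list", nirIntervals = "list",
        visibleRangeNm = "numeric", nirRangeNm = "numeric"))

setValidity("SubtractionConfig", function(object) {
    msg <- NULL
    for (nm in c("visiblePair", "nirPair")) {
        p <- slot(object, nm)
        if (length(p) != 2L || any(p < 1L))
            msg <- c(msg, sprintf("'%s' must be two positive band indices", nm))
    }
    for (nm in c("visibleIntervals", "nirIntervals")) {
        iv <- slot(object, nm)
        if (!all(c("seaweed", "belt") %in% names(iv)))
            msg <- c(msg, sprintf("'%s' needs 'seaweed' and 'belt'", nm))
        else {
            bad <- vapply(iv[c("seaweed", "belt")],
                function(x) length(x) != 2L || x[1L] > x[2L], logical(1))
            if (any(bad))
                msg <- c(msg, sprintf("'%s' intervals must be c(lo, hi)", nm))
            else if (.intervalsOverlap(iv$seaweed, iv$belt))
                msg <- c(msg, sprintf(
                    "class intervals overlap in '%s': classes not separable",
                    nm))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' DetectorParams: tunables of the two-stage detector
#'
#' @slot subtraction a [SubtractionConfig-class].
#' @slot margin numeric z-unit margin added to the standardized envelope at
#'   stage 2 (default 3).
#' @slot minForeignPixels integer; a sheet is rejected when at least this
#'   many pixels are flagged foreign (default 1).
#' @slot ignoredZoneMode \code{"none"} or \code{"outside_sheet_bbox"}.
#'
#' @seealso [detectorParams()], [detectSheet()]
#' @name DetectorParams-class
#' @aliases DetectorParams-class
#' @exportClass DetectorParams
setClass("DetectorParams",
    representation(subtraction = "SubtractionConfig", margin = "numeric",
        minForeignPixels = "integer", ignoredZoneMode = "character"))

setValidity("DetectorParams", function(object) {
    msg <- NULL
    if (object@margin < 0) msg <- c(msg, "'margin' must be >= 0")
    if (object@minForeignPixels < 1L)
        msg <- c(msg, "'minForeignPixels' must be >= 1")
    if (!object@ignoredZoneMode %in% c("none", "outside_sheet_bbox"))
        msg <- c(msg, "'ignoredZoneMode' must be 'none' or 'outside_sheet_bbox'")
    if (is.null(msg)) TRUE else msg
})

#' ClassMap: per-pixel classification result
#'
#' @slot labels character matrix (lines x samples) with values in
#'   \code{"seaweed"}, \code{"belt"}, \code{"foreign"}.
#' @slot ignored logical matrix; pixels skipped by stage-2 inspection.
#' @slot stage1Only logical matrix; TRUE where a foreign pixel was flagged
#'   at stage 1 (FALSE for stage-2 foreigns and all non-foreign pixels).
#'
#' @seealso [detectSheet()], [renderClassMap()]
#' @name ClassMap-class
#' @aliases ClassMap-class
#' @exportClass ClassMap
setClass("ClassMap",
    representation(labels = "matrix", ignored = "matrix",
        stage1Only = "matrix"))

setValidity("ClassMap", function(object) {
    msg <- NULL
    if (!all(object@labels %in% c("seaweed", "belt", "foreign")))
        msg <- c(msg, "labels must be seaweed/belt/foreign")
    if (!identical(dim(object@labels), dim(object@ignored)) ||
        !identical(dim(object@labels), dim(object@stage1Only)))
        msg <- c(msg, "labels, ignored, stage1Only must share dimensions")
    if (any(object@ignored & object@labels == "foreign" &
            !object@stage1Only))
        msg <- c(msg, "ignored pixels cannot be stage-2 foreign")
    if (is.null(msg)) TRUE else msg
})

#' SheetVerdict: sheet-level accept/reject decision
#'
#' @slot decision \code{"accept"} or \code{"reject"}.
#' @slot foreignPixelCount integer, total foreign-flagged pixels.
#' @slot foreignComponents integer, 4-connected foreign regions.
#' @slot stage1Count,stage2Count integer foreign pixels per stage.
#' @slot minForeignPixels integer threshold used for the decision.
#'
#' @name SheetVerdict-class
#' @aliases SheetVerdict-class
#' @exportClass SheetVerdict
setClass("SheetVerdict",
    representation(decision = "character", foreignPixelCount = "integer",
        foreignComponents = "integer", stage1Count = "integer",
        stage2Count = "integer", minForeignPixels = "integer"))

setValidity("SheetVerdict", function(object) {
    msg <- NULL
    if (!object@decision %in% c("accept", "reject"))
        msg <- c(msg, "'decision' must be 'accept' or 'reject'")
    want <- if (object@foreignPixelCount >= object@minForeignPixels)
        "reject" else "accept"
    if (object@decision != want)
        msg <- c(msg, "decision inconsistent with foreign pixel count")
    if (is.null(msg)) TRUE else msg
})

#' SamTrainingSet: labeled spectra for the SAM baseline
#'
#' @slot pixels numeric matrix (n x bands) of Per-Norm spectra.
#' @slot labels character vector of length n with values in
#'   \code{"seaweed"}, \code{"belt"}, \code{"foreign"}.
#'
#' @seealso [samTrainingSet()], [samClassify()]
#' @name SamTrainingSet-class
#' @aliases SamTrainingSet-class
#' @exportClass SamTrainingSet
setClass("SamTrainingSet",
    representation(pixels = "matrix", labels = "character"))

setValidity("SamTrainingSet", function(object) {
    msg <- NULL
    if (nrow(object@pixels) != length(object@labels))
        msg <- c(msg, "one label per training pixel required")
    if (nrow(object@pixels) < 1L)
        msg <- c(msg, "training set must be non-empty")
    if (any(sqrt(rowSums(object@pixels^2)) == 0))
        msg <- c(msg, "zero-norm training spectra are not allowed")
    if (is.null(msg)) TRUE else msg
})

#' SceneSpec: geometry and content of one synthetic conveyor scene
#'
#' @slot sheetShape \code{"rectangular"} (26 x 20 cm) or \code{"square"}
#'   (20 x 20 cm).
#' @slot beltSpeed conveyor speed, cm/s.
#' @slot lineRate camera line rate, lines/s.
#' @slot pixelPitchMm across-track sampling pitch, mm/sample.
#' @slot samples spatial samples per line.
#' @slot marginLines belt-only lines before and after the sheet.
#' @slot foreignObjects list of objects, each
#'   \code{list(material=, line=, sample=, height=, width=)} in sheet-relative
#'   pixel coordinates.
#' @slot seed integer RNG seed; a fixed seed yields a bit-identical scene.
#'
#' @seealso [sceneSpec()], [renderScene()], [makeBenchmark()]
#' @name SceneSpec-class
#' @aliases SceneSpec-class
#' @exportClass SceneSpec
setClass("SceneSpec",
    representation(sheetShape = "character", beltSpeed = "numeric",
        lineRate = "numeric", pixelPitchMm = "numeric", samples = "integer",
        marginLines = "integer", foreignObjects = "list", seed = "integer"))

setValidity("SceneSpec", function(object) {
    msg <- NULL
    if (!object@sheetShape %in% c("rectangular", "square"))
        msg <- c(msg, "'sheetShape' must be 'rectangular' or 'square'")
    if (object@beltSpeed <= 0 || object@lineRate <= 0 ||
        object@pixelPitchMm <= 0)
        msg <- c(msg, "beltSpeed, lineRate and pixelPitchMm must be > 0")
    if (object@samples < 1L) msg <- c(msg, "'samples' must be >= 1")
    if (is.null(msg)) TRUE else msg
})
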