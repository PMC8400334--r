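## Calibration: dark-current removal, the three normalization schemes and
## spectral binning by decimation.
##
## All three normalizations operate on dark-corrected spectra. Per-Norm and
## Max-Norm are per-pixel (each pixel's own min/max normalizes its spectrum),
## which is what cancels the large multiplicative offset between pixels of
## the same material; Reflectance-Norm divides band-wise by the
## dark-corrected white reference.

# Dark-correct a cube and return the 3-D array; negative counts are clamped
# to zero (sensor counts cannot be negative).
.darkCorrected <- function(cube, dark) {
    d <- dim(cube@data)
    D <- .frameMatrix(dark, d[2L], d[3L])
    arr <- cube@data - rep(D, each = d[1L])
    arr[arr < 0] <- 0
    arr
}

#' Remove dark current from a raw cube
#'
#' Subtracts the dark-current frame D (recorded with the lens capped) from
#' every line, clamping at zero. This removes the camera's fixed-pattern
#' offset before any normalization.
#'
#' @param cube a [HyperCube-class]
#' @param dark a dark-current [ReferenceFrame-class] (samples x bands
#'   matrix or per-band vector)
#' @return a [HyperCube-class] with DN' = max(DN - D, 0)
#' @export
subtractDark <- function(cube, dark) {
    HyperCube(.darkCorrected(cube, dark), cube@wavelengths, cube@meta)
}

# Shared per-pixel normalization core. `denomFun` maps (pixel matrix of
# dark-corrected spectra) to per-pixel (numerator offset, denominator).
.perPixelNorm <- function(cube, dark, method) {
    arr <- .darkCorrected(cube, dark)
    d <- dim(arr)
    flat <- matrix(arr, nrow = d[1L] * d[2L], ncol = d[3L])
    mx <- do.call(pmax, as.data.frame(flat))
    mn <- do.call(pmin, as.data.frame(flat))
    if (method == "per_norm") {
        denom <- mx - mn
        off <- mn
    } else { # max_norm
        denom <- mx
        off <- 0
    }
    degen <- denom <= 0
    if (any(degen)) {
        warning(sum(degen), " degenerate pixel(s) (constant spectrum after ",
            "dark removal); values set to 0")
        denom[degen] <- 1
    }
    out <- (flat - off) / denom * 100
    out[degen, ] <- 0
    new("CalibratedCube",
        data = array(out, d), wavelengths = cube@wavelengths,
        meta = cube@meta, method = method,
        binning = as.integer(cube@meta$binning %||% 1L),
        degenerate = matrix(degen, d[1L], d[2L]))
}

#' Per-Norm: per-pixel percent normalization
#'
#' After dark removal, each pixel spectrum is min-max scaled to \[0, 100\]:
#' \deqn{Pn_b = 100 (r'_b - r'_{min}) / (r'_{max} - r'_{min})}
#' with the min/max taken over that pixel's own bands. Every spectrum's
#' maximum band maps to 100 and its minimum to 0, which suppresses the
#' brightness offset between pixels while keeping the spectral shape; this
#' is the calibration the two-stage detector runs on.
#'
#' @param cube a [HyperCube-class]
#' @param dark dark-current [ReferenceFrame-class]
#' @return a [CalibratedCube-class] with \code{method = "per_norm"}.
#'   Pixels whose spectrum is constant after dark removal are flagged in
#'   the \code{degenerate} slot, set to 0, and a warning is issued.
#' @examples
#' cube <- HyperCube(array(c(10, 20, 30), c(1, 1, 3)),
#'                   wavelengths = c(400, 700, 1000))
#' dark <- ReferenceFrame(rep(0, 3))
#' cubeData(perNorm(cube, dark))[1, 1, ]   # 0 50 100
#' @export
perNorm <- function(cube, dark) .perPixelNorm(cube, dark, "per_norm")

#' Max-Norm: per-pixel division by the spectrum maximum
#'
#' After dark removal each pixel spectrum is divided by its own maximum and
#' scaled by 100: \eqn{Mn_b = 100 (r_b - D) / (r_{max} - D)}. The maximum
#' band maps to 100; other bands keep their ratio to it.
#'
#' @inheritParams perNorm
#' @return a [CalibratedCube-class] with \code{method = "max_norm"}
#' @export
maxNorm <- function(cube, dark) .perPixelNorm(cube, dark, "max_norm")

#' Reflectance-Norm: band-wise conversion to relative reflectance
#'
#' \eqn{Rn_b = (r_b - D_b) / (Wref_b - D_b)}: band-wise division of the
#' dark-corrected signal by the dark-corrected white reference. A pixel
#' identical to the white frame maps to 1 everywhere, one identical to the
#' dark frame to 0.
#'
#' @inheritParams perNorm
#' @param white white-reference [ReferenceFrame-class]; must exceed the
#'   dark frame at every (sample, band)
#' @return a [CalibratedCube-class] with \code{method = "reflectance_norm"}
#' @export
reflectanceNorm <- function(cube, dark, white) {
    d <- dim(cube@data)
    D <- .frameMatrix(dark, d[2L], d[3L])
    W <- .frameMatrix(white, d[2L], d[3L])
    bad <- W <= D
    if (any(bad)) {
        bands <- sort(unique(which(bad, arr.ind = TRUE)[, 2L]))
        stop("white reference does not exceed dark current at band(s): ",
            paste(bands, collapse = ", "))
    }
    arr <- .darkCorrected(cube, dark)
    arr <- arr / rep(W - D, each = d[1L])
    new("CalibratedCube", data = arr, wavelengths = cube@wavelengths,
        meta = cube@meta, method = "reflectance_norm",
        binning = as.integer(cube@meta$binning %||% 1L),
        degenerate = matrix(FALSE, d[1L], d[2L]))
}

.binIndices <- function(nb, n, phase) {
    if (!n %in% c(1L, 2L, 4L))
        stop("binning factor must be 1, 2 or 4")
    if (nb %% n != 0L)
        stop("band count ", nb, " not divisible by binning factor ", n,
            " (no partial bins)")
    if (phase < 1L || phase > n)
        stop("'phase' must be in 1..n")
    seq.int(phase, nb, by = n)
}

#' @describeIn spectralBin decimate a raw cube
#' @export
setMethod("spectralBin", "HyperCube", function(x, n, phase = 1L) {
    n <- as.integer(n)
    keep <- .binIndices(nBands(x), n, as.integer(phase))
    meta <- x@meta
    meta$binning <- as.integer(meta$binning %||% 1L) * n
    HyperCube(x@data[, , keep, drop = FALSE], x@wavelengths[keep], meta)
})

#' @describeIn spectralBin decimate a calibrated cube; the binning factor is
#'   recorded multiplicatively in the \code{binning} slot
#' @export
setMethod("spectralBin", "CalibratedCube", function(x, n, phase = 1L) {
    n <- as.integer(n)
    keep <- .binIndices(nBands(x), n, as.integer(phase))
    new("CalibratedCube", data = x@data[, , keep, drop = FALSE],
        wavelengths = x@wavelengths[keep], meta = x@meta,
        method = x@method, binning = x@binning * n,
        degenerate = x@degenerate)
})
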