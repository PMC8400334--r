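#' Construct a HyperCube
#'
#' @param data 3-D numeric array with axes (line, sample, band), raw DN.
#' @param wavelengths band-center wavelengths in nm, strictly increasing.
#' @param meta optional list of acquisition descriptors.
#' @return a [HyperCube-class]
#' @examples
#' cube <- HyperCube(array(0, c(2, 2, 4)),
#'                   wavelengths = c(400, 600, 800, 1000))
#' cube
#' @export
HyperCube <- function(data, wavelengths, meta = list()) {
    new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
        meta = meta)
}

#' Construct a ReferenceFrame
#'
#' Dark-current frames are recorded with the lens capped and capture the
#' fixed-pattern sensor offset; white-reference frames image a calibrated
#' white target and anchor the reflectance conversion.
#'
#' @param values numeric matrix (samples x bands), or a per-band vector for
#'   a spatially constant frame.
#' @param kind \code{"dark_current"} or \code{"white_reference"}.
#' @return a [ReferenceFrame-class]
#' @examples
#' dark <- ReferenceFrame(rep(96, 112), kind = "dark_current")
#' @export
ReferenceFrame <- function(values, kind = c("dark_current",
                                            "white_reference")) {
    kind <- match.arg(kind)
    if (is.null(dim(values)))
        values <- matrix(values, nrow = 1L)
    new("ReferenceFrame", kind = kind, values = values)
}

# Expand a reference frame to the (samples x bands) shape of a cube.
# A 1 x bands frame is recycled across samples.
.frameMatrix <- function(frame, nSamp, nBand) {
    v <- if (is(frame, "ReferenceFrame")) frame@values else frame
    if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
    if (ncol(v) != nBand)
        stop("reference frame has ", ncol(v), " bands; cube has ", nBand)
    if (nrow(v) == 1L)
        v <- matrix(v, nrow = nSamp, ncol = nBand, byrow = TRUE)
    if (nrow(v) != nSamp)
        stop("reference frame has ", nrow(v), " samples; cube has ", nSamp)
    v
}
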