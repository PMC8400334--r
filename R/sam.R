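## Spectral angle mapper (SAM) baseline: a 3-class classifier over Per-Norm
## pixels driven by the angle between spectra in band space. Provided as
## the comparison method for the two-stage detector, in two modes: a
## transparent nearest-angle classifier (default) and a one-vs-one SVM on
## a precomputed exp(-theta) kernel.

#' Spectral angle between two spectra
#'
#' \deqn{\theta(x, y) = \cos^{-1}\!\left(\frac{\sum_i x_i y_i}
#'   {\sqrt{\sum_i x_i^2}\,\sqrt{\sum_i y_i^2}}\right)}
#' The angle lies in \[0, pi\], is symmetric, zero on self, and invariant
#' to positive rescaling of either argument — brightness changes leave it
#' untouched, which is why SAM is a standard spectral-similarity measure.
#'
#' @param x,y numeric spectra of equal length, neither with zero norm.
#' @return angle in radians
#' @examples
#' samAngle(c(1, 1), c(1, 0))   # pi/4
#' @export
samAngle <- function(x, y) {
    if (length(x) != length(y))
        stop("spectra must have equal length")
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0)
        stop("zero-norm spectrum has no spectral angle")
    acos(min(1, max(-1, sum(x * y) / (nx * ny))))
}

# Angle matrix between rows of X (n x b) and rows of Y (m x b).
.samAngleMatrix <- function(X, Y) {
    nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
    if (any(nx == 0) || any(ny == 0))
        stop("zero-norm spectrum has no spectral angle")
    cosang <- (X / nx) %*% t(Y / ny)
    cosang[cosang > 1] <- 1     # clamp rounding error; keeps matrix dims
    cosang[cosang < -1] <- -1
    acos(cosang)
}

#' Construct a SAM training set
#'
#' @param pixels numeric matrix of Per-Norm spectra, one per row.
#' @param labels character labels (\code{seaweed}, \code{belt},
#'   \code{foreign}), one per row.
#' @return a [SamTrainingSet-class]
#' @export
samTrainingSet <- function(pixels, labels) {
    new("SamTrainingSet", pixels = as.matrix(pixels),
        labels = as.character(labels))
}

#' Classify pixels by spectral angle
#'
#' \code{nearest_angle} (default) assigns each pixel the label of the
#' training pixel at the smallest spectral angle, ties going to the
#' smallest training index. \code{svm_precomputed} trains a one-vs-one
#' multi-class SVM (\code{kernlab::ksvm}) on the precomputed kernel
#' \eqn{K(x, y) = \exp(-\theta(x, y))} — the kernel transform is an
#' implementation choice for a well-behaved similarity, not a claim about
#' the original deployment's SVM internals.
#'
#' @param pixels numeric spectrum (vector) or matrix of spectra (rows).
#' @param train a [SamTrainingSet-class]
#' @param mode \code{"nearest_angle"} or \code{"svm_precomputed"}.
#' @param C SVM cost parameter (svm mode only).
#' @return character label(s)
#' @export
samClassify <- function(pixels, train,
                        mode = c("nearest_angle", "svm_precomputed"),
                        C = 10) {
    mode <- match.arg(mode)
    X <- rbind(pixels)
    if (ncol(X) != ncol(train@pixels))
        stop("pixel band count ", ncol(X), " does not match training set ",
            ncol(train@pixels))
    if (mode == "nearest_angle") {
        theta <- .samAngleMatrix(X, train@pixels)
        # smallest angle wins; max.col on the negative with ties.method
        # "first" pins ties to the smallest training index
        best <- max.col(-theta, ties.method = "first")
        return(train@labels[best])
    }
    model <- .samSvmModel(train, C)
    .samSvmPredict(model, X, train)
}

.samSvmModel <- function(train, C) {
    K <- exp(-.samAngleMatrix(train@pixels, train@pixels))
    kernlab::ksvm(kernlab::as.kernelMatrix(K),
        factor(train@labels), type = "C-svc", C = C)
}

.samSvmPredict <- function(model, X, train) {
    sv <- kernlab::SVindex(model)
    Ktest <- exp(-.samAngleMatrix(X, train@pixels[sv, , drop = FALSE]))
    as.character(kernlab::predict(model, kernlab::as.kernelMatrix(Ktest)))
}

#' Run the SAM baseline over a whole cube
#'
#' Classifies every pixel with [samClassify()] and applies the same
#' sheet-level verdict rule as the two-stage detector: reject when at
#' least \code{minForeignPixels} pixels are labeled foreign. No ignored
#' zone applies — the SAM baseline inspects every pixel, which is part of
#' its computational cost.
#'
#' @param cube a Per-Norm [CalibratedCube-class]
#' @param train a [SamTrainingSet-class] with matching band count
#' @param mode passed to [samClassify()]
#' @param minForeignPixels reject threshold (default 1)
#' @return list with \code{map} ([ClassMap-class]) and \code{verdict}
#'   ([SheetVerdict-class])
#' @export
samDetectSheet <- function(cube, train, mode = "nearest_angle",
                           minForeignPixels = 1L) {
    d <- dim(cube@data)
    flat <- .flatPixels(cube)
    lab <- samClassify(flat, train, mode = mode)
    labels <- matrix(lab, d[1L], d[2L])
    foreign <- labels == "foreign"
    map <- new("ClassMap", labels = labels,
        ignored = matrix(FALSE, d[1L], d[2L]),
        stage1Only = matrix(FALSE, d[1L], d[2L]))
    list(map = map,
        verdict = .makeVerdict(foreign, matrix(FALSE, d[1L], d[2L]),
            minForeignPixels))
}
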