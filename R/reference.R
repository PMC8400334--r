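## Reference model: per-class spectral statistics from labeled Per-Norm
## pixels, the standardized min/max envelope used by stage-2 inspection, and
## the exhaustive two-band search behind the stage-1 subtraction feature.

#' Build a per-class spectral reference profile
#'
#' Computes the band-wise mean and population standard deviation of a
#' labeled reference pixel set (Per-Norm units), and the standardized
#' envelope: the band-wise minimum and maximum of the reference pixels
#' after standardization against their own mean and sd. Population (not
#' sample) sd is used: with the ~10,000-pixel reference sets the scheme is
#' built for, the distinction is negligible, and population sd keeps tiny
#' test fixtures deterministic.
#'
#' @param pixels numeric matrix, one Per-Norm reference spectrum per row.
#' @param className \code{"seaweed"} or \code{"belt"}.
#' @param wavelengths optional band-center nm, recorded in the profile.
#' @return a [ReferenceProfile-class]
#' @examples
#' p <- buildProfile(rbind(c(0, 10), c(10, 0)), "seaweed")
#' p@mu       # 5 5
#' p@envLow   # -1 -1
#' @export
buildProfile <- function(pixels, className = c("seaweed", "belt"),
                         wavelengths = numeric()) {
    className <- match.arg(className)
    pixels <- as.matrix(pixels)
    if (nrow(pixels) < 2L)
        stop("at least 2 reference pixels are required")
    mu <- colMeans(pixels)
    sigma <- sqrt(colMeans(pixels^2) - mu^2)
    sigma[sigma < 0] <- 0   # guard against negative rounding error
    zeroSd <- which(sigma == 0)
    if (length(zeroSd))
        stop("zero standard deviation at band(s): ",
            paste(zeroSd, collapse = ", "))
    z <- sweep(sweep(pixels, 2L, mu), 2L, sigma, "/")
    new("ReferenceProfile", className = className, mu = mu, sigma = sigma,
        envLow = apply(z, 2L, min), envHigh = apply(z, 2L, max),
        nPixels = nrow(pixels), wavelengths = as.numeric(wavelengths))
}

#' Standardize a spectrum against a reference profile
#'
#' Band-wise z-score: \eqn{x^{new}_b = (x_b - \mu_b) / \sigma_b}. The
#' profile mean maps to the zero vector; a spectrum one reference sd above
#' the mean at every band maps to all ones.
#'
#' @param x numeric Per-Norm spectrum (vector) or matrix of spectra (one
#'   per row).
#' @param profile a [ReferenceProfile-class] with matching band count.
#' @return z-spectrum of the same shape as \code{x}
#' @export
standardize <- function(x, profile) {
    if (is.null(dim(x))) {
        if (length(x) != length(profile@mu))
            stop("spectrum has ", length(x), " bands; profile has ",
                length(profile@mu))
        return((x - profile@mu) / profile@sigma)
    }
    if (ncol(x) != length(profile@mu))
        stop("spectra have ", ncol(x), " bands; profile has ",
            length(profile@mu))
    sweep(sweep(x, 2L, profile@mu), 2L, profile@sigma, "/")
}

#' Exhaustive two-band search for the most separating subtraction pair
#'
#' Scores every ordered band pair (i < j) whose wavelengths both lie inside
#' \code{rangeNm} by the absolute difference between the two classes' mean
#' subtraction values, \eqn{|(\mu^a_j - \mu^a_i) - (\mu^b_j - \mu^b_i)|},
#' and returns the argmax. This is deliberately brute force — the search
#' space (a few thousand pairs within a range) is tiny. Ties are broken by
#' the smaller i, then the smaller j.
#'
#' @param profileA,profileB [ReferenceProfile-class] objects for the two
#'   classes (e.g. seaweed and belt).
#' @param rangeNm numeric \code{c(lo, hi)} wavelength window, e.g.
#'   \code{c(400, 750)} for the visible range.
#' @param wavelengths band-center nm of the cube the profiles were built on.
#' @return list with \code{bandLo}, \code{bandHi} (1-based indices into the
#'   full band list) and \code{separation} (Per-Norm difference units)
#' @export
selectBandPair <- function(profileA, profileB, rangeNm, wavelengths) {
    stopifnot(length(rangeNm) == 2L)
    idx <- which(wavelengths >= rangeNm[1L] & wavelengths <= rangeNm[2L])
    if (length(idx) < 2L)
        stop("fewer than 2 bands inside [", rangeNm[1L], ", ", rangeNm[2L],
            "] nm")
    da <- profileA@mu[idx]
    db <- profileB@mu[idx]
    # separation for pair (i, j): |(da_j - da_i) - (db_j - db_i)|
    g <- da - db
    sep <- abs(outer(g, g, "-"))       # sep[i, j] = |g_j - g_i|
    sep[!upper.tri(sep)] <- -Inf       # keep ordered pairs i < j only
    best <- which(sep == max(sep), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L])[1L], , drop = TRUE]
    list(bandLo = idx[best[[1L]]], bandHi = idx[best[[2L]]],
        separation = max(sep))
}

#' Construct a SubtractionConfig
#'
#' @param visiblePair,nirPair length-2 integer band indices (low, high),
#'   1-based into the (binned) cube.
#' @param visibleIntervals,nirIntervals named lists with \code{seaweed} and
#'   \code{belt} elements, each \code{c(lo, hi)} in Per-Norm difference
#'   units.
#' @param visibleRangeNm,nirRangeNm nm windows of the two ranges.
#' @return a [SubtractionConfig-class]
#' @export
subtractionConfig <- function(visiblePair, nirPair, visibleIntervals,
                              nirIntervals,
                              visibleRangeNm = c(400, 750),
                              nirRangeNm = c(750, 1000)) {
    new("SubtractionConfig",
        visiblePair = as.integer(visiblePair), nirPair = as.integer(nirPair),
        visibleIntervals = visibleIntervals, nirIntervals = nirIntervals,
        visibleRangeNm = as.numeric(visibleRangeNm),
        nirRangeNm = as.numeric(nirRangeNm))
}

#' The bundled operating-point configuration
#'
#' Loads the configuration shipped with the package for the 112-band
#' (1/2-binned) seaweed line: visible pair bands 26 and 63 (~532 and
#' ~732 nm), NIR pair bands 68 and 93 (~759 and ~897 nm), with acceptance
#' intervals seaweed SV \[60, 80\], belt SV \[20, 45\], seaweed SN
#' \[-30, -5\], belt SN \[5, 25\].
#'
#' @return a [SubtractionConfig-class]
#' @export
defaultSubtractionConfig <- function() {
    path <- system.file("extdata", "subtraction-defaults.yaml",
        package = "kelpscan", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    subtractionConfig(
        visiblePair = unlist(cfg$visible$pair),
        nirPair = unlist(cfg$nir$pair),
        visibleIntervals = list(
            seaweed = as.numeric(unlist(cfg$visible$intervals$seaweed)),
            belt = as.numeric(unlist(cfg$visible$intervals$belt))),
        nirIntervals = list(
            seaweed = as.numeric(unlist(cfg$nir$intervals$seaweed)),
            belt = as.numeric(unlist(cfg$nir$intervals$belt))),
        visibleRangeNm = as.numeric(unlist(cfg$visible$range_nm)),
        nirRangeNm = as.numeric(unlist(cfg$nir$range_nm)))
}

#' Derive class acceptance intervals from labeled reference pixels
#'
#' For each range, the interval of a class is the \[min, max\] of its
#' reference pixels' subtraction values, optionally widened by \code{slack}
#' on each side (default 0: the bundled operating point ships fixed
#' intervals, not a derivation rule). Errors if the two classes' intervals
#' overlap within a range — the classes are then not separable at the
#' configured bands.
#'
#' @param config a [SubtractionConfig-class] whose band pairs are already
#'   chosen; its intervals are replaced.
#' @param pixels named list with elements \code{seaweed} and \code{belt},
#'   each a matrix of Per-Norm spectra (one per row).
#' @param slack non-negative widening applied to both ends of every
#'   interval, Per-Norm difference units.
#' @return the \code{config} with intervals replaced by the observed ones
#' @export
deriveIntervals <- function(config, pixels, slack = 0) {
    stopifnot(all(c("seaweed", "belt") %in% names(pixels)), slack >= 0)
    for (cls in c("seaweed", "belt"))
        if (nrow(as.matrix(pixels[[cls]])) == 1L)
            warning("one-pixel class '", cls,
                "': degenerate zero-width interval")
    rangeOf <- function(mat, pair) {
        mat <- as.matrix(mat)
        v <- mat[, pair[2L]] - mat[, pair[1L]]
        c(min(v) - slack, max(v) + slack)
    }
    vis <- list(seaweed = rangeOf(pixels$seaweed, config@visiblePair),
        belt = rangeOf(pixels$belt, config@visiblePair))
    nir <- list(seaweed = rangeOf(pixels$seaweed, config@nirPair),
        belt = rangeOf(pixels$belt, config@nirPair))
    if (.intervalsOverlap(vis$seaweed, vis$belt))
        stop("visible-range intervals overlap: classes not separable at ",
            "these bands")
    if (.intervalsOverlap(nir$seaweed, nir$belt))
        stop("NIR-range intervals overlap: classes not separable at these ",
            "bands")
    initialize(config, visibleIntervals = vis, nirIntervals = nir)
}

#' Serialize reference profiles to a plain-text table
#'
#' Profiles are written as a versioned TSV (band, wavelength, mu, sigma,
#' envLow, envHigh per class) so detection runs are reproducible without
#' the training pixels.
#'
#' @param profiles named list of [ReferenceProfile-class] objects.
#' @param path file to write / read.
#' @return \code{writeProfiles}: \code{path} invisibly;
#'   \code{readProfiles}: named list of profiles
#' @export
writeProfiles <- function(profiles, path) {
    rows <- lapply(profiles, function(p) {
        nb <- length(p@mu)
        data.frame(class = p@className, band = seq_len(nb),
            wavelength = if (length(p@wavelengths)) p@wavelengths else NA,
            mu = p@mu, sigma = p@sigma, envLow = p@envLow,
            envHigh = p@envHigh, nPixels = p@nPixels)
    })
    tab <- do.call(rbind, rows)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# kelpscan reference profiles v1", con)
    utils::write.table(tab, con, sep = "\t", row.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
    first <- readLines(path, n = 1L)
    if (!grepl("^# kelpscan reference profiles v1", first))
        stop("unrecognized profile file: ", path)
    tab <- utils::read.delim(path, skip = 1L)
    out <- lapply(split(tab, tab$class), function(d) {
        d <- d[order(d$band), ]
        new("ReferenceProfile", className = d$class[1L], mu = d$mu,
            sigma = d$sigma, envLow = d$envLow, envHigh = d$envHigh,
            nPixels = as.integer(d$nPixels[1L]),
            wavelengths = if (all(is.na(d$wavelength))) numeric()
                else d$wavelength)
    })
    out
}
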