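## Two-stage detector.
##
## Stage 1 segments each line by two band subtractions (one visible pair,
## one NIR pair): a pixel whose subtraction value falls in neither class
## interval in either range is foreign; otherwise the visible-range interval
## decides seaweed vs belt. Stage 2 standardizes the remaining pixels
## against their class's reference profile and flags any pixel whose
## z-score leaves the reference envelope widened by a margin at any band.

#' Construct detector parameters
#'
#' @param subtraction a [SubtractionConfig-class]; defaults to the bundled
#'   operating point ([defaultSubtractionConfig()]).
#' @param margin z-unit margin added to both envelope bounds at stage 2
#'   (default 3). Smaller margins increase sensitivity.
#' @param minForeignPixels reject threshold on the foreign pixel count
#'   (default 1: a single flagged pixel rejects the sheet; configurable
#'   because single-pixel triggers are noise-sensitive).
#' @param ignoredZoneMode \code{"outside_sheet_bbox"} (default): belt pixels
#'   outside the bounding box of seaweed-labeled pixels are skipped by
#'   stage 2; \code{"none"}: every non-foreign pixel is inspected.
#' @return a [DetectorParams-class]
#' @export
detectorParams <- function(subtraction = defaultSubtractionConfig(),
                           margin = 3, minForeignPixels = 1L,
                           ignoredZoneMode = c("outside_sheet_bbox",
                                               "none")) {
    ignoredZoneMode <- match.arg(ignoredZoneMode)
    new("DetectorParams", subtraction = subtraction, margin = margin,
        minForeignPixels = as.integer(minForeignPixels),
        ignoredZoneMode = ignoredZoneMode)
}

#' Stage-1 subtraction features
#'
#' Per pixel, \eqn{SV = P_{hi,vis} - P_{lo,vis}} and
#' \eqn{SN = P_{hi,nir} - P_{lo,nir}}: the difference between the high and
#' low configured bands of each range, in Per-Norm units.
#'
#' @param line numeric matrix (samples x bands) of Per-Norm values, e.g.
#'   from [lineSlice()].
#' @param config a [SubtractionConfig-class]
#' @return list with numeric vectors \code{sv} and \code{sn}, one value per
#'   sample
#' @export
subtractionFeatures <- function(line, config) {
    line <- rbind(line)   # promote a single spectrum to a 1-row matrix
    nb <- ncol(line)
    idx <- c(config@visiblePair, config@nirPair)
    if (any(idx > nb))
        stop("configured band index ", max(idx), " exceeds band count ", nb)
    list(sv = line[, config@visiblePair[2L]] - line[, config@visiblePair[1L]],
        sn = line[, config@nirPair[2L]] - line[, config@nirPair[1L]])
}

.inInterval <- function(x, iv) x >= iv[1L] & x <= iv[2L]

#' Stage-1 classification from subtraction values
#'
#' A pixel is foreign if its SV lies in neither visible-range class
#' interval \emph{or} its SN lies in neither NIR-range class interval
#' (a foreign object is called in either range). Otherwise the
#' visible-range membership decides seaweed vs belt; when the two ranges
#' place the pixel in different classes, the visible range wins and the
#' disagreement is counted in the \code{"disagreements"} attribute.
#'
#' @param sv,sn numeric subtraction values per sample (from
#'   [subtractionFeatures()]).
#' @param config a [SubtractionConfig-class]
#' @return character vector of labels in \code{seaweed}/\code{belt}/
#'   \code{foreign}, with attribute \code{disagreements}
#' @export
stage1Classify <- function(sv, sn, config) {
    visSw <- .inInterval(sv, config@visibleIntervals$seaweed)
    visBelt <- .inInterval(sv, config@visibleIntervals$belt)
    nirSw <- .inInterval(sn, config@nirIntervals$seaweed)
    nirBelt <- .inInterval(sn, config@nirIntervals$belt)
    foreign <- (!visSw & !visBelt) | (!nirSw & !nirBelt)
    labels <- ifelse(foreign, "foreign", ifelse(visSw, "seaweed", "belt"))
    disagree <- !foreign & ((visSw & nirBelt) | (visBelt & nirSw))
    attr(labels, "disagreements") <- sum(disagree)
    labels
}

#' Stage-2 skip mask (ignored zone)
#'
#' With mode \code{"outside_sheet_bbox"}, belt-labeled pixels outside the
#' bounding box of the seaweed-labeled pixels are excluded from stage-2
#' inspection — foreign objects on the bare conveyor need not be found, and
#' skipping that zone saves a substantial share of the standardization
#' work. Belt pixels \emph{inside} the box stay inspected, so an object
#' overhanging the sheet edge is still caught.
#'
#' @param labels character matrix of stage-1 labels (lines x samples).
#' @param mode \code{"outside_sheet_bbox"} or \code{"none"}.
#' @return logical matrix; \code{TRUE} where stage 2 is skipped
#' @export
ignoredZone <- function(labels, mode = c("outside_sheet_bbox", "none")) {
    mode <- match.arg(mode)
    ign <- matrix(FALSE, nrow(labels), ncol(labels))
    if (mode == "none") return(ign)
    sw <- labels == "seaweed"
    if (!any(sw)) {
        warning("no seaweed pixels found; entire raster ignored")
        return(labels == "belt")
    }
    rows <- range(which(rowSums(sw) > 0))
    cols <- range(which(colSums(sw) > 0))
    inBox <- matrix(FALSE, nrow(labels), ncol(labels))
    inBox[rows[1L]:rows[2L], cols[1L]:cols[2L]] <- TRUE
    labels == "belt" & !inBox
}

#' Stage-2 standardization envelope inspection
#'
#' Standardizes Per-Norm spectra against the profile of their stage-1 class
#' and flags a pixel as foreign when \emph{any} band's z-score falls below
#' \code{envLow - margin} or above \code{envHigh + margin}. Every pixel of
#' the reference set itself is clean at any margin >= 0, because the
#' envelope is the band-wise min/max of the standardized reference set.
#'
#' @param x numeric spectrum or matrix of spectra (rows).
#' @param profile the [ReferenceProfile-class] of the pixels' class.
#' @param margin non-negative z-unit margin (default 3).
#' @return logical: \code{TRUE} where the pixel is foreign (per row for a
#'   matrix)
#' @export
stage2Inspect <- function(x, profile, margin = 3) {
    stopifnot(margin >= 0)
    z <- standardize(x, profile)
    lo <- profile@envLow - margin
    hi <- profile@envHigh + margin
    if (is.null(dim(z)))
        return(any(z < lo | z > hi))
    out <- sweep(z, 2L, lo, "<") | sweep(z, 2L, hi, ">")
    rowSums(out) > 0
}

# 4-connected component count of a logical mask (flood fill over the
# typically sparse foreign mask).
.componentCount4 <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    idx <- which(mask)
    if (!length(idx)) return(0L)
    seen <- logical(nr * nc)
    comp <- 0L
    for (s in idx) {
        if (seen[s]) next
        comp <- comp + 1L
        queue <- s
        seen[s] <- TRUE
        while (length(queue)) {
            cur <- queue[[1L]]
            queue <- queue[-1L]
            r <- (cur - 1L) %% nr + 1L
            cc <- (cur - 1L) %/% nr + 1L
            nb <- c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
                if (cc > 1L) cur - nr, if (cc < nc) cur + nr)
            nb <- nb[mask[nb] & !seen[nb]]
            seen[nb] <- TRUE
            queue <- c(queue, nb)
        }
    }
    comp
}

.makeVerdict <- function(foreignMask, stage1Mask, minForeign) {
    count <- sum(foreignMask)
    new("SheetVerdict",
        decision = if (count >= minForeign) "reject" else "accept",
        foreignPixelCount = as.integer(count),
        foreignComponents = .componentCount4(foreignMask),
        stage1Count = as.integer(sum(stage1Mask)),
        stage2Count = as.integer(count - sum(stage1Mask)),
        minForeignPixels = as.integer(minForeign))
}

# Stage-2 pass over a labels matrix: returns a logical foreign mask for
# pixels labeled `class` that are inspectable (not ignored).
.stage2Pass <- function(flat, labels, ignored, profiles, margin) {
    foreign <- matrix(FALSE, nrow(labels), ncol(labels))
    for (cls in c("seaweed", "belt")) {
        sel <- which(labels == cls & !ignored)
        if (!length(sel)) next
        prof <- profiles[[cls]]
        if (is.null(prof))
            stop("no reference profile for class '", cls, "'")
        foreign[sel] <- stage2Inspect(flat[sel, , drop = FALSE], prof,
            margin)
    }
    foreign
}

.flatPixels <- function(cube) {
    d <- dim(cube@data)
    matrix(cube@data, nrow = d[1L] * d[2L], ncol = d[3L])
}

#' Run the full two-stage detector on a calibrated cube
#'
#' Stage 1 classifies every pixel from its two subtraction values; the
#' ignored zone is derived from the stage-1 label raster; stage 2 inspects
#' the remaining seaweed/belt pixels against their class profiles
#' (stage-1 foreign pixels are excluded from stage 2). The verdict rejects
#' the sheet when at least \code{minForeignPixels} pixels are foreign.
#'
#' With \code{streaming = TRUE} the cube is processed strictly line by
#' line, honoring the push-broom acquisition order. With the ignored zone
#' off, streaming results are bit-identical to whole-cube results; with
#' mode \code{"outside_sheet_bbox"} the streaming bounding box is computed
#' over a trailing window of \code{windowLines} lines and can differ from
#' the batch box near the sheet ends.
#'
#' @param cube a Per-Norm [CalibratedCube-class] at the binning the
#'   profiles were built on.
#' @param profiles named list with [ReferenceProfile-class] elements
#'   \code{seaweed} and \code{belt}.
#' @param params a [DetectorParams-class]
#' @param streaming process line-by-line (default FALSE).
#' @param windowLines trailing-window length for the streaming ignored
#'   zone (default 64).
#' @return list with \code{map} (a [ClassMap-class]) and \code{verdict}
#'   (a [SheetVerdict-class])
#' @examples
#' \donttest{
#' mats <- makeMaterials()
#' sc <- sceneSpec(seed = 11, samples = 128L, pixelPitchMm = 2,
#'                 lineRate = 50)
#' scene <- renderScene(sc, mats)
#' pn <- perNorm(scene$cube, scene$dark)
#' profs <- list(
#'   seaweed = buildProfile(referencePixels("seaweed", 2000, seed = 1),
#'                          "seaweed"),
#'   belt = buildProfile(referencePixels("belt", 2000, seed = 2), "belt"))
#' res <- detectSheet(pn, profs, detectorParams())
#' res$verdict
#' }
#' @export
detectSheet <- function(cube, profiles, params = detectorParams(),
                        streaming = FALSE, windowLines = 64L) {
    if (!is(cube, "CalibratedCube") || cube@method != "per_norm")
        stop("detectSheet expects a Per-Norm calibrated cube")
    for (cls in c("seaweed", "belt")) {
        prof <- profiles[[cls]]
        if (is.null(prof))
            stop("missing reference profile for class '", cls, "'")
        if (length(prof@mu) != nBands(cube))
            stop("profile '", cls, "' has ", length(prof@mu),
                " bands; cube has ", nBands(cube))
    }
    if (streaming)
        return(.detectSheetStream(cube, profiles, params, windowLines))
    d <- dim(cube@data)
    flat <- .flatPixels(cube)
    cfg <- params@subtraction
    feats <- subtractionFeatures(flat, cfg)
    s1 <- stage1Classify(feats$sv, feats$sn, cfg)
    labels <- matrix(as.character(s1), d[1L], d[2L])
    ignored <- ignoredZone(labels, params@ignoredZoneMode)
    stage1Foreign <- labels == "foreign"
    s2foreign <- .stage2Pass(flat, labels, ignored, profiles, params@margin)
    labels[s2foreign] <- "foreign"
    foreignMask <- stage1Foreign | s2foreign
    map <- new("ClassMap", labels = labels, ignored = ignored,
        stage1Only = stage1Foreign)
    list(map = map,
        verdict = .makeVerdict(foreignMask, stage1Foreign,
            params@minForeignPixels))
}

# Line-by-line variant. Stage 1 runs per line as acquired; the ignored
# zone (if enabled) uses a trailing window of stage-1 labels; stage 2 runs
# per line on the non-ignored pixels.
.detectSheetStream <- function(cube, profiles, params, windowLines) {
    d <- dim(cube@data)
    cfg <- params@subtraction
    labels <- matrix("", d[1L], d[2L])
    ignored <- matrix(FALSE, d[1L], d[2L])
    s2foreign <- matrix(FALSE, d[1L], d[2L])
    for (i in seq_len(d[1L])) {
        line <- cube@data[i, , , drop = TRUE]
        if (is.null(dim(line))) line <- matrix(line, nrow = 1L)
        feats <- subtractionFeatures(line, cfg)
        lab <- as.character(stage1Classify(feats$sv, feats$sn, cfg))
        labels[i, ] <- lab
        if (params@ignoredZoneMode == "outside_sheet_bbox") {
            lo <- max(1L, i - as.integer(windowLines) + 1L)
            win <- labels[lo:i, , drop = FALSE]
            sw <- win == "seaweed"
            if (any(sw)) {
                cols <- range(which(colSums(sw) > 0))
                ignored[i, ] <- lab == "belt" &
                    (seq_len(d[2L]) < cols[1L] | seq_len(d[2L]) > cols[2L])
            } else {
                ignored[i, ] <- lab == "belt"
            }
        }
        inspect <- which(lab != "foreign" & !ignored[i, ])
        for (cls in c("seaweed", "belt")) {
            sel <- inspect[lab[inspect] == cls]
            if (!length(sel)) next
            s2foreign[i, sel] <- stage2Inspect(
                line[sel, , drop = FALSE], profiles[[cls]], params@margin)
        }
    }
    stage1Foreign <- labels == "foreign"
    labels[s2foreign] <- "foreign"
    foreignMask <- stage1Foreign | s2foreign
    map <- new("ClassMap", labels = labels, ignored = ignored,
        stage1Only = stage1Foreign)
    list(map = map,
        verdict = .makeVerdict(foreignMask, stage1Foreign,
            params@minForeignPixels))
}

#' Render a class map as an RGB array
#'
#' Seaweed renders black, conveyor belt white, foreign red; ignored pixels
#' render white (they are belt by construction).
#'
#' @param map a [ClassMap-class]
#' @return numeric array (lines x samples x 3) with values in \[0, 1\],
#'   suitable for \code{png::writePNG}
#' @export
renderClassMap <- function(map) {
    lab <- map@labels
    r <- (lab != "seaweed") * 1
    gb <- (lab == "belt") * 1
    out <- array(0, c(nrow(lab), ncol(lab), 3L))
    out[, , 1L] <- r
    out[, , 2L] <- gb
    out[, , 3L] <- gb
    out
}
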