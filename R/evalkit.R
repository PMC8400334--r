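## Sheet-level confusion metrics and the data-rate calculator.
##
## Positive class = "sheet contains a foreign object": TP counts
## contaminated sheets rejected, FN contaminated sheets accepted, FP clean
## sheets rejected, TN clean sheets accepted. Under this convention
## recall = TP/(TP+FN) is the fraction of contaminated sheets caught and
## precision = TP/(TP+FP) the fraction of rejections that were justified.

# round-half-up at k decimals (display convention; raw values retained)
.roundHalfUp <- function(x, k = 2L) floor(x * 10^k + 0.5) / 10^k

#' Score a benchmark of sheet verdicts
#'
#' @param rejected logical: the detector's decision per sheet
#'   (TRUE = rejected).
#' @param contaminated logical ground truth per sheet.
#' @return list with counts \code{tp}, \code{fn}, \code{fp}, \code{tn},
#'   raw metrics \code{recall}, \code{precision}, \code{accuracy}
#'   (\code{NA} when undefined, e.g. recall with no contaminated sheets)
#'   and their 2-decimal display roundings \code{recall2} etc.
#' @examples
#' scoreBenchmark(rejected = c(TRUE, TRUE, FALSE),
#'                contaminated = c(TRUE, FALSE, FALSE))
#' @export
scoreBenchmark <- function(rejected, contaminated) {
    stopifnot(length(rejected) == length(contaminated),
        length(rejected) > 0L)
    tp <- sum(rejected & contaminated)
    fn <- sum(!rejected & contaminated)
    fp <- sum(rejected & !contaminated)
    tn <- sum(!rejected & !contaminated)
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    recall <- safe(tp, tp + fn)
    precision <- safe(tp, tp + fp)
    accuracy <- (tp + tn) / (tp + fn + fp + tn)
    list(tp = tp, fn = fn, fp = fp, tn = tn,
        recall = recall, precision = precision, accuracy = accuracy,
        recall2 = .roundHalfUp(recall), precision2 = .roundHalfUp(precision),
        accuracy2 = .roundHalfUp(accuracy))
}

#' @rdname scoreBenchmark
#' @param tp,fn,fp,tn confusion counts, for scoring pre-tabulated results.
#' @export
scoreCounts <- function(tp, fn, fp, tn) {
    scoreBenchmark(
        rejected = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fn, fp, tn)),
        contaminated = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, fp, tn)))
}

#' Line rate required for a target along-track resolution
#'
#' A belt moving at \code{beltSpeed} cm/s advances \code{beltSpeed * 10}
#' mm every second; resolving \code{resolutionMm} per line therefore needs
#' \code{beltSpeed * 10 / resolutionMm} lines/s (300 lines/s for 30 cm/s
#' at 1 mm).
#'
#' @param beltSpeed conveyor speed, cm/s.
#' @param resolutionMm along-track resolution, mm per line.
#' @return required line rate, lines/s
#' @export
requiredLineRate <- function(beltSpeed, resolutionMm) {
    stopifnot(beltSpeed > 0, resolutionMm > 0)
    beltSpeed * 10 / resolutionMm
}

#' Raw data rate of a hyperspectral line stream
#'
#' @param samples spatial samples per line.
#' @param bands spectral bands per sample.
#' @param bytesPerSample bytes per stored value (default 1).
#' @param lineRate lines per second.
#' @return list with \code{bytesPerLine} and \code{bytesPerSecond}
#' @examples
#' dataRate(1024, 224, 1, 300)  # 229376 B/line, 68812800 B/s
#' @export
dataRate <- function(samples, bands, bytesPerSample = 1, lineRate) {
    stopifnot(samples > 0, bands > 0, bytesPerSample > 0, lineRate > 0)
    bpl <- samples * bands * bytesPerSample
    list(bytesPerLine = bpl, bytesPerSecond = bpl * lineRate)
}

#' Data-rate reduction from spectral binning
#'
#' 1/n binning keeps one band in n, so the stream shrinks by a factor
#' (1 - 1/n) of the full-band rate, in bytes per second.
#'
#' @inheritParams dataRate
#' @param n binning factor, 2 or 4.
#' @return bytes/s removed from the stream
#' @export
binningSavings <- function(samples, bands, bytesPerSample = 1, lineRate,
                           n) {
    stopifnot(n %in% c(2, 4))
    dataRate(samples, bands, bytesPerSample, lineRate)$bytesPerSecond *
        (1 - 1 / n)
}

#' Run the two-stage detector (and optionally the SAM baseline) over a
#' synthetic benchmark
#'
#' For each scene: render, Per-Norm calibrate, detect, record the verdict.
#' Reference profiles are built once from labeled reference pixel draws of
#' the same material library.
#'
#' @param bench benchmark from [makeBenchmark()].
#' @param profiles named list of [ReferenceProfile-class] (seaweed, belt).
#' @param params a [DetectorParams-class].
#' @param materials library from [makeMaterials()].
#' @param samTrain optional [SamTrainingSet-class]; when supplied the SAM
#'   nearest-angle baseline is run on the same cubes.
#' @return data.frame, one row per scene: decision, foreign pixel counts
#'   per stage, ground truth, and (when \code{samTrain} is given) the SAM
#'   verdict and SAM foreign-pixel count
#' @export
runBenchmark <- function(bench, profiles, params = detectorParams(),
                         materials = makeMaterials(), samTrain = NULL) {
    n <- length(bench$scenes)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        scene <- renderScene(bench$scenes[[i]], materials)
        pn <- perNorm(scene$cube, scene$dark)
        res <- detectSheet(pn, profiles, params)
        v <- res$verdict
        row <- data.frame(scene = i,
            contaminated = bench$manifest$contaminated[i],
            decision = v@decision,
            foreignPixels = v@foreignPixelCount,
            stage1 = v@stage1Count, stage2 = v@stage2Count)
        if (!is.null(samTrain)) {
            sres <- samDetectSheet(pn, samTrain,
                minForeignPixels = params@minForeignPixels)
            row$samDecision <- sres$verdict@decision
            row$samForeignPixels <- sres$verdict@foreignPixelCount
        }
        rows[[i]] <- row
    }
    do.call(rbind, rows)
}
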