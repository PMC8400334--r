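## Synthetic push-broom line-scan camera.
##
## Scenes emulate the decision structure of the conveyor rig, not
## radiometry: each material is a piecewise-linear per-normalized band
## profile with per-pixel jitter, a multiplicative illumination gain
## (the pixel-to-pixel brightness offset that per-pixel normalization
## cancels), an optional additive diffuse-reflection boost confined to
## 500-680 nm, and additive sensor noise. Material anchor draws are chosen
## so that, after Per-Norm, seaweed and belt subtraction values land inside
## the operating-point intervals, shrimp shell / insect / thread fall
## outside them (stage-1-detectable), and plastic matches seaweed at the
## four configured bands while leaving the stage-2 envelope elsewhere
## (stage-2-only).

.SYNTH_NBANDS <- 112L
.SYNTH_WL <- seq(400, 1000, length.out = 112L)

# Linear interpolation weights from anchor bands onto the full grid, so
# that shapes = anchorValues %*% W (one shape per row).
.interpWeights <- function(anchorBands, nb = .SYNTH_NBANDS) {
    k <- length(anchorBands)
    W <- matrix(0, k, nb)
    for (b in seq_len(nb)) {
        if (b <= anchorBands[1L]) W[1L, b] <- 1
        else if (b >= anchorBands[k]) W[k, b] <- 1
        else {
            j <- findInterval(b, anchorBands)
            w <- (b - anchorBands[j]) / (anchorBands[j + 1L] - anchorBands[j])
            W[j, b] <- 1 - w
            W[j + 1L, b] <- w
        }
    }
    W
}

# Per-material anchor samplers: n draws -> per-norm shape matrix (n x 112).
#
# Two realism constraints shape the anchor scheme. First, each spectrum's
# extremes sit on short 2-3 band plateaus whose anchors are jittered
# independently per pixel, so the band attaining the per-pixel min/max
# wanders: with a fixed argmax band, per-pixel normalization would pin
# that band to exactly 100 everywhere and its reference sd would collapse
# to zero. Second, every band carries nonzero cross-pixel variance (real
# reference sets do), keeping the z-margin meaningful in raw units at all
# bands. The jitter makes per-norm rescale each spectrum by up to
# 100/97.5 ~ 1.026; the interval draws below leave headroom for that
# factor plus the diffuse boost and sensor noise.
.shapeSamplers <- list(
    seaweed = function(n) {
        p26 <- runif(n, 8, 14)
        p63 <- p26 + runif(n, 67, 77)       # SV in [67, 77]
        p68 <- runif(n, 88, 96)
        p93 <- p68 + runif(n, -27, -8)      # SN in [-27, -8]
        V <- cbind(runif(n, 0, 1.5), runif(n, 0, 1.5), runif(n, 2, 6),
            p26, p63, runif(n, 99, 100), runif(n, 99, 100), p68, p93,
            p93 - runif(n, 3, 8))
        V %*% .interpWeights(c(1L, 3L, 10L, 26L, 63L, 65L, 67L, 68L, 93L,
            112L))
    },
    belt = function(n) {
        p26 <- runif(n, 22, 30)
        p63 <- p26 + runif(n, 24, 42)       # SV in [24, 42]
        p68 <- runif(n, 40, 52)
        p93 <- p68 + runif(n, 7, 23)        # SN in [7, 23]
        V <- cbind(runif(n, 0, 1.5), runif(n, 0, 1.5), runif(n, 12, 18),
            p26, p63, p68, p93, runif(n, 99, 100), runif(n, 99, 100))
        V %*% .interpWeights(c(1L, 3L, 10L, 26L, 63L, 68L, 93L, 110L,
            112L))
    },
    shrimp_shell = function(n) {
        # bright reddish shell: visible values high, SV ~ [-3, 17] lies in
        # neither visible interval -> caught at stage 1
        p26 <- runif(n, 55, 65)
        p63 <- runif(n, 62, 72)
        V <- cbind(runif(n, 0, 1.5), runif(n, 0, 1.5), runif(n, 30, 45),
            p26, runif(n, 99, 100), runif(n, 99, 100), p63,
            runif(n, 64, 74), runif(n, 70, 82), runif(n, 75, 85))
        V %*% .interpWeights(c(1L, 3L, 15L, 26L, 39L, 41L, 63L, 68L, 93L,
            112L))
    },
    plastic = function(n) {
        # seaweed-like at the four configured bands (stage 1 calls it
        # seaweed) but with out-of-envelope excursions near 600-645 nm
        # (+42) and 785-805 nm (-28): the stage-2-only case
        shape <- .shapeSamplers$seaweed(n)
        shape[, 38:46] <- shape[, 38:46] + 42
        shape[, 72:76] <- shape[, 72:76] - 28
        shape
    },
    insect = function(n) {
        # dark, spectrally flat bug: SV ~ [-3, 8] outside both intervals
        p26 <- runif(n, 35, 45)
        p63 <- p26 + runif(n, -3, 8)
        p68 <- runif(n, 48, 58)
        V <- cbind(runif(n, 0, 1.5), runif(n, 0, 1.5), runif(n, 30, 40),
            p26, runif(n, 45, 55), p63, p68, p68 + runif(n, -4, 6),
            runif(n, 99, 100), runif(n, 99, 100))
        V %*% .interpWeights(c(1L, 3L, 20L, 26L, 50L, 63L, 68L, 93L, 110L,
            112L))
    },
    thread = function(n) {
        # dark thread blending with seaweed: near-seaweed shape but
        # SV ~ [49, 57], in the gap between the two visible intervals
        p26 <- runif(n, 9, 14)
        p63 <- p26 + runif(n, 49, 57)
        p68 <- runif(n, 88, 96)
        p93 <- p68 + runif(n, -27, -8)
        V <- cbind(runif(n, 0, 1.5), runif(n, 0, 1.5), runif(n, 2, 6),
            p26, p63, runif(n, 99, 100), runif(n, 99, 100), p68, p93,
            p93 - runif(n, 3, 8))
        V %*% .interpWeights(c(1L, 3L, 10L, 26L, 63L, 65L, 67L, 68L, 93L,
            112L))
    })

#' Build the synthetic material library
#'
#' Returns the material definitions plus the radiometric parameters of the
#' simulated camera. The constructed per-norm ranges are checked against
#' \code{config}: seaweed and belt draws (including the worst-case diffuse
#' boost) must land inside the configured class intervals, and every
#' foreign material's visible subtraction value must fall outside both —
#' infeasible combinations error.
#'
#' @param config a [SubtractionConfig-class] the library must satisfy
#'   (default: the bundled operating point).
#' @param boostProb probability that a seaweed pixel shows a diffuse
#'   reflection boost (default 0.25).
#' @param boostAmpRange additive DN boost range over 500-680 nm.
#' @param gainRange per-pixel multiplicative illumination gain range.
#' @param noiseSd additive DN noise standard deviation.
#' @param darkLevel,whiteLevel,dnScale dark-current DN, white-reference DN
#'   and full-scale signal DN of the simulated sensor.
#' @return a material library (list) consumed by [renderScene()] and
#'   [referencePixels()]
#' @export
makeMaterials <- function(config = defaultSubtractionConfig(),
                          boostProb = 0.25, boostAmpRange = c(40, 110),
                          gainRange = c(0.8, 1.25), noiseSd = 4,
                          darkLevel = 96, whiteLevel = 3600,
                          dnScale = 2500) {
    # worst-case per-norm shift of a boosted band, and worst-case
    # renormalization factor from the jittered extreme anchors
    shift <- 100 * max(boostAmpRange) / (dnScale * min(gainRange))
    f <- 100 / 97.5
    inIv <- function(rng, iv) rng[1L] >= iv[1L] && rng[2L] <= iv[2L]
    feasible <-
        inIv(c(67 - shift, 77 * f), config@visibleIntervals$seaweed) &&
        inIv(c(-27 * f, -8), config@nirIntervals$seaweed) &&
        inIv(c(24, 42 * f), config@visibleIntervals$belt) &&
        inIv(c(7, 23 * f), config@nirIntervals$belt)
    outsideVis <- function(rng)
        (rng[2L] < config@visibleIntervals$belt[1L] ||
         rng[1L] > config@visibleIntervals$belt[2L]) &&
        (rng[2L] < config@visibleIntervals$seaweed[1L] ||
         rng[1L] > config@visibleIntervals$seaweed[2L])
    # foreign materials carry no diffuse boost, so no boost shift applies
    feasible <- feasible && outsideVis(c(-3 * f, 17 * f)) &&  # shrimp
        outsideVis(c(-3 * f, 8 * f)) &&                       # insect
        outsideVis(c(49, 57 * f))                             # thread
    if (!feasible)
        stop("material construction infeasible for the given subtraction ",
            "config / camera parameters")
    list(wavelengths = .SYNTH_WL, samplers = .shapeSamplers,
        boostProb = c(seaweed = boostProb, belt = 0, shrimp_shell = 0,
            plastic = 0, insect = 0, thread = 0),
        boostAmpRange = boostAmpRange, gainRange = gainRange,
        noiseSd = noiseSd, darkLevel = darkLevel, whiteLevel = whiteLevel,
        dnScale = dnScale,
        boostBands = which(.SYNTH_WL >= 500 & .SYNTH_WL <= 680))
}

# Draw n raw DN spectra of one material (n x bands), dark current included.
.sampleDN <- function(material, n, materials, boost = TRUE) {
    sampler <- materials$samplers[[material]]
    if (is.null(sampler)) stop("unknown material: ", material)
    shape <- sampler(n)
    gain <- runif(n, materials$gainRange[1L], materials$gainRange[2L])
    dn <- shape / 100 * (gain * materials$dnScale)
    p <- if (boost) materials$boostProb[[material]] else 0
    if (p > 0) {
        boosted <- runif(n) < p
        amp <- runif(n, materials$boostAmpRange[1L],
            materials$boostAmpRange[2L]) * boosted
        dn[, materials$boostBands] <- dn[, materials$boostBands] + amp
    }
    dn <- dn + materials$darkLevel +
        matrix(rnorm(n * ncol(dn), sd = materials$noiseSd), n)
    dn <- round(dn)
    dn[dn < 0] <- 0
    dn
}

.withSeed <- function(seed, expr) {
    hasSeed <- exists(".Random.seed", envir = globalenv())
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Draw calibrated reference pixels of one material
#'
#' Renders \code{n} single-pixel DN spectra of \code{material} through the
#' simulated camera (gain jitter, optional diffuse boost, noise, dark
#' current) and applies Per-Norm. This is the source of the labeled
#' reference sets that [buildProfile()] and [samTrainingSet()] consume.
#'
#' @param material material name from the library.
#' @param n number of pixels.
#' @param seed RNG seed.
#' @param materials library from [makeMaterials()].
#' @param boost include diffuse-reflection boosts (default TRUE; disable to
#'   emulate training pixels picked from non-specular regions).
#' @return numeric matrix (n x 112) of Per-Norm spectra
#' @export
referencePixels <- function(material, n, seed,
                            materials = makeMaterials(), boost = TRUE) {
    dn <- .withSeed(seed, .sampleDN(material, n, materials, boost))
    dn <- dn - materials$darkLevel
    dn[dn < 0] <- 0
    mn <- do.call(pmin, as.data.frame(dn))
    mx <- do.call(pmax, as.data.frame(dn))
    (dn - mn) / (mx - mn) * 100
}

#' Construct a scene specification
#'
#' @param sheetShape \code{"rectangular"} (26 cm along the belt) or
#'   \code{"square"} (20 cm); both are 20 cm across.
#' @param beltSpeed conveyor speed in cm/s (default 30).
#' @param lineRate camera line rate in lines/s (default 300; together with
#'   the default belt speed this gives 1 mm per line).
#' @param pixelPitchMm across-track pitch in mm/sample (default 0.25: a
#'   20 cm sheet spans ~800 of the 1024 default samples, leaving belt
#'   margins for the ignored zone).
#' @param samples spatial samples per line (default 1024).
#' @param marginLines belt-only lines before and after the sheet.
#' @param foreignObjects list of \code{list(material=, line=, sample=,
#'   height=, width=)} in sheet-relative pixels.
#' @param seed integer seed; fixed seed gives a bit-identical scene.
#' @return a [SceneSpec-class]
#' @export
sceneSpec <- function(sheetShape = c("rectangular", "square"),
                      beltSpeed = 30, lineRate = 300, pixelPitchMm = 0.25,
                      samples = 1024L, marginLines = 16L,
                      foreignObjects = list(), seed = 1L) {
    sheetShape <- match.arg(sheetShape)
    new("SceneSpec", sheetShape = sheetShape, beltSpeed = beltSpeed,
        lineRate = lineRate, pixelPitchMm = pixelPitchMm,
        samples = as.integer(samples), marginLines = as.integer(marginLines),
        foreignObjects = foreignObjects, seed = as.integer(seed))
}

# Sheet extent in raster pixels implied by a scene spec.
.sheetGeometry <- function(spec) {
    lengthCm <- if (spec@sheetShape == "rectangular") 26 else 20
    widthCm <- 20
    sheetLines <- round(lengthCm / spec@beltSpeed * spec@lineRate)
    sheetSamples <- round(widthCm * 10 / spec@pixelPitchMm)
    list(sheetLines = as.integer(sheetLines),
        sheetSamples = as.integer(sheetSamples),
        lines = as.integer(sheetLines + 2L * spec@marginLines),
        firstLine = spec@marginLines + 1L,
        firstSample = as.integer((spec@samples - sheetSamples) %/% 2 + 1L))
}

#' Render a synthetic conveyor scene
#'
#' Produces a raw DN [HyperCube-class] of a seaweed sheet centered on a
#' conveyor belt, line by line at the spec geometry, together with the
#' ground-truth material mask and dark/white reference frames consistent
#' with [reflectanceNorm()] expectations. Output is deterministic for a
#' fixed \code{seed}.
#'
#' @param spec a [SceneSpec-class]
#' @param materials library from [makeMaterials()]
#' @return list with \code{cube}, \code{mask} (character matrix of
#'   material names), \code{dark} and \code{white}
#'   ([ReferenceFrame-class]), and \code{geometry}
#' @export
renderScene <- function(spec, materials = makeMaterials()) {
    geom <- .sheetGeometry(spec)
    if (geom$sheetSamples > spec@samples)
        stop("geometry overflow: sheet spans ", geom$sheetSamples,
            " samples but the line has only ", spec@samples)
    nb <- length(materials$wavelengths)
    mask <- matrix("belt", geom$lines, spec@samples)
    rows <- geom$firstLine:(geom$firstLine + geom$sheetLines - 1L)
    cols <- geom$firstSample:(geom$firstSample + geom$sheetSamples - 1L)
    mask[rows, cols] <- "seaweed"
    for (fo in spec@foreignObjects) {
        r0 <- geom$firstLine + fo$line - 1L
        c0 <- geom$firstSample + fo$sample - 1L
        r1 <- r0 + fo$height - 1L
        c1 <- c0 + fo$width - 1L
        if (r0 < 1L || c0 < 1L || r1 > geom$lines || c1 > spec@samples)
            stop("foreign object '", fo$material, "' outside raster extent")
        mask[r0:r1, c0:c1] <- fo$material
    }
    arr <- array(0, c(geom$lines, spec@samples, nb))
    .withSeed(spec@seed, {
        for (mat in c("seaweed", "belt", "shrimp_shell", "plastic",
                      "insect", "thread")) {
            sel <- which(mask == mat)
            if (!length(sel)) next
            dn <- .sampleDN(mat, length(sel), materials)
            for (b in seq_len(nb))
                arr[sel + (b - 1L) * length(mask)] <- dn[, b]
        }
    })
    cube <- HyperCube(arr, materials$wavelengths,
        meta = list(lineRate = spec@lineRate))
    dark <- ReferenceFrame(rep(materials$darkLevel, nb),
        kind = "dark_current")
    white <- ReferenceFrame(rep(materials$whiteLevel, nb),
        kind = "white_reference")
    list(cube = cube, mask = mask, dark = dark, white = white,
        geometry = geom)
}

#' Build a synthetic benchmark of clean and contaminated sheets
#'
#' Generates scene specifications for \code{nClean} normal sheets and
#' \code{nContaminated} sheets carrying 1-3 foreign objects of mixed
#' materials (each at least 1 sample across and 1 line long), alternating
#' rectangular and square sheet shapes. The manifest records the ground
#' truth per scene.
#'
#' @param nClean,nContaminated scene counts.
#' @param seed master seed; per-scene seeds are derived from it.
#' @param samples,pixelPitchMm,lineRate,beltSpeed,marginLines scene
#'   geometry shared by all scenes (defaults give a compact raster: a
#'   20 cm sheet spans 200 of 256 samples and 50 lines).
#' @return list with \code{scenes} (list of [SceneSpec-class]) and
#'   \code{manifest} (data.frame: scene, shape, contaminated, nObjects,
#'   materials, seed)
#' @export
makeBenchmark <- function(nClean, nContaminated, seed = 1L,
                          samples = 256L, pixelPitchMm = 1,
                          lineRate = 75, beltSpeed = 30,
                          marginLines = 8L) {
    stopifnot(nClean >= 0, nContaminated >= 0)
    total <- nClean + nContaminated
    if (total == 0L)
        return(list(scenes = list(),
            manifest = data.frame(scene = integer(), shape = character(),
                contaminated = logical(), nObjects = integer(),
                materials = character(), seed = integer())))
    foreignMats <- c("shrimp_shell", "plastic", "insect", "thread")
    scenes <- vector("list", total)
    rows <- vector("list", total)
    .withSeed(seed, {
        sceneSeeds <- sample.int(2^31 - 1L, total)
        contaminated <- rep(c(FALSE, TRUE), c(nClean, nContaminated))
        for (i in seq_len(total)) {
            shape <- if (i %% 2L == 1L) "rectangular" else "square"
            probe <- sceneSpec(shape, beltSpeed = beltSpeed,
                lineRate = lineRate, pixelPitchMm = pixelPitchMm,
                samples = samples, marginLines = marginLines,
                seed = sceneSeeds[i])
            geom <- .sheetGeometry(probe)
            objs <- list()
            if (contaminated[i]) {
                nObj <- sample(1:3, 1L)
                for (k in seq_len(nObj)) {
                    h <- sample(2:5, 1L)
                    w <- sample(2:5, 1L)
                    objs[[k]] <- list(
                        material = sample(foreignMats, 1L),
                        line = sample.int(geom$sheetLines - h, 1L),
                        sample = sample.int(geom$sheetSamples - w, 1L),
                        height = h, width = w)
                }
            }
            scenes[[i]] <- initialize(probe, foreignObjects = objs)
            rows[[i]] <- data.frame(scene = i, shape = shape,
                contaminated = contaminated[i], nObjects = length(objs),
                materials = paste(vapply(objs, `[[`, "", "material"),
                    collapse = ","),
                seed = sceneSeeds[i])
        }
    })
    list(scenes = scenes, manifest = do.call(rbind, rows))
}
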