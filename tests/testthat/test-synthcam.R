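test_that("a fixed seed reproduces a scene bit for bit, and ENVI output is byte-identical", {
    mats <- ksMaterials()
    a <- renderScene(ksSmallScene(seed = 91), mats)
    b <- renderScene(ksSmallScene(seed = 91), mats)
    expect_identical(cubeData(a$cube), cubeData(b$cube))
    expect_identical(a$mask, b$mask)
    dir <- withr::local_tempdir()
    writeENVI(a$cube, file.path(dir, "a"))
    writeENVI(b$cube, file.path(dir, "b"))
    expect_identical(readBin(file.path(dir, "a"), "raw", 1e7),
        readBin(file.path(dir, "b"), "raw", 1e7))
    c <- renderScene(ksSmallScene(seed = 92), mats)
    expect_false(identical(cubeData(a$cube), cubeData(c$cube)))
})

test_that("scene geometry follows belt speed, line rate and pixel pitch", {
    # 26 cm sheet at 300 lines/s and 30 cm/s spans 260 lines
    spec <- sceneSpec("rectangular", beltSpeed = 30, lineRate = 300,
        pixelPitchMm = 4, samples = 64L, marginLines = 4L, seed = 1)
    scene <- renderScene(spec, ksMaterials())
    expect_equal(scene$geometry$sheetLines, 260L)
    expect_equal(nLines(scene$cube), 260L + 8L)
    # a 20 cm wide sheet at 4 mm pitch spans 50 samples
    expect_equal(scene$geometry$sheetSamples, 50L)
    # clean scene mask contains only seaweed and belt
    expect_setequal(unique(as.vector(scene$mask)), c("seaweed", "belt"))
    # sheet wider than the line is a geometry overflow
    tooWide <- sceneSpec("square", pixelPitchMm = 1, samples = 64L, seed = 1)
    expect_error(renderScene(tooWide, ksMaterials()), "overflow")
})

test_that("foreign objects land in the mask at their sheet-relative position", {
    obj <- list(material = "insect", line = 3L, sample = 7L,
        height = 2L, width = 4L)
    scene <- renderScene(ksSmallScene(seed = 93,
        foreignObjects = list(obj)), ksMaterials())
    g <- scene$geometry
    rows <- g$firstLine + 2L + 0:1
    cols <- g$firstSample + 6L + 0:3
    expect_true(all(scene$mask[rows, cols] == "insect"))
    expect_equal(sum(scene$mask == "insect"), 8L)
    # out-of-extent object errors
    bad <- list(material = "thread", line = 10000L, sample = 1L,
        height = 2L, width = 2L)
    expect_error(renderScene(ksSmallScene(seed = 93,
        foreignObjects = list(bad)), ksMaterials()), "outside")
})

test_that("seaweed and belt draws land inside the operating-point intervals", {
    cfg <- defaultSubtractionConfig()
    sw <- referencePixels("seaweed", 1000, seed = 601,
        materials = ksMaterials())
    f <- subtractionFeatures(sw, cfg)
    expect_true(all(f$sv >= 60 & f$sv <= 80))
    expect_true(all(f$sn >= -30 & f$sn <= -5))
    bt <- referencePixels("belt", 1000, seed = 602,
        materials = ksMaterials())
    fb <- subtractionFeatures(bt, cfg)
    expect_true(all(fb$sv >= 20 & fb$sv <= 45))
    expect_true(all(fb$sn >= 5 & fb$sn <= 25))
})

test_that("plastic evades stage 1 but is fully caught by the stage-2 envelope", {
    cfg <- defaultSubtractionConfig()
    pl <- referencePixels("plastic", 1000, seed = 603,
        materials = ksMaterials())
    f <- subtractionFeatures(pl, cfg)
    lab <- stage1Classify(f$sv, f$sn, cfg)
    expect_equal(mean(lab == "foreign"), 0)
    profs <- ksProfiles()
    expect_equal(mean(stage2Inspect(pl, profs$seaweed, margin = 3)), 1)
    expect_equal(mean(stage2Inspect(pl, profs$belt, margin = 3)), 1)
})

test_that("the diffuse-reflection boost raises DN only within 500-680 nm", {
    mats <- makeMaterials(boostProb = 1, noiseSd = 0,
        gainRange = c(1, 1))
    set.seed(42)
    boosted <- kelpscan:::.sampleDN("seaweed", 50, mats, boost = TRUE)
    set.seed(42)
    plain <- kelpscan:::.sampleDN("seaweed", 50, mats, boost = FALSE)
    diff <- boosted - plain
    wl <- mats$wavelengths
    inBoost <- wl >= 500 & wl <= 680
    expect_true(all(diff[, inBoost] > 0))
    expect_true(all(diff[, !inBoost] == 0))
})

test_that("infeasible material constraints are rejected", {
    cfg <- subtractionConfig(c(26L, 63L), c(68L, 93L),
        visibleIntervals = list(seaweed = c(70, 80), belt = c(20, 45)),
        nirIntervals = list(seaweed = c(-30, -5), belt = c(5, 25)))
    expect_error(makeMaterials(cfg), "infeasible")
})

test_that("benchmarks enumerate scenes with ground truth and minimum object sizes", {
    bench <- makeBenchmark(4, 3, seed = 7)
    expect_length(bench$scenes, 7L)
    expect_equal(sum(bench$manifest$contaminated), 3L)
    expect_equal(sum(!bench$manifest$contaminated), 4L)
    nObjs <- vapply(bench$scenes, function(s) length(s@foreignObjects), 0L)
    expect_true(all(nObjs[bench$manifest$contaminated] >= 1L))
    expect_true(all(nObjs[bench$manifest$contaminated] <= 3L))
    expect_true(all(nObjs[!bench$manifest$contaminated] == 0L))
    # alternating sheet shapes
    expect_equal(bench$manifest$shape[1:4],
        c("rectangular", "square", "rectangular", "square"))
    for (s in bench$scenes) for (fo in s@foreignObjects) {
        expect_gte(fo$height, 1L)
        expect_gte(fo$width, 1L)
    }
    empty <- makeBenchmark(0, 0)
    expect_length(empty$scenes, 0L)
    expect_equal(nrow(empty$manifest), 0L)
    # same master seed reproduces the same benchmark
    again <- makeBenchmark(4, 3, seed = 7)
    expect_identical(bench$manifest, again$manifest)
})
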