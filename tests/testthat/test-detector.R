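specWith <- function(vals, nb = 112L) {
    x <- rep(50, nb)
    x[as.integer(names(vals))] <- vals
    x
}

test_that("subtraction features are the configured band differences", {
    cfg <- defaultSubtractionConfig()
    px <- specWith(c(`26` = 20, `63` = 85, `68` = 90, `93` = 70))
    f <- subtractionFeatures(px, cfg)
    expect_equal(unname(f$sv), 65)
    expect_equal(unname(f$sn), -20)
    flat <- rep(7, 112)
    f0 <- subtractionFeatures(flat, cfg)
    expect_equal(unname(c(f0$sv, f0$sn)), c(0, 0))
    small <- matrix(1, 2, 50)
    expect_error(subtractionFeatures(small, cfg), "band index")
})

test_that("stage-1 rule: interval membership decides, visible range wins, gaps are foreign", {
    cfg <- defaultSubtractionConfig()
    lab <- stage1Classify(c(65, 30, 50, 65, 30), c(-20, 15, -20, 15, -20),
        cfg)
    expect_equal(as.character(lab),
        c("seaweed",   # SV and SN both seaweed
          "belt",      # SV and SN both belt
          "foreign",   # SV in neither interval
          "seaweed",   # SV seaweed, SN belt: visible decides
          "belt"))     # SV belt, SN seaweed: visible decides
    expect_equal(attr(lab, "disagreements"), 2L)
    # SN outside both NIR intervals is foreign even with a clean SV
    expect_equal(as.character(stage1Classify(65, 0, cfg)), "foreign")
})

test_that("stage-1 labels depend only on the four configured bands", {
    cfg <- defaultSubtractionConfig()
    set.seed(19)
    px <- referencePixels("seaweed", 20, seed = 301,
        materials = ksMaterials())
    f <- subtractionFeatures(px, cfg)
    lab <- stage1Classify(f$sv, f$sn, cfg)
    keep <- c(cfg@visiblePair, cfg@nirPair)
    others <- setdiff(seq_len(112L), keep)
    perm <- px
    perm[, others] <- px[, sample(others)]
    fp <- subtractionFeatures(perm, cfg)
    expect_equal(stage1Classify(fp$sv, fp$sn, cfg)[], lab[])
})

test_that("ignored zone is the belt outside the seaweed bounding box", {
    labels <- matrix("belt", 10, 20)
    labels[3:8, 5:15] <- "seaweed"
    labels[5, 9] <- "foreign"
    ign <- ignoredZone(labels, "outside_sheet_bbox")
    expect_true(all(ign[, c(1:4, 16:20)][labels[, c(1:4, 16:20)] == "belt"]))
    expect_false(any(ign[3:8, 5:15]))
    expect_false(any(ign[labels == "foreign"]))
    # rows outside the box are ignored too
    expect_true(all(ign[c(1:2, 9:10), 1]))
    expect_equal(ignoredZone(labels, "none"),
        matrix(FALSE, 10, 20))
    allBelt <- matrix("belt", 4, 4)
    expect_warning(ignAll <- ignoredZone(allBelt), "ignored")
    expect_true(all(ignAll))
})

test_that("stage-2 flags exactly the out-of-envelope pixels, monotonically in margin", {
    profs <- ksProfiles()
    p <- profs$seaweed
    expect_false(stage2Inspect(p@mu, p, margin = 0))
    # one band just past the widened envelope flips the pixel
    b <- 40L
    x <- p@mu
    x[b] <- p@mu[b] + p@sigma[b] * (p@envHigh[b] + 3 + 0.1)
    expect_true(stage2Inspect(x, p, margin = 3))
    x[b] <- p@mu[b] + p@sigma[b] * (p@envHigh[b] + 3 - 0.1)
    expect_false(stage2Inspect(x, p, margin = 3))
    # margin monotonicity on a mixed pixel set
    px <- rbind(ksRefPixels()$seaweed[1:2000, ],
        referencePixels("plastic", 200, seed = 401,
            materials = ksMaterials()))
    flagged <- lapply(c(0, 1, 3, 5), function(m)
        which(stage2Inspect(px, p, margin = m)))
    for (k in 2:4)
        expect_true(all(flagged[[k]] %in% flagged[[k - 1]]))
})

test_that("whole-sheet detection separates clean, stage-1 and stage-2-only contamination", {
    mats <- ksMaterials()
    profs <- ksProfiles()
    params <- detectorParams()
    clean <- renderScene(ksSmallScene(seed = 31), mats)
    res <- detectSheet(perNorm(clean$cube, clean$dark), profs, params)
    expect_equal(res$verdict@decision, "accept")
    expect_equal(res$verdict@foreignPixelCount, 0L)

    shrimp <- renderScene(ksSmallScene(seed = 32, foreignObjects = list(
        list(material = "shrimp_shell", line = 5L, sample = 10L,
            height = 3L, width = 3L))), mats)
    res <- detectSheet(perNorm(shrimp$cube, shrimp$dark), profs, params)
    expect_equal(res$verdict@decision, "reject")
    expect_gte(res$verdict@stage1Count, 9L)
    expect_equal(res$verdict@foreignComponents, 1L)

    plastic <- renderScene(ksSmallScene(seed = 33, foreignObjects = list(
        list(material = "plastic", line = 5L, sample = 10L,
            height = 3L, width = 3L))), mats)
    res <- detectSheet(perNorm(plastic$cube, plastic$dark), profs, params)
    expect_equal(res$verdict@decision, "reject")
    expect_equal(res$verdict@stage1Count, 0L)   # invisible to stage 1
    expect_equal(res$verdict@stage2Count, 9L)   # fully caught at stage 2
})

test_that("profile/cube band mismatches and wrong calibrations are refused", {
    mats <- ksMaterials()
    scene <- renderScene(ksSmallScene(seed = 35), mats)
    pn <- perNorm(scene$cube, scene$dark)
    short <- buildProfile(ksRefPixels()$seaweed[1:100, 1:56], "seaweed")
    expect_error(
        detectSheet(pn, list(seaweed = short, belt = ksProfiles()$belt)),
        "bands")
    refl <- reflectanceNorm(scene$cube, scene$dark, scene$white)
    expect_error(detectSheet(refl, ksProfiles()), "Per-Norm")
})

test_that("class maps render with the black/white/red palette", {
    labels <- matrix("seaweed", 3, 4)
    labels[1, 1] <- "belt"
    labels[2, 3] <- "foreign"
    map <- new("ClassMap", labels = labels,
        ignored = matrix(FALSE, 3, 4), stage1Only = matrix(FALSE, 3, 4))
    img <- renderClassMap(map)
    expect_equal(img[1, 1, ], c(1, 1, 1))   # belt: white
    expect_equal(img[2, 3, ], c(1, 0, 0))   # foreign: red
    expect_equal(img[3, 4, ], c(0, 0, 0))   # seaweed: black
    # palette histogram equals label histogram
    expect_equal(sum(img[, , 1] == 1 & img[, , 2] == 0),
        sum(labels == "foreign"))
    expect_equal(sum(img[, , 1] == 0), sum(labels == "seaweed"))
})

test_that("verdict counts 4-connected foreign components and honors the reject threshold", {
    mats <- ksMaterials()
    profs <- ksProfiles()
    two <- renderScene(ksSmallScene(seed = 36, foreignObjects = list(
        list(material = "insect", line = 3L, sample = 5L, height = 2L,
            width = 2L),
        list(material = "thread", line = 10L, sample = 30L, height = 1L,
            width = 4L))), mats)
    pn <- perNorm(two$cube, two$dark)
    res <- detectSheet(pn, profs, detectorParams())
    expect_equal(res$verdict@foreignComponents, 2L)
    # a reject threshold above the foreign count accepts the sheet
    lax <- detectorParams(minForeignPixels = 1000L)
    res2 <- detectSheet(pn, profs, lax)
    expect_equal(res2$verdict@decision, "accept")
    expect_equal(res2$verdict@foreignPixelCount,
        res$verdict@foreignPixelCount)
})
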