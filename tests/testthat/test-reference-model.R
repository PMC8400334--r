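test_that("profiles use population sd and min/max standardized envelopes", {
    p <- buildProfile(rbind(c(0, 10), c(10, 0)), "seaweed")
    expect_equal(p@mu, c(5, 5))
    expect_equal(p@sigma, c(5, 5))     # population, not sample, sd
    expect_equal(p@envLow, c(-1, -1))
    expect_equal(p@envHigh, c(1, 1))
    expect_equal(p@nPixels, 2L)
})

test_that("constant bands are refused with the band named", {
    px <- rbind(c(1, 5, 9), c(1, 7, 3), c(1, 6, 6))
    expect_error(buildProfile(px, "belt"), "band\\(s\\): 1")
    expect_error(buildProfile(px[1, , drop = FALSE], "belt"), "at least 2")
})

test_that("standardization maps mu to 0, mu + k sigma to k", {
    ref <- ksRefPixels()$seaweed[1:500, ]
    p <- buildProfile(ref, "seaweed")
    expect_equal(standardize(p@mu, p), rep(0, length(p@mu)))
    expect_equal(standardize(p@mu + p@sigma, p), rep(1, length(p@mu)))
    expect_equal(standardize(p@mu - 2 * p@sigma, p),
        rep(-2, length(p@mu)))
    expect_error(standardize(p@mu[-1], p), "bands")
})

test_that("every reference pixel lies inside its own envelope and the envelope grows monotonically", {
    ref <- ksRefPixels()$belt
    p <- buildProfile(ref, "belt")
    z <- standardize(ref, p)
    expect_true(all(sweep(z, 2, p@envLow, ">=")))
    expect_true(all(sweep(z, 2, p@envHigh, "<=")))
    expect_true(all(p@envLow <= 0) && all(p@envHigh >= 0))
    # enlarging the reference set can only widen the envelope
    pHalf <- buildProfile(ref[1:5000, ], "belt")
    zFull <- standardize(ref, pHalf)  # same mu/sigma basis
    expect_true(all(apply(zFull, 2, min) <= pHalf@envLow + 1e-12))
    expect_true(all(apply(zFull, 2, max) >= pHalf@envHigh - 1e-12))
})

bruteForcePair <- function(muA, muB, idx) {
    best <- NULL
    for (i in idx) for (j in idx) {
        if (i >= j) next
        s <- abs((muA[j] - muA[i]) - (muB[j] - muB[i]))
        if (is.null(best) || s > best$separation)
            best <- list(bandLo = i, bandHi = j, separation = s)
    }
    best
}

test_that("band-pair search returns a constructed argmax and pins ties", {
    nb <- 20L
    wl <- seq(400, 750, length.out = nb)
    mk <- function(mu) new("ReferenceProfile", className = "seaweed",
        mu = mu, sigma = rep(1, nb), envLow = rep(-1, nb),
        envHigh = rep(1, nb), nPixels = 10L, wavelengths = wl)
    # profiles differing only at bands 7 and 15 -> that pair wins
    muA <- rep(10, nb); muA[7] <- 0; muA[15] <- 30
    muB <- rep(10, nb)
    res <- selectBandPair(mk(muA), mk(muB), c(400, 750), wl)
    expect_equal(c(res$bandLo, res$bandHi), c(7L, 15L))
    expect_equal(res$separation, abs((30 - 10) - (0 - 10)))  # = 30
    # identical profiles: separation 0, lexicographically first pair
    res0 <- selectBandPair(mk(muB), mk(muB), c(400, 750), wl)
    expect_equal(res0$separation, 0)
    expect_equal(c(res0$bandLo, res0$bandHi), c(1L, 2L))
    expect_error(selectBandPair(mk(muA), mk(muB), c(400, 401), wl),
        "fewer than 2")
})

test_that("band-pair search equals independent brute force on random profiles", {
    nb <- 20L
    wl <- seq(400, 1000, length.out = nb)
    set.seed(77)
    for (trial in 1:25) {
        muA <- runif(nb, 0, 100)
        muB <- runif(nb, 0, 100)
        mk <- function(mu) new("ReferenceProfile", className = "belt",
            mu = mu, sigma = rep(1, nb), envLow = rep(-1, nb),
            envHigh = rep(1, nb), nPixels = 5L, wavelengths = wl)
        rng <- sort(runif(2, 400, 1000))
        idx <- which(wl >= rng[1] & wl <= rng[2])
        if (length(idx) < 2) next
        got <- selectBandPair(mk(muA), mk(muB), rng, wl)
        want <- bruteForcePair(muA, muB, idx)
        expect_equal(got, want)
    }
})

test_that("interval derivation recovers generator ranges and rejects overlap", {
    cfg <- defaultSubtractionConfig()
    set.seed(5)
    nb <- 112L
    mkPixels <- function(n, svRange, snRange) {
        px <- matrix(50, n, nb)
        sv <- runif(n, svRange[1], svRange[2])
        sn <- runif(n, snRange[1], snRange[2])
        px[, cfg@visiblePair[2]] <- px[, cfg@visiblePair[1]] + sv
        px[, cfg@nirPair[2]] <- px[, cfg@nirPair[1]] + sn
        list(px = px, sv = sv, sn = sn)
    }
    sw <- mkPixels(400, c(62, 78), c(-28, -6))
    bt <- mkPixels(400, c(21, 44), c(6, 24))
    derived <- deriveIntervals(cfg, list(seaweed = sw$px, belt = bt$px))
    expect_equal(derived@visibleIntervals$seaweed, range(sw$sv))
    expect_equal(derived@nirIntervals$belt, range(bt$sn))
    # recovered intervals sit inside the generating ranges
    expect_true(derived@visibleIntervals$belt[1] >= 21 &&
        derived@visibleIntervals$belt[2] <= 44)
    # slack widens symmetrically
    slacked <- deriveIntervals(cfg, list(seaweed = sw$px, belt = bt$px),
        slack = 2)
    expect_equal(slacked@visibleIntervals$seaweed, range(sw$sv) + c(-2, 2))
    # overlapping classes are not separable
    btBad <- mkPixels(100, c(50, 70), c(6, 24))
    expect_error(
        deriveIntervals(cfg, list(seaweed = sw$px, belt = btBad$px)),
        "not separable")
    # one-pixel class: zero-width interval with a warning
    expect_warning(
        one <- deriveIntervals(cfg, list(seaweed = sw$px,
            belt = bt$px[1, , drop = FALSE])),
        "one-pixel")
    expect_equal(one@visibleIntervals$belt[1], one@visibleIntervals$belt[2])
})

test_that("the bundled config carries the documented operating point", {
    cfg <- defaultSubtractionConfig()
    expect_equal(cfg@visiblePair, c(26L, 63L))
    expect_equal(cfg@nirPair, c(68L, 93L))
    expect_equal(cfg@visibleIntervals$seaweed, c(60, 80))
    expect_equal(cfg@visibleIntervals$belt, c(20, 45))
    expect_equal(cfg@nirIntervals$seaweed, c(-30, -5))
    expect_equal(cfg@nirIntervals$belt, c(5, 25))
})

test_that("profiles round-trip through the plain-text table", {
    profs <- ksProfiles()
    path <- file.path(withr::local_tempdir(), "profiles.tsv")
    writeProfiles(profs, path)
    back <- readProfiles(path)
    expect_equal(back$seaweed@mu, profs$seaweed@mu)
    expect_equal(back$belt@envHigh, profs$belt@envHigh)
    expect_equal(back$seaweed@nPixels, profs$seaweed@nPixels)
})
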