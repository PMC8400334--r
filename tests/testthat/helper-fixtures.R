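# Shared fixtures, built once per test run and cached.

.ksCache <- new.env(parent = emptyenv())

ksMaterials <- function() {
    if (is.null(.ksCache$mats)) .ksCache$mats <- makeMaterials()
    .ksCache$mats
}

# 10,000-pixel labeled reference sets (the scale the reference model is
# designed around) and the profiles built from them.
ksRefPixels <- function() {
    if (is.null(.ksCache$ref))
        .ksCache$ref <- list(
            seaweed = referencePixels("seaweed", 10000, seed = 101,
                materials = ksMaterials()),
            belt = referencePixels("belt", 10000, seed = 102,
                materials = ksMaterials()))
    .ksCache$ref
}

ksProfiles <- function() {
    if (is.null(.ksCache$profs)) {
        ref <- ksRefPixels()
        .ksCache$profs <- list(
            seaweed = buildProfile(ref$seaweed, "seaweed"),
            belt = buildProfile(ref$belt, "belt"))
    }
    .ksCache$profs
}

# SAM training set: boost-free seaweed/belt plus mixed foreign materials.
ksSamTrain <- function() {
    if (is.null(.ksCache$train)) {
        m <- ksMaterials()
        px <- rbind(
            referencePixels("seaweed", 150, seed = 201, materials = m,
                boost = FALSE),
            referencePixels("belt", 150, seed = 202, materials = m),
            referencePixels("shrimp_shell", 25, seed = 203, materials = m),
            referencePixels("plastic", 25, seed = 204, materials = m),
            referencePixels("insect", 25, seed = 205, materials = m),
            referencePixels("thread", 25, seed = 206, materials = m))
        .ksCache$train <- samTrainingSet(px,
            rep(c("seaweed", "belt", "foreign"), c(150, 150, 100)))
    }
    .ksCache$train
}

# A small deterministic raw cube for I/O and calibration tests.
ksTinyCube <- function(lines = 4L, samples = 5L, bands = 8L, seed = 3L) {
    set.seed(seed)
    arr <- array(
        as.double(sample.int(4000L, lines * samples * bands,
            replace = TRUE)),
        c(lines, samples, bands))
    HyperCube(arr, wavelengths = seq(400, 1000, length.out = bands))
}

# Compact scene geometry used across detector tests: a 20 cm sheet spanning
# 50 samples and 17 lines.
ksSmallScene <- function(seed, foreignObjects = list(),
                         shape = "square") {
    sceneSpec(shape, samples = 64L, pixelPitchMm = 4, lineRate = 25,
        marginLines = 4L, foreignObjects = foreignObjects, seed = seed)
}
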