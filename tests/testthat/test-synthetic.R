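test_that("makeMultiOmic is reproducible and structurally sound", {
    d1 <- makeMultiOmic(nCells = 40, nTypes = 3, dx = 6, dy = 8,
                        noiseSd = 0.2, seed = 99)
    d2 <- makeMultiOmic(nCells = 40, nTypes = 3, dx = 6, dy = 8,
                        noiseSd = 0.2, seed = 99)
    expect_identical(dataMatrix(d1@X), dataMatrix(d2@X))
    expect_identical(dataMatrix(d1@Y), dataMatrix(d2@Y))
    expect_identical(d1@cellPairs, cbind(1:40, 1:40))
    expect_identical(d1@featurePairs, cbind(1:6, 1:6))
    # labels identical across paired domains
    expect_identical(cellLabels(d1@X), cellLabels(d1@Y))
    expect_equal(nlevels(cellLabels(d1@X)), 3)
    # a different seed gives different data
    d3 <- makeMultiOmic(nCells = 40, nTypes = 3, dx = 6, dy = 8,
                        noiseSd = 0.2, seed = 100)
    expect_false(identical(dataMatrix(d1@X), dataMatrix(d3@X)))
    expect_error(makeMultiOmic(nCells = 2, nTypes = 5), "nTypes")
})

test_that("single-type data make label transfer vacuously perfect", {
    d <- makeMultiOmic(nCells = 20, nTypes = 1, dx = 4, dy = 4,
                       noiseSd = 0.1, seed = 3)
    expect_equal(nlevels(cellLabels(d@X)), 1)
    proj <- barycentricProject(matrix(1 / 400, 20, 20), dataMatrix(d@Y))
    expect_equal(labelTransferAccuracy(dataMatrix(d@Y), cellLabels(d@Y),
                                       proj, cellLabels(d@X)), 1)
})

test_that("noiseless linear domains share their latent geometry", {
    d <- makeMultiOmic(nCells = 30, nTypes = 3, dx = 6, dy = 4,
                       noiseSd = 0, seed = 4, latentDim = 2)
    # complete-graph geodesics = Euclidean distances = scaled latent ones
    DXn <- distValues(normalizeDistances(knnGeodesic(dataMatrix(d@X), 29)))
    DYn <- distValues(normalizeDistances(knnGeodesic(dataMatrix(d@Y), 29)))
    expect_equal(DXn, DYn, tolerance = 1e-10)
    DL <- as.matrix(dist(d@latent))
    expect_equal(DXn, unname(DL / max(DL)), tolerance = 1e-10)
})

test_that("noiseless self-alignment recovers the identity pairing", {
    d <- makeMultiOmic(nCells = 50, nTypes = 3, dx = 8, dy = 8,
                       noiseSd = 0, seed = 5)
    DX <- suppressWarnings(
        normalizeDistances(knnGeodesic(dataMatrix(d@X), 12)))
    DY <- suppressWarnings(
        normalizeDistances(knnGeodesic(dataMatrix(d@Y), 12)))
    r <- suppressWarnings(alignOT("gw", DX = DX, DY = DY,
        config = SolverConfig(alpha = 1, epsGW = 2e-4, nOuter = 20L,
                              innerMaxIter = 2000L, innerTol = 1e-5)))
    rec <- mean(apply(plan(sampleCoupling(r)), 1, which.max) == 1:50)
    expect_gte(rec, 0.95)
})

test_that("downsampleByType removes the drawn per-type fractions", {
    d <- makeMultiOmic(nCells = 60, nTypes = 3, dx = 4, dy = 4,
                       noiseSd = 0.1, seed = 6)
    # maxFraction = 0 leaves the dataset untouched
    ds0 <- downsampleByType(d@X, 0, seed = 1)
    expect_identical(ds0$kept, 1:60)
    expect_identical(dataMatrix(ds0$dataset), dataMatrix(d@X))
    # deterministic under a fixed seed
    a <- downsampleByType(d@X, 0.5, seed = 7)
    b <- downsampleByType(d@X, 0.5, seed = 7)
    expect_identical(a$kept, b$kept)
    # removed counts equal round(f * nType) for the drawn fractions
    set.seed(7)
    expected <- integer(0)
    labels <- cellLabels(d@X)
    for (t in levels(labels)) {
        f <- runif(1, 0, 0.5)
        expected <- c(expected, as.integer(round(f * sum(labels == t))))
        nRemove <- expected[length(expected)]
        if (nRemove > 0) sample(which(labels == t), nRemove)
    }
    got <- as.integer(table(labels) - table(cellLabels(a$dataset)))
    expect_identical(got, expected)
    expect_error(downsampleByType(d@X, 1.5), "maxFraction")
    noLab <- OmicsDataset(dataMatrix(d@X))
    expect_error(downsampleByType(noLab, 0.5), "labels")
})

test_that("independent downsampling of both domains unbalances proportions", {
    d <- makeMultiOmic(nCells = 120, nTypes = 4, dx = 4, dy = 4,
                       noiseSd = 0.1, seed = 8)
    dx <- downsampleByType(d@X, 0.5, seed = 21)
    dy <- downsampleByType(d@Y, 0.5, seed = 22)
    px <- as.vector(prop.table(table(cellLabels(dx$dataset))))
    py <- as.vector(prop.table(table(cellLabels(dy$dataset))))
    expect_gt(max(abs(px - py)), 0.01)
})
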