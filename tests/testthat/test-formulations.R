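test_that("localCostGW matches the quadruple-loop tensor contraction", {
    # zero distances: zero distortion
    z <- localCostGW(matrix(0, 3, 3), matrix(0, 4, 4), matrix(1 / 12, 3, 4))
    expect_equal(z, matrix(0, 3, 4))

    # matched geometry with identity coupling: zero diagonal distortion
    set.seed(6)
    D <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    C <- localCostGW(D, D, diag(4) / 4)
    expect_equal(unname(diag(C)), rep(0, 4), tolerance = 1e-14)

    # random instance against the naive oracle
    DX <- as.matrix(dist(matrix(rnorm(6), 3, 2)))
    DY <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    p <- matrix(runif(12), 3, 4); p <- p / sum(p)
    expect_equal(unname(localCostGW(DX, DY, p)), naiveCostGW(DX, DY, p),
                 tolerance = 1e-10)
    expect_error(localCostGW(DX, DY, matrix(1, 4, 3)), "shape")
})

test_that("localCostCOOT matches the quadruple-loop oracle on both axes", {
    set.seed(7)
    X <- matrix(rnorm(6), 3, 2); Y <- matrix(rnorm(12), 4, 3)
    Q <- matrix(runif(6), 2, 3); Q <- Q / sum(Q)
    P <- matrix(runif(12), 3, 4); P <- P / sum(P)
    expect_equal(localCostCOOT(X, Y, Q, "samples"),
                 naiveCostCOOTSamples(X, Y, Q), tolerance = 1e-10)
    expect_equal(localCostCOOT(X, Y, P, "features"),
                 naiveCostCOOTFeatures(X, Y, P), tolerance = 1e-10)

    # identical rows under an identity feature coupling: zero diagonal
    C <- localCostCOOT(X, X, diag(2) / 2, "samples")
    expect_equal(diag(C), rep(0, 3), tolerance = 1e-14)
    # equal constant matrices: zero cost
    expect_equal(localCostCOOT(matrix(2, 3, 2), matrix(2, 4, 2),
                               matrix(0.25, 2, 2), "samples"),
                 matrix(0, 3, 4))
})

test_that("the joint objective agrees with flattened generalized KL", {
    set.seed(8)
    a <- runif(3); b <- runif(4); u <- runif(3) + 0.5; v <- runif(4) + 0.5
    expect_equal(OTAlign:::.klProd(a, b, u, v),
                 generalizedKL(outer(a, b), outer(u, v)), tolerance = 1e-12)
})

test_that("alpha = 1 and alpha = 0 reproduce the dedicated GW/COOT paths", {
    inst <- makeInstance(10, seed = 9)
    cfg <- SolverConfig(alpha = 1, epsGW = 1e-3, nOuter = 10L,
                        innerMaxIter = 5000L, innerTol = 1e-9)
    a <- suppressWarnings(solveUAGW(DX = inst$DX, DY = inst$DY, config = cfg))
    b <- suppressWarnings(alignOT("gw", DX = inst$DX, DY = inst$DY,
                                  config = cfg))
    expect_identical(plan(sampleCoupling(a)), plan(sampleCoupling(b)))
    expect_null(featureCoupling(a))

    cfg0 <- SolverConfig(alpha = 0, epsCOOT = 1e-3, nOuter = 10L,
                         innerMaxIter = 5000L, innerTol = 1e-9)
    a0 <- suppressWarnings(solveUAGW(inst$X, inst$Y, config = cfg0))
    b0 <- suppressWarnings(alignOT("coot", X = inst$X, Y = inst$Y,
                                   config = cfg0))
    expect_identical(plan(sampleCoupling(a0)), plan(sampleCoupling(b0)))
    expect_equal(dim(plan(featureCoupling(a0))),
                 c(ncol(inst$X), ncol(inst$Y)))
})

test_that("balanced runs conserve unit mass in all couplings", {
    inst <- makeInstance(8, seed = 10)
    r <- suppressWarnings(solveUAGW(inst$X, inst$Y, inst$DX, inst$DY,
        config = SolverConfig(alpha = 0.5, epsGW = 5e-3, epsCOOT = 5e-3,
                              nOuter = 10L, innerMaxIter = 5000L)))
    expect_equal(totalMass(sampleCoupling(r)), 1, tolerance = 1e-8)
    expect_equal(totalMass(sampleCouplingPrime(r)), 1, tolerance = 1e-8)
    expect_equal(totalMass(featureCoupling(r)), 1, tolerance = 1e-8)
})

test_that("permuting one domain permutes the coupling rows identically", {
    inst <- makeInstance(8, seed = 11)
    cfg <- SolverConfig(alpha = 0.5, epsGW = 5e-3, epsCOOT = 5e-3,
                        nOuter = 6L, innerMaxIter = 3000L)
    r1 <- suppressWarnings(solveUAGW(inst$X, inst$Y, inst$DX, inst$DY,
                                     config = cfg))
    perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
    DXp <- DistanceMatrix(distValues(inst$DX)[perm, perm])
    r2 <- suppressWarnings(solveUAGW(inst$X[perm, ], inst$Y, DXp, inst$DY,
                                     config = cfg))
    expect_equal(plan(sampleCoupling(r2)),
                 plan(sampleCoupling(r1))[perm, ], tolerance = 1e-9)
})

test_that("solutions at rho = 1e6 match balanced solutions entrywise", {
    inst <- makeInstance(10, seed = 12)
    bal <- suppressWarnings(solveUAGW(DX = inst$DX, DY = inst$DY,
        config = SolverConfig(alpha = 1, epsGW = 5e-3, nOuter = 8L,
                              innerMaxIter = 10000L, innerTol = 1e-8)))
    ub <- suppressWarnings(solveUAGW(DX = inst$DX, DY = inst$DY,
        config = SolverConfig(alpha = 1, epsGW = 5e-3,
                              rhoGW1 = 1e6, rhoGW2 = 1e6, nOuter = 8L,
                              innerMaxIter = 10000L, innerTol = 1e-8)))
    expect_lt(max(abs(plan(sampleCoupling(bal)) - plan(sampleCoupling(ub)))),
              1e-3)
})

test_that("relaxed marginals shed mass from an orphaned cluster", {
    set.seed(13)
    # three asymmetric clusters in X, only the first two present in Y;
    # raw (unnormalized) distances so the shared clusters match at a
    # common scale and the orphan is geometrically unambiguous
    centers <- matrix(c(0, 0, 1, 0, 0.3, 0.75), 3, 2, byrow = TRUE)
    mk <- function(rows) {
        idx <- rep(rows, each = 6)
        centers[idx, ] + matrix(rnorm(length(idx) * 2, sd = 0.03),
                                ncol = 2)
    }
    X <- mk(1:3); Y <- mk(1:2)
    DX <- DistanceMatrix(as.matrix(dist(X)))
    DY <- DistanceMatrix(as.matrix(dist(Y)))
    r <- suppressWarnings(solveUAGW(DX = DX, DY = DY,
        config = SolverConfig(alpha = 1, epsGW = 1e-3,
                              rhoGW1 = 0.01, rhoGW2 = 0.01,
                              nOuter = 10L, innerMaxIter = 5000L)))
    P <- plan(sampleCoupling(r))
    orphanShare <- sum(P[13:18, ]) / sum(P)
    expect_lt(orphanShare, 6 / 18)
})

test_that("COOT on identical data recovers the identity feature map", {
    d <- makeMultiOmic(nCells = 30, nTypes = 3, dx = 20, dy = 20,
                       noiseSd = 0.1, seed = 14, latentDim = 20)
    X <- dataMatrix(d@X)
    r <- suppressWarnings(alignOT("coot", X = X, Y = X,
        config = SolverConfig(alpha = 0, epsCOOT = 1e-3, nOuter = 15L,
                              innerMaxIter = 3000L, innerTol = 1e-8)))
    Q <- plan(featureCoupling(r))
    expect_equal(unname(apply(Q, 1, which.max)), 1:20)
})

test_that("alignOT rejects finite rho in balanced modes and sets sentinels", {
    inst <- makeInstance(6, seed = 15)
    expect_error(alignOT("gw", DX = inst$DX, DY = inst$DY,
                         config = SolverConfig(rhoGW1 = 0.1, rhoGW2 = 0.1)),
                 "balanced")
    r <- suppressWarnings(alignOT("ugw", DX = inst$DX, DY = inst$DY,
        config = SolverConfig(epsGW = 5e-3, nOuter = 4L)))
    expect_true(is.finite(solverConfig(r)@rhoGW1))
    r <- suppressWarnings(alignOT("agw", X = inst$X, Y = inst$Y,
        DX = inst$DX, DY = inst$DY,
        config = SolverConfig(epsGW = 5e-3, epsCOOT = 5e-3, nOuter = 4L)))
    cfg <- solverConfig(r)
    expect_true(cfg@alpha > 0 && cfg@alpha < 1)
    expect_true(all(diff(lossTrace(r)) <= 1e-6))
})

test_that("couplingDensity measures the sharp-row fraction", {
    expect_equal(couplingDensity(diag(4) / 4), 1)
    expect_equal(couplingDensity(matrix(1 / 16, 4, 4)), 0)
    p <- rbind(c(0.6, 0.2, 0.2), c(1, 1, 1) / 3)
    expect_equal(couplingDensity(p), 0.5)
})
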