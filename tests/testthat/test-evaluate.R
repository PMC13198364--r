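test_that("barycentric projection reproduces hand-computed values", {
    # identity transport returns Y exactly
    Y <- matrix(rnorm(12), 4, 3)
    expect_equal(barycentricProject(diag(4) / 4, Y), Y)
    # uniform coupling maps every cell to the column mean
    proj <- barycentricProject(matrix(1 / 12, 3, 4), Y)
    expect_equal(proj, matrix(colMeans(Y), 3, 3, byrow = TRUE))
    # hand evaluation
    P <- matrix(c(0.3, 0.1, 0.2, 0.4), 2, 2)
    expect_equal(barycentricProject(P, matrix(c(1, 3), 2, 1)),
                 matrix(c(1.8, 2.6), 2, 1))
    # zero-mass rows become NaN with a warning
    P0 <- rbind(c(0.5, 0.5), c(0, 0))
    expect_warning(out <- barycentricProject(P0, Y[1:2, ]), "zero mass")
    expect_true(all(is.nan(out[2, ])))
    expect_false(anyNA(out[1, ]))
})

test_that("projected points stay inside the convex hull of Y", {
    set.seed(16)
    P <- matrix(runif(50), 10, 5); P <- P / sum(P)
    Y <- matrix(rnorm(10), 5, 2)
    proj <- barycentricProject(P, Y)
    # every projected coordinate lies within the per-axis range (necessary
    # condition), and each row is a convex combination by construction
    expect_true(all(proj[, 1] >= min(Y[, 1]) & proj[, 1] <= max(Y[, 1])))
    expect_true(all(proj[, 2] >= min(Y[, 2]) & proj[, 2] <= max(Y[, 2])))
    w <- P / rowSums(P)
    expect_equal(rowSums(w), rep(1, 10), tolerance = 1e-12)
})

test_that("foscttm matches exhaustive counting and its invariances", {
    A <- matrix(rnorm(20), 10, 2)
    expect_equal(foscttm(A, A), 0)
    # 1-D hand instance: both directions give (1 + 0 + 1) / 3
    expect_equal(foscttm(matrix(0:2), matrix(2:0)), 2 / 3)
    expect_equal(foscttm(matrix(0:2), matrix(2:0), bidirectional = FALSE),
                 2 / 3)
    set.seed(17)
    A <- matrix(rnorm(45), 15, 3); B <- matrix(rnorm(45), 15, 3)
    expect_equal(foscttm(A, B), naiveFoscttm(A, B), tolerance = 1e-12)
    expect_equal(foscttm(A, B), foscttm(B, A))   # symmetric by construction
    expect_error(foscttm(A[1, , drop = FALSE], B[1, , drop = FALSE]),
                 "two samples")
    expect_error(foscttm(A, B[1:3, ]), "shape")
})

test_that("label transfer accuracy follows the kNN vote with NN tie-break", {
    # self-classification on separated clusters is perfect
    pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                 matrix(rnorm(10, 10, 0.1), 5, 2))
    lab <- rep(c("a", "b"), each = 5)
    expect_equal(labelTransferAccuracy(pts, lab, pts, lab), 1)
    # a single shared label is vacuously perfect
    expect_equal(labelTransferAccuracy(pts, rep("a", 10), pts,
                                       rep("a", 10)), 1)
    # hand-checkable 6-point instance: k = 2 labels, one test point sits
    # inside the wrong cluster
    train <- rbind(c(0, 0), c(0.1, 0), c(5, 0), c(5.1, 0))
    trainLab <- c("a", "a", "b", "b")
    test <- rbind(c(0.05, 0), c(5.05, 0), c(5.02, 0))
    testLab <- c("a", "b", "a")     # last point mislabeled on purpose
    expect_equal(labelTransferAccuracy(train, trainLab, test, testLab),
                 2 / 3)
    # unseen test label counts as an error with a warning
    expect_warning(
        acc <- labelTransferAccuracy(train, trainLab, test,
                                     c("a", "b", "c")),
        "unseen")
    expect_equal(acc, 2 / 3)
})

test_that("feature mass on pairs sums correctly and ignores scale", {
    Q <- matrix(1 / 500, 25, 20)
    pairs <- cbind(1:20, 1:20)
    expect_equal(featureMassOnPairs(Q, pairs), 0.04)
    # all mass on the pair set
    Q2 <- matrix(0, 5, 5); Q2[cbind(1:5, 1:5)] <- 0.2
    expect_equal(featureMassOnPairs(Q2, cbind(1:5, 1:5)), 1)
    # direct summation on a random coupling + rescaling invariance
    set.seed(18)
    Q3 <- matrix(runif(30), 6, 5)
    pr <- cbind(c(1, 4, 6), c(2, 5, 3))
    expect_equal(featureMassOnPairs(Q3, pr), sum(Q3[pr]) / sum(Q3))
    expect_equal(featureMassOnPairs(Q3 * 17, pr),
                 featureMassOnPairs(Q3, pr))
    expect_warning(z <- featureMassOnPairs(Q3, matrix(0, 0, 2)), "empty")
    expect_equal(z, 0)
    expect_error(featureMassOnPairs(Q3, cbind(7, 1)), "range")
})

test_that("cell-type matching aggregates couplings and scores argmaxes", {
    # block-diagonal coupling with matching type order: perfect
    P <- diag(6) / 6
    lab <- rep(c("t1", "t2", "t3"), each = 2)
    truth <- c(t1 = "t1", t2 = "t2", t3 = "t3")
    res <- celltypeMatchAccuracy(P, lab, lab, truth)
    expect_equal(res$accuracy, 1)
    expect_equal(dim(res$matrix), c(3, 3))
    expect_equal(sum(res$matrix), 1, tolerance = 1e-12)
    # 5 of 7 row types correct -> 71.43% at two decimals
    agg <- diag(7); agg[6, 6] <- 0; agg[6, 1] <- 1
    agg[7, 7] <- 0; agg[7, 2] <- 1
    labX <- paste0("m", 1:7); labY <- paste0("m", 1:7)
    truth7 <- setNames(labY, labX)
    res7 <- celltypeMatchAccuracy(agg, labX, labY, truth7)
    expect_equal(res7$accuracy, 5 / 7)
    expect_equal(round(100 * res7$accuracy, 2), 71.43)
    # every argmax wrong
    flip <- matrix(0, 4, 4); flip[cbind(1:4, c(2, 1, 4, 3))] <- 0.25
    labs <- paste0("t", 1:4)
    expect_equal(celltypeMatchAccuracy(flip, labs, labs,
                                       setNames(labs, labs))$accuracy, 0)
    # row types absent from the truth map are excluded
    resPart <- celltypeMatchAccuracy(P, lab, lab, c(t1 = "t1", t2 = "t3"))
    expect_equal(resPart$accuracy, 0.5)
})
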