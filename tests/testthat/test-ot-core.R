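test_that("generalizedKL matches direct evaluation and handles edge cases", {
    expect_equal(generalizedKL(c(0.25, 0.75), c(0.25, 0.75)), 0)
    expect_equal(generalizedKL(c(0.5, 0.5), c(0.25, 0.75)),
                 0.5 * log(2) + 0.5 * log(2 / 3))
    # all-zero p: -sum(p) + sum(r) with 0 log 0 = 0
    expect_equal(generalizedKL(c(0, 0, 0), c(0.2, 0.3, 0.5)), 1)
    # matrices are accepted
    m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
    expect_equal(generalizedKL(m, m), 0)
    expect_gt(generalizedKL(m, m * 2 + 0.1), 0)
    expect_error(generalizedKL(c(0.5, 0.5), c(0.5, 0.5, 0)), "shape")
    expect_error(generalizedKL(c(-0.1, 1.1), c(0.5, 0.5)), "nonnegative")
})

test_that("balanced solveLocal enforces marginals and known solutions", {
    # zero cost: entropic minimizer is the product measure
    s <- solveLocal(matrix(0, 2, 2), c(0.5, 0.5), c(0.5, 0.5),
                    epsilon = 0.1)
    expect_equal(plan(s$coupling), matrix(0.25, 2, 2), tolerance = 1e-12)
    expect_true(s$converged)

    # anti-identity cost at small epsilon concentrates on the diagonal
    s <- solveLocal(matrix(c(0, 1, 1, 0), 2, 2), c(0.5, 0.5),
                    c(0.5, 0.5), epsilon = 0.01)
    expect_equal(plan(s$coupling), diag(2) / 2, tolerance = 1e-3)

    # marginal agreement within 10 * tol on converged runs, random sizes
    set.seed(42)
    for (rep in 1:5) {
        nx <- sample(3:7, 1); ny <- sample(3:7, 1)
        C <- matrix(runif(nx * ny), nx, ny)
        mu1 <- runif(nx) + 0.2; mu1 <- mu1 / sum(mu1)
        mu2 <- runif(ny) + 0.2; mu2 <- mu2 / sum(mu2)
        s <- solveLocal(C, mu1, mu2, epsilon = 0.05, tol = 1e-10,
                        maxIter = 50000L)
        expect_true(s$converged)
        expect_lt(max(abs(marginal1(s$coupling) - mu1)), 1e-9)
        expect_lt(max(abs(marginal2(s$coupling) - mu2)), 1e-9)
    }
})

test_that("rho = 0 gives the closed-form unconstrained minimizer", {
    set.seed(7)
    C <- matrix(runif(12), 3, 4)
    mu1 <- c(0.2, 0.3, 0.5); mu2 <- rep(0.25, 4)
    s <- solveLocal(C, mu1, mu2, epsilon = 0.05, rho1 = 0, rho2 = 0)
    expect_equal(plan(s$coupling), outer(mu1, mu2) * exp(-C / 0.05),
                 tolerance = 1e-12)
})

test_that("entropic solution approaches the exact LP optimum as eps -> 0", {
    set.seed(11)
    u <- rep(0.25, 4)
    for (rep in 1:5) {
        C <- matrix(runif(16), 4, 4)
        s <- solveLocal(C, u, u, epsilon = 1e-3, maxIter = 100000L,
                        tol = 1e-7, warn = FALSE)
        cost <- sum(C * plan(s$coupling))
        expect_lt(abs(cost - exactOTCostUniform(C)), 1e-2 * max(C))
    }
})

test_that("unbalanced solutions converge to balanced ones as rho grows", {
    set.seed(13)
    u <- rep(0.2, 5)
    for (rep in 1:3) {
        C <- matrix(runif(25), 5, 5)
        b <- solveLocal(C, u, u, epsilon = 0.05, maxIter = 20000L)
        ub <- solveLocal(C, u, u, epsilon = 0.05, rho1 = 1e6, rho2 = 1e6,
                         maxIter = 50000L, tol = 1e-7, warn = FALSE)
        expect_lt(max(abs(plan(b$coupling) - plan(ub$coupling))), 1e-4)
    }
})

test_that("the local objective is non-increasing along Sinkhorn iterates", {
    set.seed(17)
    C <- matrix(runif(20), 4, 5)
    mu1 <- rep(0.25, 4); mu2 <- rep(0.2, 5)
    obj <- vapply(1:15, function(k) {
        s <- solveLocal(C, mu1, mu2, epsilon = 0.05, rho1 = 0.5,
                        rho2 = 0.8, maxIter = k, tol = 0, warn = FALSE)
        localObjective(s$coupling, C, mu1, mu2, epsilon = 0.05,
                       rho1 = 0.5, rho2 = 0.8)
    }, numeric(1))
    expect_true(all(diff(obj) <= 1e-8))
})

test_that("strong supervision forces mass onto the supervised pairs", {
    set.seed(19)
    C <- matrix(runif(25), 5, 5)
    D <- 1 - diag(5)             # zero cost on the known (i, i) pairs
    u <- rep(0.2, 5)
    s <- solveLocal(C, u, u, epsilon = 0.05, supervision = D, beta = 1e6,
                    maxIter = 20000L)
    expect_gte(sum(diag(plan(s$coupling))) / totalMass(s$coupling), 0.99)
})

test_that("solveLocal rejects malformed problems and flags non-convergence", {
    expect_error(solveLocal(matrix(c(0, NA, 1, 2), 2, 2), c(0.5, 0.5),
                            c(0.5, 0.5), 0.1), "non-finite")
    expect_error(solveLocal(matrix(0, 2, 2), c(0, 1), c(0.5, 0.5), 0.1),
                 "positive")
    expect_error(solveLocal(matrix(0, 2, 2), c(0.5, 0.5), c(0.5, 0.5), -1),
                 "epsilon")
    set.seed(23)
    C <- matrix(runif(100), 10, 10)
    expect_warning(
        s <- solveLocal(C, rep(0.1, 10), rep(0.1, 10), epsilon = 1e-4,
                        maxIter = 3L),
        "still moving")
    expect_false(s$converged)
})

test_that("log-domain iterations survive small epsilon without overflow", {
    set.seed(29)
    C <- matrix(runif(36), 6, 6)    # costs in [0, 1]
    u <- rep(1 / 6, 6)
    s <- solveLocal(C, u, u, epsilon = 1e-4, maxIter = 100000L,
                    tol = 1e-8, warn = FALSE)
    expect_true(all(is.finite(plan(s$coupling))))
    expect_lt(max(abs(marginal1(s$coupling) - u)), 1e-5)
})
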