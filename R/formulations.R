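## The generic unbalanced augmented Gromov-Wasserstein (UAGW) solver and
## its reductions. The joint objective over the sample couplings P, P'
## and the feature coupling Q is
##
##   J(P, P', Q) =
##     alpha   * [ <L(DX,DY), P (x) P'> + epsGW*KL(P (x) P' | nuS (x) nuS)
##                 + rhoGW1*KL(P#1 (x) P'#1 | muS1 (x) muS1)
##                 + rhoGW2*KL(P#2 (x) P'#2 | muS2 (x) muS2) ]
##   + (1-a) * [ <L(X,Y), P (x) Q> + epsCOOT*KL(P (x) Q | nuS (x) nuF)
##                 + rhoCOOT1*KL(P#1 (x) Q#1 | muS1 (x) muF1)
##                 + rhoCOOT2*KL(P#2 (x) Q#2 | muS2 (x) muF2) ]
##   + betaSample*<Dsample, P> + betaFeature*<Dfeature, Q>
##
## with L the squared difference loss, nuS = muS1 (x) muS2 and
## nuF = muF1 (x) muF2. Holding two blocks fixed, the restriction to the
## third is exactly one entropic (un)balanced linear OT problem with
## mass-rescaled effective eps and rho plus a scalar cost offset; these
## are solved by solveLocal(). Because each block update minimizes the
## exact restriction, the objective trace is non-increasing.

#' Gromov-Wasserstein local cost
#'
#' Given intra-domain distance matrices and the coupling of the opposite
#' sample block, returns the cost matrix
#' \deqn{C_{ik} = \sum_{j,l} |DX_{ij} - DY_{kl}|^2 \, \pi_{jl}}
#' via the squared-loss factorization
#' \eqn{DX^2 \pi_{\#1} \oplus DY^2 \pi_{\#2} - 2\, DX\, \pi\, DY^\top},
#' never materializing the 4-index distortion tensor.
#'
#' @param DX,DY [DistanceMatrix-class] (or square matrices) of the two
#'   domains.
#' @param other the fixed sample [Coupling-class] (or plan matrix) of
#'   shape `nx` by `ny`.
#' @return the `nx` by `ny` cost matrix.
#' @export
localCostGW <- function(DX, DY, other) {
    dx <- if (is(DX, "DistanceMatrix")) DX@values else as.matrix(DX)
    dy <- if (is(DY, "DistanceMatrix")) DY@values else as.matrix(DY)
    p <- asPlan(other)
    if (nrow(p) != nrow(dx) || ncol(p) != nrow(dy))
        stop("localCostGW: coupling shape must be nrow(DX) x nrow(DY)")
    a <- as.vector(dx^2 %*% rowSums(p))        # length nx
    b <- as.vector(dy^2 %*% colSums(p))        # length ny
    outer(a, rep(1, length(b))) + outer(rep(1, length(a)), b) -
        2 * dx %*% p %*% t(dy)
}

#' Co-optimal-transport local cost
#'
#' The raw-data analogue of [localCostGW()]: with the feature coupling
#' fixed (`axis = "samples"`) returns
#' \deqn{C_{ik} = \sum_{j,l} (X_{ij} - Y_{kl})^2 \, Q_{jl},}
#' with the sample coupling fixed (`axis = "features"`) the transposed
#' analogue over features, both through the same squared-loss
#' factorization.
#'
#' @param X,Y the two data matrices (cells by features).
#' @param other the fixed [Coupling-class] of the opposite axis.
#' @param axis `"samples"` or `"features"`.
#' @return the cost matrix (`nx` by `ny`, or `dx` by `dy`).
#' @export
localCostCOOT <- function(X, Y, other, axis = c("samples", "features")) {
    axis <- match.arg(axis)
    X <- as.matrix(X); Y <- as.matrix(Y)
    p <- asPlan(other)
    if (axis == "samples") {
        if (nrow(p) != ncol(X) || ncol(p) != ncol(Y))
            stop("localCostCOOT: feature coupling must be ncol(X) x ncol(Y)")
        a <- as.vector(X^2 %*% rowSums(p))
        b <- as.vector(Y^2 %*% colSums(p))
        outer(a, rep(1, length(b))) + outer(rep(1, length(a)), b) -
            2 * X %*% p %*% t(Y)
    } else {
        if (nrow(p) != nrow(X) || ncol(p) != nrow(Y))
            stop("localCostCOOT: sample coupling must be nrow(X) x nrow(Y)")
        a <- as.vector(t(X^2) %*% rowSums(p))
        b <- as.vector(t(Y^2) %*% colSums(p))
        outer(a, rep(1, length(b))) + outer(rep(1, length(a)), b) -
            2 * t(X) %*% p %*% Y
    }
}

## generalized KL of an outer product of two nonnegative measures against
## an outer product reference: KL(a (x) b | u (x) v)
.klProd <- function(a, b, u, v) {
    ma <- sum(a); mb <- sum(b); mu <- sum(u); mv <- sum(v)
    mb * plogpr(a, u) + ma * plogpr(b, v) - ma * mb + mu * mv
}

#' Joint UAGW objective
#'
#' Evaluates the full block-coordinate-descent objective (GW distortion,
#' COOT distortion, entropic and marginal-relaxation generalized-KL terms
#' weighted by `alpha`, plus supervision inner products) at given
#' couplings. Marginal terms with `rho = Inf` are hard constraints and
#' contribute zero.
#'
#' @param P,Pprime,Q couplings (or plan matrices); `Q` may be `NULL` when
#'   `alpha = 1`.
#' @param X,Y data matrices (ignored when `alpha = 1`).
#' @param DX,DY distance matrices (ignored when `alpha = 0`).
#' @param muS1,muS2,muF1,muF2 sample and feature marginals.
#' @param config a [SolverConfig-class].
#' @return the scalar objective value.
#' @export
uagwObjective <- function(P, Pprime, Q, X, Y, DX, DY,
                          muS1, muS2, muF1, muF2, config) {
    a <- config@alpha
    p <- asPlan(P); pp <- asPlan(Pprime)
    nuS <- outer(muS1, muS2)
    val <- 0
    if (a > 0) {
        gw <- sum(localCostGW(DX, DY, pp) * p) +
            config@epsGW * .klProd(p, pp, nuS, nuS)
        if (is.finite(config@rhoGW1))
            gw <- gw + config@rhoGW1 *
                .klProd(rowSums(p), rowSums(pp), muS1, muS1)
        if (is.finite(config@rhoGW2))
            gw <- gw + config@rhoGW2 *
                .klProd(colSums(p), colSums(pp), muS2, muS2)
        val <- val + a * gw
    }
    if (a < 1) {
        q <- asPlan(Q)
        nuF <- outer(muF1, muF2)
        co <- sum(localCostCOOT(X, Y, q, "samples") * p) +
            config@epsCOOT * .klProd(p, q, nuS, nuF)
        if (is.finite(config@rhoCOOT1))
            co <- co + config@rhoCOOT1 *
                .klProd(rowSums(p), rowSums(q), muS1, muF1)
        if (is.finite(config@rhoCOOT2))
            co <- co + config@rhoCOOT2 *
                .klProd(colSums(p), colSums(q), muS2, muF2)
        val <- val + (1 - a) * co
    }
    if (config@betaSample > 0 && !is.null(config@supervisionSample))
        val <- val + config@betaSample * sum(config@supervisionSample * p)
    if (config@betaFeature > 0 && a < 1 &&
        !is.null(config@supervisionFeature))
        val <- val + config@betaFeature *
            sum(config@supervisionFeature * asPlan(Q))
    val
}

## effective (eps, rho1, rho2, costOffset) for one block update.
## terms: list of active contributions, each with weight w (alpha or
## 1-alpha), eps, rho1, rho2, and the fixed block's plan `fixed` with its
## reference outer product plus marginal references.
.blockParams <- function(terms) {
    eps <- 0; rho1 <- 0; rho2 <- 0; off <- 0
    hard1 <- FALSE; hard2 <- FALSE
    for (tm in terms) {
        mFix <- sum(tm$fixed)
        eps <- eps + tm$w * tm$eps * mFix
        off <- off + tm$w * tm$eps * plogpr(tm$fixed, tm$ref)
        if (is.infinite(tm$rho1)) hard1 <- TRUE
        else {
            rho1 <- rho1 + tm$w * tm$rho1 * mFix
            off <- off + tm$w * tm$rho1 *
                plogpr(rowSums(tm$fixed), tm$refM1)
        }
        if (is.infinite(tm$rho2)) hard2 <- TRUE
        else {
            rho2 <- rho2 + tm$w * tm$rho2 * mFix
            off <- off + tm$w * tm$rho2 *
                plogpr(colSums(tm$fixed), tm$refM2)
        }
    }
    list(eps = eps, rho1 = if (hard1) Inf else rho1,
         rho2 = if (hard2) Inf else rho2, offset = off)
}

#' Unified block-coordinate-descent alignment solver
#'
#' Minimizes the joint unbalanced augmented Gromov-Wasserstein objective
#' (see [uagwObjective()]) over the sample couplings `P`, `P'` and the
#' feature coupling `Q` by block coordinate descent: each sweep updates
#' `P` against the `alpha`-blended GW + COOT cost, then `P'` against the
#' GW cost (skipped when `alpha = 0`), then `Q` against the feature-axis
#' COOT cost (skipped when `alpha = 1`). Every block update is one
#' entropic (un)balanced linear OT problem solved by [solveLocal()] with
#' effective parameters rescaled by the fixed block's total mass; dual
#' potentials are warm-started across sweeps. All couplings are
#' initialized at the product of their marginals, so the solver is fully
#' deterministic.
#'
#' Setting `alpha = 1` recovers (unbalanced) Gromov-Wasserstein, `alpha =
#' 0` (unbalanced) co-optimal transport, and `rho = Inf` everywhere the
#' balanced variants; see [alignOT()] for the named dispatch.
#'
#' @param X,Y data matrices (cells by features); may be `NULL` when
#'   `alpha = 1`.
#' @param DX,DY [DistanceMatrix-class] objects; may be `NULL` when
#'   `alpha = 0`.
#' @param muS1,muS2 sample marginals (default uniform).
#' @param muF1,muF2 feature marginals (default uniform).
#' @param config a [SolverConfig-class].
#' @param verbose print per-sweep diagnostics.
#' @return an [AlignmentResult-class].
#' @examples
#' d <- makeMultiOmic(nCells = 30, nTypes = 2, dx = 4, dy = 4,
#'                    noiseSd = 0.05, seed = 1)
#' DX <- normalizeDistances(knnGeodesic(dataMatrix(d@X), k = 5))
#' DY <- normalizeDistances(knnGeodesic(dataMatrix(d@Y), k = 5))
#' res <- solveUAGW(dataMatrix(d@X), dataMatrix(d@Y), DX, DY,
#'                  config = SolverConfig(alpha = 1, nOuter = 10L))
#' @export
solveUAGW <- function(X = NULL, Y = NULL, DX = NULL, DY = NULL,
                      muS1 = NULL, muS2 = NULL, muF1 = NULL, muF2 = NULL,
                      config = SolverConfig(), verbose = FALSE) {
    a <- config@alpha
    if (a > 0 && (is.null(DX) || is.null(DY)))
        stop("solveUAGW: DX and DY are required when alpha > 0")
    if (a < 1 && (is.null(X) || is.null(Y)))
        stop("solveUAGW: X and Y are required when alpha < 1")
    if (!is.null(X)) X <- as.matrix(X)
    if (!is.null(Y)) Y <- as.matrix(Y)
    dxv <- if (!is.null(DX)) {
        if (is(DX, "DistanceMatrix")) DX@values else as.matrix(DX)
    }
    dyv <- if (!is.null(DY)) {
        if (is(DY, "DistanceMatrix")) DY@values else as.matrix(DY)
    }
    nx <- if (!is.null(X)) nrow(X) else nrow(dxv)
    ny <- if (!is.null(Y)) nrow(Y) else nrow(dyv)
    if (!is.null(X) && !is.null(dxv) && nrow(X) != nrow(dxv))
        stop("solveUAGW: DX dimension disagrees with nrow(X)")
    if (!is.null(Y) && !is.null(dyv) && nrow(Y) != nrow(dyv))
        stop("solveUAGW: DY dimension disagrees with nrow(Y)")
    if (is.null(muS1)) muS1 <- rep(1 / nx, nx)
    if (is.null(muS2)) muS2 <- rep(1 / ny, ny)
    if (a < 1) {
        if (is.null(muF1)) muF1 <- rep(1 / ncol(X), ncol(X))
        if (is.null(muF2)) muF2 <- rep(1 / ncol(Y), ncol(Y))
    }

    nuS <- outer(muS1, muS2)
    P <- nuS; Pp <- nuS
    Q <- if (a < 1) outer(muF1, muF2) else NULL
    nuF <- if (a < 1) outer(muF1, muF2) else NULL

    dualP <- dualPp <- dualQ <- NULL
    innerOK <- TRUE

    loss <- uagwObjective(P, Pp, Q, X, Y, dxv, dyv,
                          muS1, muS2, muF1, muF2, config)
    trace <- loss
    converged <- FALSE

    checkPlan <- function(p, block, sweep) {
        if (any(!is.finite(p)))
            stop(sprintf(
                "solveUAGW: non-finite values in the %s update at sweep %d",
                block, sweep))
        p
    }

    for (sweep in seq_len(config@nOuter)) {
        ## --- P update: blended GW + COOT cost -------------------------
        terms <- list()
        C <- matrix(0, nx, ny)
        if (a > 0) {
            C <- C + a * localCostGW(dxv, dyv, Pp)
            terms <- c(terms, list(list(
                w = a, eps = config@epsGW,
                rho1 = config@rhoGW1, rho2 = config@rhoGW2,
                fixed = Pp, ref = nuS, refM1 = muS1, refM2 = muS2)))
        }
        if (a < 1) {
            C <- C + (1 - a) * localCostCOOT(X, Y, Q, "samples")
            terms <- c(terms, list(list(
                w = 1 - a, eps = config@epsCOOT,
                rho1 = config@rhoCOOT1, rho2 = config@rhoCOOT2,
                fixed = Q, ref = nuF, refM1 = muF1, refM2 = muF2)))
        }
        bp <- .blockParams(terms)
        sol <- solveLocal(C + bp$offset, muS1, muS2, bp$eps,
                          bp$rho1, bp$rho2,
                          supervision = config@supervisionSample,
                          beta = config@betaSample,
                          maxIter = config@innerMaxIter,
                          tol = config@innerTol,
                          init = dualP, warn = FALSE)
        innerOK <- innerOK && sol$converged
        dualP <- sol[c("f", "g")]
        P <- checkPlan(plan(sol$coupling), "P", sweep)

        ## --- P' update: GW cost against P -----------------------------
        if (a > 0) {
            C <- localCostGW(dxv, dyv, P)
            bp <- .blockParams(list(list(
                w = 1, eps = config@epsGW,
                rho1 = config@rhoGW1, rho2 = config@rhoGW2,
                fixed = P, ref = nuS, refM1 = muS1, refM2 = muS2)))
            sol <- solveLocal(C + bp$offset, muS1, muS2, bp$eps,
                              bp$rho1, bp$rho2,
                              maxIter = config@innerMaxIter,
                              tol = config@innerTol,
                              init = dualPp, warn = FALSE)
            innerOK <- innerOK && sol$converged
            dualPp <- sol[c("f", "g")]
            Pp <- checkPlan(plan(sol$coupling), "P'", sweep)
        }

        ## --- Q update: feature-axis COOT cost against P ---------------
        if (a < 1) {
            C <- localCostCOOT(X, Y, P, "features")
            bp <- .blockParams(list(list(
                w = 1, eps = config@epsCOOT,
                rho1 = config@rhoCOOT1, rho2 = config@rhoCOOT2,
                fixed = P, ref = nuS, refM1 = muS1, refM2 = muS2)))
            ## the Q block is solved with the (1 - alpha) factor divided
            ## out, so the supervision strength must be rescaled too
            sol <- solveLocal(C + bp$offset, muF1, muF2, bp$eps,
                              bp$rho1, bp$rho2,
                              supervision = config@supervisionFeature,
                              beta = config@betaFeature / (1 - a),
                              maxIter = config@innerMaxIter,
                              tol = config@innerTol,
                              init = dualQ, warn = FALSE)
            innerOK <- innerOK && sol$converged
            dualQ <- sol[c("f", "g")]
            Q <- checkPlan(plan(sol$coupling), "Q", sweep)
        }

        lossNew <- uagwObjective(P, Pp, Q, X, Y, dxv, dyv,
                                 muS1, muS2, muF1, muF2, config)
        trace <- c(trace, lossNew)
        if (verbose)
            otaLog(sprintf("sweep %d: objective %.8g (mass P = %.4g)",
                           sweep, lossNew, sum(P)))
        if (abs(loss - lossNew) < config@innerTol) {
            converged <- TRUE
            loss <- lossNew
            break
        }
        loss <- lossNew
    }
    if (!converged)
        warning("solveUAGW: objective still changing after nOuter sweeps")
    drift <- max(diff(trace), 0)
    if (drift > 1e-6)
        warning(sprintf(
            "solveUAGW: loss trace increased by %.3g (inner solves may need a larger budget)",
            drift))

    new("AlignmentResult",
        P = Coupling(P), Pprime = Coupling(Pp),
        Q = if (a < 1) Coupling(Q) else NULL,
        lossTrace = trace, converged = converged, config = config)
}

#' Named dispatch over the alignment formulations
#'
#' Convenience wrapper around [solveUAGW()] that fixes `alpha` and the
#' marginal-relaxation sentinels for the six supported formulations:
#'
#' * `"gw"`: `alpha = 1`, hard marginals (`rhoGW = Inf`);
#' * `"ugw"`: `alpha = 1`, finite `rhoGW` (default 0.1);
#' * `"coot"`: `alpha = 0`, hard marginals;
#' * `"ucoot"`: `alpha = 0`, finite `rhoCOOT` (default 0.1);
#' * `"agw"`: `0 < alpha < 1`, hard marginals everywhere;
#' * `"uagw"`: everything as configured.
#'
#' Supplying a finite relaxation weight together with a balanced mode is
#' a configuration error, not a silent override.
#'
#' @param mode one of `"gw"`, `"ugw"`, `"coot"`, `"ucoot"`, `"agw"`,
#'   `"uagw"`.
#' @inheritParams solveUAGW
#' @return an [AlignmentResult-class].
#' @export
alignOT <- function(mode = c("gw", "ugw", "coot", "ucoot", "agw", "uagw"),
                    X = NULL, Y = NULL, DX = NULL, DY = NULL,
                    muS1 = NULL, muS2 = NULL, muF1 = NULL, muF2 = NULL,
                    config = SolverConfig(), verbose = FALSE) {
    mode <- match.arg(mode)
    cf <- config
    finiteGW <- is.finite(cf@rhoGW1) || is.finite(cf@rhoGW2)
    finiteCOOT <- is.finite(cf@rhoCOOT1) || is.finite(cf@rhoCOOT2)
    if (mode %in% c("gw", "coot", "agw") && (finiteGW || finiteCOOT))
        stop(sprintf(
            "alignOT: mode '%s' is balanced but a finite rho was supplied; use the unbalanced mode instead",
            mode))
    defaultRho <- 0.1
    cf <- switch(mode,
        gw = { cf@alpha <- 1; cf },
        ugw = {
            cf@alpha <- 1
            if (!finiteGW) { cf@rhoGW1 <- defaultRho; cf@rhoGW2 <- defaultRho }
            cf
        },
        coot = { cf@alpha <- 0; cf },
        ucoot = {
            cf@alpha <- 0
            if (!finiteCOOT) { cf@rhoCOOT1 <- defaultRho; cf@rhoCOOT2 <- defaultRho }
            cf
        },
        agw = {
            if (cf@alpha %in% c(0, 1)) cf@alpha <- 0.3
            cf
        },
        uagw = cf)
    validObject(cf)
    solveUAGW(X, Y, DX, DY, muS1, muS2, muF1, muF2, cf, verbose = verbose)
}

#' Coupling density diagnostic
#'
#' Fraction of rows whose largest entry carries more than half of that
#' row's mass. A value near 1 indicates a sharp, near-deterministic
#' matching; values near 0 indicate a diffuse coupling (typically a too
#' large entropic weight). Used by [gridSearch()] as the density
#' diagnostic when tuning `eps`.
#'
#' @param P a [Coupling-class] or plan matrix.
#' @return a scalar in `[0, 1]`.
#' @export
couplingDensity <- function(P) {
    p <- asPlan(P)
    rs <- rowSums(p)
    ok <- rs > 0
    mean(apply(p[ok, , drop = FALSE], 1L, max) / rs[ok] > 0.5)
}
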