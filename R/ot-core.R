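## Core entropic, optionally unbalanced, optionally supervised linear OT
## solver. Every alignment formulation in the package reduces, one block
## update at a time, to the problem solved here:
##
##   min_P  <C + beta*D, P> + eps*KL(P | mu1 (x) mu2)
##          + rho1*KL(P#1 | mu1) + rho2*KL(P#2 | mu2)
##
## with generalized (unnormalized) KL divergences and the convention that
## rho = Inf encodes a hard marginal constraint (classic balanced
## Sinkhorn). All iterations run in the log domain so that small entropic
## weights (eps down to 1e-4 on costs scaled to [0, 1]) do not overflow.

#' Generalized Kullback-Leibler divergence
#'
#' Computes the unnormalized KL divergence
#' \deqn{KL(p \mid r) = \sum_i p_i \log(p_i / r_i) - \sum_i p_i + \sum_i r_i}
#' with the convention \eqn{0 \log 0 = 0}. Unlike the probability-simplex
#' KL, this is finite and meaningful for arbitrary nonnegative measures of
#' unequal total mass, which is what the unbalanced marginal-relaxation
#' terms require.
#'
#' @param p nonnegative numeric vector or matrix.
#' @param r positive reference of the same shape (strict positivity is
#'   only required where `p > 0`).
#' @return a nonnegative scalar; zero exactly when `p == r` entrywise.
#' @examples
#' generalizedKL(c(0.25, 0.75), c(0.25, 0.75))      # 0
#' generalizedKL(c(0.5, 0.5), c(0.25, 0.75))
#' @export
generalizedKL <- function(p, r) {
    if (length(p) != length(r))
        stop("generalizedKL: 'p' and 'r' must have the same shape")
    p <- as.numeric(p); r <- as.numeric(r)
    if (any(p < 0))
        stop("generalizedKL: 'p' must be nonnegative")
    if (any(r[p > 0] <= 0))
        stop("generalizedKL: 'r' must be positive wherever p > 0")
    plogpr(p, r) - sum(p) + sum(r)
}

#' Solve one entropic (un)balanced optimal transport problem
#'
#' Log-domain Sinkhorn scaling for the local problem
#' \deqn{\min_P \langle C + \beta D, P\rangle + \varepsilon KL(P|\mu_1
#' \otimes \mu_2) + \rho_1 KL(P_{\#1}|\mu_1) + \rho_2 KL(P_{\#2}|\mu_2).}
#' Each dual update is damped by the unbalanced exponent
#' \eqn{\rho/(\rho+\varepsilon)}; `rho = Inf` gives the undamped balanced
#' update (hard marginal constraint) and `rho = 0` drops the marginal
#' penalty entirely, whose minimizer is the closed form
#' \eqn{(\mu_1\otimes\mu_2) \exp(-(C+\beta D)/\varepsilon)}.
#'
#' @param cost finite numeric cost matrix (rows = domain-1 atoms).
#' @param mu1,mu2 strictly positive marginal weight vectors.
#' @param epsilon positive entropic weight.
#' @param rho1,rho2 nonnegative marginal relaxation weights; `Inf`
#'   (default) enforces the marginal exactly.
#' @param supervision optional supervision matrix D of the same shape as
#'   `cost` (convention: 0 for known pairs, 1 otherwise).
#' @param beta nonnegative supervision strength.
#' @param maxIter maximum number of Sinkhorn iterations.
#' @param tol convergence tolerance on the sup-norm change of the scaled
#'   dual potentials (`f / epsilon`), which bounds the relative change of
#'   the plan entries and, in balanced mode, the total-variation marginal
#'   violation.
#' @param init optional list with numeric vectors `f`, `g` to warm-start
#'   the dual potentials.
#' @param warn emit a warning when the iteration budget is exhausted
#'   before the duals settle.
#' @return a list with elements `coupling` (a [Coupling-class]),
#'   `converged` (logical), `iterations`, and the dual potentials `f`,
#'   `g`.
#' @examples
#' sol <- solveLocal(matrix(c(0, 1, 1, 0), 2, 2),
#'                   mu1 = c(0.5, 0.5), mu2 = c(0.5, 0.5),
#'                   epsilon = 0.01)
#' plan(sol$coupling)   # ~ diag(2)/2
#' @export
solveLocal <- function(cost, mu1, mu2, epsilon,
                       rho1 = Inf, rho2 = Inf,
                       supervision = NULL, beta = 0,
                       maxIter = 1000L, tol = 1e-9,
                       init = NULL, warn = TRUE) {
    cost <- as.matrix(cost)
    if (any(!is.finite(cost)))
        stop("solveLocal: cost matrix contains non-finite entries")
    if (length(mu1) != nrow(cost) || length(mu2) != ncol(cost))
        stop("solveLocal: marginal lengths must match cost dimensions")
    if (any(mu1 <= 0) || any(mu2 <= 0))
        stop("solveLocal: marginals must be strictly positive")
    if (epsilon <= 0)
        stop("solveLocal: epsilon must be positive")
    if (rho1 < 0 || rho2 < 0)
        stop("solveLocal: rho weights must be nonnegative")
    if (!is.null(supervision)) {
        supervision <- as.matrix(supervision)
        if (!all(dim(supervision) == dim(cost)))
            stop("solveLocal: supervision shape must equal cost shape")
        if (beta != 0) cost <- cost + beta * supervision
    }

    lam1 <- if (is.infinite(rho1)) 1 else rho1 / (rho1 + epsilon)
    lam2 <- if (is.infinite(rho2)) 1 else rho2 / (rho2 + epsilon)
    lmu1 <- log(mu1); lmu2 <- log(mu2)
    A <- -cost / epsilon
    f <- if (!is.null(init$f)) init$f else numeric(nrow(cost))
    g <- if (!is.null(init$g)) init$g else numeric(ncol(cost))

    it <- 0L; err <- Inf
    while (it < maxIter) {
        it <- it + 1L
        fNew <- -lam1 * epsilon *
            rowLSE(sweep(A, 2L, g / epsilon + lmu2, "+"))
        gNew <- -lam2 * epsilon *
            colLSE(A + (fNew / epsilon + lmu1))
        ## change of the scaled potentials f/eps: a bound on the relative
        ## change of the plan entries, and (balanced case) on the
        ## total-variation marginal violation
        err <- max(max(abs(fNew - f)), max(abs(gNew - g))) / epsilon
        f <- fNew; g <- gNew
        if (err < tol) break
    }
    converged <- err < tol
    if (!converged && warn)
        warning(sprintf(
            "solveLocal: duals still moving (%.3g > tol %.3g) after %d iterations",
            err, tol, it))

    logP <- sweep(A + (f / epsilon + lmu1), 2L, g / epsilon + lmu2, "+")
    list(coupling = Coupling(exp(logP)), converged = converged,
         iterations = it, f = f, g = g)
}

#' Objective value of the local entropic OT problem
#'
#' Evaluates \eqn{\langle C+\beta D, P\rangle + \varepsilon KL(P|\mu_1
#' \otimes \mu_2) + \rho_1 KL(P_{\#1}|\mu_1) + \rho_2 KL(P_{\#2}|\mu_2)}
#' at a given plan. Marginal terms with `rho = Inf` are treated as a
#' satisfied hard constraint and contribute zero.
#'
#' @inheritParams solveLocal
#' @param P a [Coupling-class] or plan matrix.
#' @return the scalar objective value.
#' @export
localObjective <- function(P, cost, mu1, mu2, epsilon,
                           rho1 = Inf, rho2 = Inf,
                           supervision = NULL, beta = 0) {
    p <- asPlan(P)
    cost <- as.matrix(cost)
    if (!is.null(supervision) && beta != 0)
        cost <- cost + beta * as.matrix(supervision)
    val <- sum(cost * p) + epsilon * generalizedKL(p, outer(mu1, mu2))
    if (is.finite(rho1))
        val <- val + rho1 * generalizedKL(rowSums(p), mu1)
    if (is.finite(rho2))
        val <- val + rho2 * generalizedKL(colSums(p), mu2)
    val
}
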