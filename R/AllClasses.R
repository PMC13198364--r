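setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("factorOrNULL", c("factor", "NULL"))

## ---------------------------------------------------------------------------
## OmicsDataset
## ---------------------------------------------------------------------------

#' One modality of a multi-omic experiment
#'
#' Container for a single modality's measurement matrix in the fixed
#' cells-as-rows orientation, together with sample identifiers, feature
#' identifiers and optional per-cell type labels.
#'
#' @slot assay numeric matrix, `n` cells by `d` features, all finite.
#' @slot sampleIds character vector of unique cell identifiers (length `n`).
#' @slot featureIds character vector of feature identifiers (length `d`).
#' @slot labels factor of per-cell type labels, or `NULL`.
#'
#' @seealso [readDataset()], [makeMultiOmic()]
#' @export
setClass("OmicsDataset",
         representation(assay = "matrix",
                        sampleIds = "character",
                        featureIds = "character",
                        labels = "factorOrNULL"))

setValidity("OmicsDataset", function(object) {
    m <- object@assay
    msg <- character()
    if (!is.numeric(m))
        msg <- c(msg, "assay must be a numeric matrix")
    if (any(!is.finite(m)))
        msg <- c(msg, "assay contains non-finite values")
    if (length(object@sampleIds) != nrow(m))
        msg <- c(msg, "sampleIds length must equal nrow(assay)")
    if (length(object@featureIds) != ncol(m))
        msg <- c(msg, "featureIds length must equal ncol(assay)")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "duplicate sample ids")
    if (!is.null(object@labels) && length(object@labels) != nrow(m))
        msg <- c(msg, "labels length must equal nrow(assay)")
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsDataset
#'
#' @param assay numeric matrix with cells as rows and features as columns.
#' @param sampleIds character vector of cell identifiers; defaults to the
#'   matrix row names or `cell1, cell2, ...`.
#' @param featureIds character vector of feature identifiers; defaults to
#'   the matrix column names or `feat1, feat2, ...`.
#' @param labels optional per-cell type labels (coerced to factor).
#' @return an [OmicsDataset-class] object.
#' @examples
#' ds <- OmicsDataset(matrix(rnorm(20), 5, 4),
#'                    labels = c("a", "a", "b", "b", "b"))
#' nSamples(ds)
#' @export
OmicsDataset <- function(assay, sampleIds = NULL, featureIds = NULL,
                         labels = NULL) {
    assay <- as.matrix(assay)
    storage.mode(assay) <- "double"
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(assay))) rownames(assay)
                     else paste0("cell", seq_len(nrow(assay)))
    if (is.null(featureIds))
        featureIds <- if (!is.null(colnames(assay))) colnames(assay)
                      else paste0("feat", seq_len(ncol(assay)))
    rownames(assay) <- sampleIds
    colnames(assay) <- featureIds
    if (!is.null(labels)) labels <- as.factor(labels)
    new("OmicsDataset", assay = assay,
        sampleIds = as.character(sampleIds),
        featureIds = as.character(featureIds),
        labels = labels)
}

#' @rdname dataMatrix
#' @export
setMethod("dataMatrix", "OmicsDataset", function(x) x@assay)
#' @rdname dataMatrix
#' @export
setMethod("sampleIds", "OmicsDataset", function(x) x@sampleIds)
#' @rdname dataMatrix
#' @export
setMethod("featureIds", "OmicsDataset", function(x) x@featureIds)
#' @rdname dataMatrix
#' @export
setMethod("cellLabels", "OmicsDataset", function(x) x@labels)
#' @rdname dataMatrix
#' @export
setMethod("nSamples", "OmicsDataset", function(x) nrow(x@assay))
#' @rdname dataMatrix
#' @export
setMethod("nFeatures", "OmicsDataset", function(x) ncol(x@assay))

setMethod("show", "OmicsDataset", function(object) {
    cat("OmicsDataset:", nrow(object@assay), "cells x",
        ncol(object@assay), "features\n")
    if (!is.null(object@labels)) {
        tab <- table(object@labels)
        cat("  labels:", paste0(names(tab), " (", as.integer(tab), ")",
                                collapse = ", "), "\n")
    }
})

#' Subset an OmicsDataset by cells
#'
#' @param x an [OmicsDataset-class].
#' @param i integer or logical index over cells (rows).
#' @param j,...,drop ignored; present for generic compatibility.
#' @return the subset [OmicsDataset-class].
#' @export
setMethod("[", "OmicsDataset", function(x, i, j, ..., drop = FALSE) {
    OmicsDataset(x@assay[i, , drop = FALSE],
                 sampleIds = x@sampleIds[i],
                 featureIds = x@featureIds,
                 labels = if (!is.null(x@labels)) droplevels(x@labels[i]))
})

## ---------------------------------------------------------------------------
## Coupling
## ---------------------------------------------------------------------------

#' Transport plan between two sets of atoms
#'
#' A nonnegative matrix whose entry (i, j) is the mass transported from
#' atom i of the first domain to atom j of the second, stored together
#' with its pushforward marginals (row and column sums) and total mass.
#' In balanced optimal transport the pushforwards equal the prescribed
#' marginals up to solver tolerance; unbalanced solvers may create or
#' destroy mass.
#'
#' @slot plan nonnegative numeric matrix.
#' @slot marginal1 numeric vector of row sums (first pushforward).
#' @slot marginal2 numeric vector of column sums (second pushforward).
#' @slot totalMass sum of all plan entries.
#' @export
setClass("Coupling",
         representation(plan = "matrix",
                        marginal1 = "numeric",
                        marginal2 = "numeric",
                        totalMass = "numeric"))

setValidity("Coupling", function(object) {
    p <- object@plan
    msg <- character()
    if (any(!is.finite(p)))
        msg <- c(msg, "plan contains non-finite entries")
    if (any(p < 0))
        msg <- c(msg, "plan entries must be nonnegative")
    if (length(object@marginal1) != nrow(p) ||
        length(object@marginal2) != ncol(p))
        msg <- c(msg, "marginal lengths must match plan dimensions")
    if (max(abs(object@marginal1 - rowSums(p))) > 1e-10 ||
        max(abs(object@marginal2 - colSums(p))) > 1e-10)
        msg <- c(msg, "stored marginals disagree with plan row/column sums")
    if (abs(object@totalMass - sum(p)) > 1e-8)
        msg <- c(msg, "totalMass disagrees with sum(plan)")
    if (length(msg)) msg else TRUE
})

#' Construct a Coupling from a plan matrix
#'
#' @param plan nonnegative numeric matrix; marginals and total mass are
#'   computed from it.
#' @return a [Coupling-class] object.
#' @examples
#' Coupling(diag(4) / 4)
#' @export
Coupling <- function(plan) {
    plan <- as.matrix(plan)
    storage.mode(plan) <- "double"
    new("Coupling", plan = plan,
        marginal1 = rowSums(plan), marginal2 = colSums(plan),
        totalMass = sum(plan))
}

#' @rdname plan
#' @export
setMethod("plan", "Coupling", function(x) x@plan)
#' @rdname plan
#' @export
setMethod("marginal1", "Coupling", function(x) x@marginal1)
#' @rdname plan
#' @export
setMethod("marginal2", "Coupling", function(x) x@marginal2)
#' @rdname plan
#' @export
setMethod("totalMass", "Coupling", function(x) x@totalMass)

setMethod("show", "Coupling", function(object) {
    cat("Coupling:", nrow(object@plan), "x", ncol(object@plan),
        "| total mass", format(object@totalMass, digits = 6), "\n")
})

## ---------------------------------------------------------------------------
## DistanceMatrix
## ---------------------------------------------------------------------------

#' Symmetric intra-domain distance matrix
#'
#' Pairwise distances within one domain, typically geodesic distances on a
#' k-nearest-neighbour graph, consumed by the Gromov-Wasserstein term.
#'
#' @slot values symmetric nonnegative numeric matrix with zero diagonal.
#' @seealso [knnGeodesic()], [normalizeDistances()]
#' @export
setClass("DistanceMatrix", representation(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v))
        msg <- c(msg, "distance matrix must be square")
    if (any(!is.finite(v)))
        msg <- c(msg, "distances must be finite")
    else {
        if (any(v < 0))
            msg <- c(msg, "distances must be nonnegative")
        if (max(abs(v - t(v))) > 1e-12)
            msg <- c(msg, "distance matrix must be symmetric within 1e-12")
        if (any(abs(diag(v)) > 0))
            msg <- c(msg, "diagonal must be zero")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DistanceMatrix
#'
#' @param values square symmetric nonnegative matrix with zero diagonal.
#'   Symmetry is enforced exactly by averaging with the transpose (guards
#'   against floating-point asymmetry of upstream shortest-path output).
#' @return a [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    values <- (values + t(values)) / 2
    diag(values) <- 0
    new("DistanceMatrix", values = values)
}

#' @rdname distValues
#' @export
setMethod("distValues", "DistanceMatrix", function(x) x@values)

setMethod("show", "DistanceMatrix", function(object) {
    cat("DistanceMatrix:", nrow(object@values), "x", ncol(object@values),
        "| max", format(max(object@values), digits = 6), "\n")
})

## ---------------------------------------------------------------------------
## SolverConfig
## ---------------------------------------------------------------------------

#' Hyperparameters for the unified alignment solver
#'
#' @slot alpha trade-off in `[0, 1]` between the Gromov-Wasserstein term
#'   (`alpha = 1`) and the co-optimal-transport term (`alpha = 0`).
#' @slot epsGW,epsCOOT positive entropic weights for the two terms.
#' @slot rhoGW1,rhoGW2 nonnegative marginal-relaxation weights of the GW
#'   term (`Inf` = hard balanced constraint).
#' @slot rhoCOOT1,rhoCOOT2 the analogous weights of the COOT term.
#' @slot betaSample,betaFeature nonnegative supervision strengths.
#' @slot supervisionSample optional cells-by-cells supervision matrix D
#'   (0 for known pairs, 1 otherwise by convention; any real matrix
#'   accepted).
#' @slot supervisionFeature optional features-by-features supervision
#'   matrix.
#' @slot nOuter maximum number of block-coordinate-descent sweeps.
#' @slot innerMaxIter,innerTol iteration budget and dual-change tolerance
#'   of each inner Sinkhorn solve; `innerTol` also stops the outer loop
#'   when the objective change falls below it.
#' @slot seed integer; retained for provenance (the solver itself is
#'   deterministic).
#' @export
setClass("SolverConfig",
         representation(alpha = "numeric",
                        epsGW = "numeric", epsCOOT = "numeric",
                        rhoGW1 = "numeric", rhoGW2 = "numeric",
                        rhoCOOT1 = "numeric", rhoCOOT2 = "numeric",
                        betaSample = "numeric", betaFeature = "numeric",
                        supervisionSample = "matrixOrNULL",
                        supervisionFeature = "matrixOrNULL",
                        nOuter = "integer",
                        innerMaxIter = "integer", innerTol = "numeric",
                        seed = "integer"))

setValidity("SolverConfig", function(object) {
    msg <- character()
    if (object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "alpha must lie in [0, 1]")
    if (object@epsGW <= 0 || object@epsCOOT <= 0)
        msg <- c(msg, "entropic weights must be positive")
    for (nm in c("rhoGW1", "rhoGW2", "rhoCOOT1", "rhoCOOT2"))
        if (slot(object, nm) < 0)
            msg <- c(msg, paste(nm, "must be nonnegative (Inf = balanced)"))
    if (object@betaSample < 0 || object@betaFeature < 0)
        msg <- c(msg, "supervision strengths must be nonnegative")
    if (object@nOuter < 1L || object@innerMaxIter < 1L)
        msg <- c(msg, "iteration budgets must be at least 1")
    if (object@innerTol <= 0)
        msg <- c(msg, "innerTol must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a SolverConfig
#'
#' Defaults follow the recommended desk-scale settings: entropic weights
#' of 1e-3 on distance matrices normalized to maximum 1, balanced
#' marginals (`rho = Inf`), no supervision, 50 outer sweeps with inner
#' Sinkhorn budget 1000 iterations at tolerance 1e-9.
#'
#' @param alpha GW/COOT trade-off in `[0, 1]`.
#' @param epsGW,epsCOOT entropic regularization weights.
#' @param rhoGW1,rhoGW2,rhoCOOT1,rhoCOOT2 marginal relaxation weights;
#'   `Inf` enforces the corresponding marginal exactly.
#' @param betaSample,betaFeature supervision strengths.
#' @param supervisionSample,supervisionFeature optional supervision
#'   matrices.
#' @param nOuter,innerMaxIter,innerTol iteration budgets and tolerance.
#' @param seed integer recorded for provenance.
#' @return a [SolverConfig-class] object.
#' @examples
#' SolverConfig(alpha = 1, epsGW = 1e-3)
#' @export
SolverConfig <- function(alpha = 1, epsGW = 1e-3, epsCOOT = 1e-3,
                         rhoGW1 = Inf, rhoGW2 = Inf,
                         rhoCOOT1 = Inf, rhoCOOT2 = Inf,
                         betaSample = 0, betaFeature = 0,
                         supervisionSample = NULL,
                         supervisionFeature = NULL,
                         nOuter = 50L, innerMaxIter = 1000L,
                         innerTol = 1e-9, seed = 0L) {
    sup <- function(m) {
        if (is.null(m)) return(NULL)
        m <- as.matrix(m); storage.mode(m) <- "double"; m
    }
    new("SolverConfig", alpha = alpha, epsGW = epsGW, epsCOOT = epsCOOT,
        rhoGW1 = rhoGW1, rhoGW2 = rhoGW2,
        rhoCOOT1 = rhoCOOT1, rhoCOOT2 = rhoCOOT2,
        betaSample = betaSample, betaFeature = betaFeature,
        supervisionSample = sup(supervisionSample),
        supervisionFeature = sup(supervisionFeature),
        nOuter = as.integer(nOuter),
        innerMaxIter = as.integer(innerMaxIter),
        innerTol = innerTol, seed = as.integer(seed))
}

setMethod("show", "SolverConfig", function(object) {
    rhoFmt <- function(r) if (is.infinite(r)) "Inf" else format(r)
    cat("SolverConfig: alpha =", object@alpha,
        "| epsGW =", object@epsGW, "epsCOOT =", object@epsCOOT, "\n")
    cat("  rhoGW = (", rhoFmt(object@rhoGW1), ",", rhoFmt(object@rhoGW2),
        ")  rhoCOOT = (", rhoFmt(object@rhoCOOT1), ",",
        rhoFmt(object@rhoCOOT2), ")\n")
    cat("  beta = (", object@betaSample, ",", object@betaFeature,
        ")  nOuter =", object@nOuter,
        " inner:", object@innerMaxIter, "@", object@innerTol, "\n")
})

setClassUnion("CouplingOrNULL", c("Coupling", "NULL"))

## ---------------------------------------------------------------------------
## AlignmentResult
## ---------------------------------------------------------------------------

#' Result of a block-coordinate-descent alignment run
#'
#' @slot P primary sample [Coupling-class] (domain 1 cells to domain 2
#'   cells).
#' @slot Pprime second sample coupling of the bi-coupling GW term.
#' @slot Q feature coupling, or `NULL` when `alpha = 1` (pure GW).
#' @slot lossTrace numeric vector of joint-objective values, one before
#'   the first sweep and one after each sweep.
#' @slot converged logical: did the objective change fall below tolerance
#'   before the sweep budget was exhausted?
#' @slot config the [SolverConfig-class] used.
#' @export
setClass("AlignmentResult",
         representation(P = "Coupling",
                        Pprime = "Coupling",
                        Q = "CouplingOrNULL",
                        lossTrace = "numeric",
                        converged = "logical",
                        config = "SolverConfig"))

setValidity("AlignmentResult", function(object) {
    msg <- character()
    if (length(object@lossTrace) < 1L)
        msg <- c(msg, "lossTrace must be non-empty")
    if ((object@config@alpha < 1) != !is.null(object@Q))
        msg <- c(msg, "Q must be present exactly when alpha < 1")
    if (length(msg)) msg else TRUE
})

#' @rdname sampleCoupling
#' @export
setMethod("sampleCoupling", "AlignmentResult", function(x) x@P)
#' @rdname sampleCoupling
#' @export
setMethod("sampleCouplingPrime", "AlignmentResult", function(x) x@Pprime)
#' @rdname sampleCoupling
#' @export
setMethod("featureCoupling", "AlignmentResult", function(x) x@Q)
#' @rdname sampleCoupling
#' @export
setMethod("lossTrace", "AlignmentResult", function(x) x@lossTrace)
#' @rdname sampleCoupling
#' @export
setMethod("hasConverged", "AlignmentResult", function(x) x@converged)
#' @rdname sampleCoupling
#' @export
setMethod("solverConfig", "AlignmentResult", function(x) x@config)

setMethod("show", "AlignmentResult", function(object) {
    cat("AlignmentResult\n")
    cat("  P:", nrow(object@P@plan), "x", ncol(object@P@plan),
        "| mass", format(object@P@totalMass, digits = 6), "\n")
    if (!is.null(object@Q))
        cat("  Q:", nrow(object@Q@plan), "x", ncol(object@Q@plan),
            "| mass", format(object@Q@totalMass, digits = 6), "\n")
    n <- length(object@lossTrace)
    cat("  sweeps:", n - 1L,
        "| final objective", format(object@lossTrace[n], digits = 8),
        "| converged:", object@converged, "\n")
})

## ---------------------------------------------------------------------------
## SyntheticMultiOmic
## ---------------------------------------------------------------------------

#' Synthetic paired multi-modal dataset with known ground truth
#'
#' Emulates a co-assay experiment: a shared latent cluster structure is
#' mapped into two feature spaces by distinct (possibly nonlinear) maps,
#' so every cell is measured in both modalities and the true cell-to-cell
#' and feature-to-feature correspondences are known.
#'
#' @slot X,Y the two modality [OmicsDataset-class]s.
#' @slot cellPairs two-column integer matrix of ground-truth cell
#'   correspondences (identity pairing before any downsampling).
#' @slot featurePairs two-column integer matrix of ground-truth feature
#'   correspondences.
#' @slot latent the generating low-dimensional coordinates.
#' @slot seed integer seed the dataset was generated from.
#' @seealso [makeMultiOmic()], [downsampleByType()]
#' @export
setClass("SyntheticMultiOmic",
         representation(X = "OmicsDataset", Y = "OmicsDataset",
                        cellPairs = "matrix", featurePairs = "matrix",
                        latent = "matrix", seed = "integer"))

setValidity("SyntheticMultiOmic", function(object) {
    msg <- character()
    if (ncol(object@cellPairs) != 2L || ncol(object@featurePairs) != 2L)
        msg <- c(msg, "pair matrices must have two columns")
    if (max(object@cellPairs[, 1L]) > nSamples(object@X) ||
        max(object@cellPairs[, 2L]) > nSamples(object@Y))
        msg <- c(msg, "cellPairs index out of range")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticMultiOmic", function(object) {
    cat("SyntheticMultiOmic (seed ", object@seed, ")\n", sep = "")
    cat("  X:", nSamples(object@X), "x", nFeatures(object@X),
        " Y:", nSamples(object@Y), "x", nFeatures(object@Y), "\n")
    cat("  ", nrow(object@cellPairs), "cell pairs,",
        nrow(object@featurePairs), "feature pairs\n")
})
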