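## Barycentric projection and alignment-quality metrics.

#' Barycentric projection across modalities
#'
#' Maps every cell of the first domain to the coupling-weighted average
#' of the second domain's measurements,
#' \deqn{\hat Y_i = \sum_j \frac{P_{ij}}{P_{\#1,i}} Y_j,}
#' producing an in-silico co-assay: the cells of domain 1 expressed in
#' the features of domain 2. Rows whose coupling mass is zero (possible
#' after unbalanced solves) are set to `NaN` with a warning.
#'
#' @param P a [Coupling-class] or plan matrix of shape `nx` by `ny`.
#' @param Y numeric matrix `ny` by `dy` (or an [OmicsDataset-class]).
#' @return the `nx` by `dy` projected matrix.
#' @examples
#' P <- matrix(c(0.3, 0.1, 0.2, 0.4), 2, 2)
#' barycentricProject(P, matrix(c(1, 3), 2, 1))   # rows 1.8 and 2.6
#' @export
barycentricProject <- function(P, Y) {
    p <- asPlan(P)
    if (is(Y, "OmicsDataset")) Y <- dataMatrix(Y)
    Y <- as.matrix(Y)
    if (ncol(p) != nrow(Y))
        stop("barycentricProject: ncol(P) must equal nrow(Y)")
    rs <- rowSums(p)
    zero <- rs <= 0
    if (any(zero)) {
        warning(sprintf(
            "barycentricProject: %d row(s) of P carry zero mass; projected rows set to NaN",
            sum(zero)))
        rs[zero] <- 1
    }
    out <- (p / rs) %*% Y
    out[zero, ] <- NaN
    out
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' Given two same-shape embeddings whose rows correspond 1-1 (row `i` of
#' `A` is the true match of row `i` of `B`), computes for every cell the
#' fraction of cells in the other domain that lie strictly closer (in
#' Euclidean distance) than its true match, and averages. `0` means every
#' cell's nearest counterpart is its true match; `0.5` is the expectation
#' under random matching. By default the metric is averaged over both
#' directions (`A` against `B` and `B` against `A`); set
#' `bidirectional = FALSE` for the single-direction variant.
#'
#' @param A,B numeric matrices of identical shape with aligned rows.
#' @param bidirectional average over both directions (default `TRUE`).
#' @return a scalar in `[0, 1]`.
#' @examples
#' foscttm(diag(3), diag(3))   # 0
#' @export
foscttm <- function(A, B, bidirectional = TRUE) {
    A <- as.matrix(A); B <- as.matrix(B)
    if (!all(dim(A) == dim(B)))
        stop("foscttm: A and B must have identical shape")
    n <- nrow(A)
    if (n < 2)
        stop("foscttm: need at least two samples")
    D <- .crossdist(A, B)            # D[i, j] = ||A_i - B_j||
    oneDir <- function(M) {          # rows = queries, cols = candidates
        true <- diag(M)
        mean((rowSums(M < true) - (diag(M) < true)) / (n - 1))
    }
    f1 <- oneDir(D)
    if (!bidirectional) return(f1)
    (f1 + oneDir(t(D))) / 2
}

## Euclidean cross-distance matrix
.crossdist <- function(A, B) {
    a2 <- rowSums(A^2); b2 <- rowSums(B^2)
    d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
}

#' Label-transfer accuracy
#'
#' Trains a k-nearest-neighbour classifier on one domain and scores it on
#' the (typically projected) other domain: the fraction of test cells
#' whose majority vote among the `k` nearest training cells equals their
#' true label. `k` defaults to the number of distinct training labels
#' (one neighbour per cell type). Vote ties are broken by the nearest
#' neighbour's label. Test labels unseen in training count as errors,
#' with a warning.
#'
#' @param trainPoints,testPoints numeric matrices in a shared space.
#' @param trainLabels,testLabels label vectors.
#' @param k number of neighbours; default `length(unique(trainLabels))`.
#' @return accuracy in `[0, 1]`.
#' @export
labelTransferAccuracy <- function(trainPoints, trainLabels,
                                  testPoints, testLabels, k = NULL) {
    trainPoints <- as.matrix(trainPoints)
    testPoints <- as.matrix(testPoints)
    trainLabels <- as.character(trainLabels)
    testLabels <- as.character(testLabels)
    if (nrow(trainPoints) == 0)
        stop("labelTransferAccuracy: empty training set")
    if (is.null(k)) k <- length(unique(trainLabels))
    k <- min(k, nrow(trainPoints))
    if (any(!testLabels %in% trainLabels))
        warning("labelTransferAccuracy: test labels unseen in training counted as errors")
    D <- .crossdist(testPoints, trainPoints)
    pred <- vapply(seq_len(nrow(testPoints)), function(i) {
        ord <- order(D[i, ])[seq_len(k)]
        votes <- table(trainLabels[ord])
        top <- names(votes)[votes == max(votes)]
        if (length(top) == 1L) top
        else trainLabels[ord][match(TRUE, trainLabels[ord] %in% top)]
    }, character(1))
    mean(pred == testLabels)
}

#' Mass of a feature coupling on known pairs
#'
#' Fraction of the feature coupling's total mass that sits on a list of
#' ground-truth feature pairs (for example biologically validated
#' antibody-gene pairs). Under a uniform coupling the expected value is
#' `length(pairs) / (dx * dy)`; a well-aligned feature map concentrates
#' far more. Invariant under positive rescaling of `Q`.
#'
#' @param Q a [Coupling-class] or plan matrix.
#' @param pairs two-column matrix (or list of length-2 vectors) of
#'   (row, column) indices.
#' @return a scalar in `[0, 1]` (0 with a warning for an empty pair
#'   list).
#' @examples
#' featureMassOnPairs(matrix(1 / 500, 25, 20), cbind(1:20, 1:20))  # 0.04
#' @export
featureMassOnPairs <- function(Q, pairs) {
    q <- asPlan(Q)
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    pairs <- as.matrix(pairs)
    if (nrow(pairs) == 0) {
        warning("featureMassOnPairs: empty pair list")
        return(0)
    }
    if (ncol(pairs) != 2L)
        stop("featureMassOnPairs: 'pairs' must have two columns")
    if (max(pairs[, 1]) > nrow(q) || max(pairs[, 2]) > ncol(q) ||
        min(pairs) < 1)
        stop("featureMassOnPairs: pair index out of range")
    sum(q[pairs]) / sum(q)
}

#' Cell-type-level matching accuracy
#'
#' Aggregates a cell-cell coupling into a cell-type alignment matrix
#' \eqn{A_{tu} = \sum_{i \in t, j \in u} P_{ij}}, predicts for every
#' row type the column type carrying the most mass, and scores the
#' predictions against a ground-truth type correspondence. Row types
#' absent from the truth map are excluded from the denominator; empty
#' types are excluded with a warning.
#'
#' @param P a [Coupling-class] or plan matrix.
#' @param labelsX,labelsY label vectors for the rows and columns of `P`.
#' @param truth named character vector or list mapping each row type to
#'   its true counterpart column type.
#' @return a list with `accuracy` (scalar), `matrix` (the aggregated
#'   type-by-type alignment matrix) and `predicted` (named character
#'   vector of argmax counterparts).
#' @export
celltypeMatchAccuracy <- function(P, labelsX, labelsY, truth) {
    p <- asPlan(P)
    labelsX <- as.character(labelsX); labelsY <- as.character(labelsY)
    if (length(labelsX) != nrow(p) || length(labelsY) != ncol(p))
        stop("celltypeMatchAccuracy: label lengths must match coupling shape")
    truth <- unlist(truth)
    tx <- sort(unique(labelsX)); ty <- sort(unique(labelsY))
    agg <- matrix(0, length(tx), length(ty), dimnames = list(tx, ty))
    for (t in tx) for (u in ty)
        agg[t, u] <- sum(p[labelsX == t, labelsY == u, drop = FALSE])
    empty <- rowSums(agg) == 0
    if (any(empty))
        warning("celltypeMatchAccuracy: empty row type(s) excluded: ",
                paste(tx[empty], collapse = ", "))
    predicted <- vapply(tx, function(t) ty[which.max(agg[t, ])],
                        character(1))
    scored <- tx[!empty & tx %in% names(truth)]
    acc <- if (length(scored) == 0) NA_real_
           else mean(predicted[scored] == unlist(truth[scored]))
    list(accuracy = acc, matrix = agg, predicted = predicted)
}
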