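## Intra-domain geometry: kNN-graph geodesics for the GW term, plus
## generic normalization / PCA plumbing.

#' Geodesic distances on a k-nearest-neighbour graph
#'
#' Builds the symmetrized (union of directed edges) kNN graph of the rows
#' of `X` in Euclidean space and returns all-pairs shortest-path
#' distances. This is the standard construction of the intra-domain
#' distance matrices that the Gromov-Wasserstein term compares: the graph
#' metric follows the data manifold rather than the ambient space.
#'
#' If the kNN graph is disconnected the components are reconnected before
#' shortest paths are computed: a minimum-spanning-tree over components
#' (weighted by the shortest Euclidean distance between any two of their
#' points) is added edge by edge, with a warning. Grid searches over `k`
#' therefore never fail on a disconnected graph.
#'
#' @param X numeric matrix, samples as rows.
#' @param k number of neighbours, `1 <= k < nrow(X)`.
#' @param weighted use Euclidean edge weights (default); `FALSE` gives
#'   unweighted hop-count geodesics.
#' @return a [DistanceMatrix-class] of all-pairs graph distances.
#' @examples
#' pts <- cbind(c(0, 1, 2), 0)
#' distValues(knnGeodesic(pts, k = 1))[1, 3]   # 2: path through the middle
#' @export
knnGeodesic <- function(X, k, weighted = TRUE) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (any(!is.finite(X)))
        stop("knnGeodesic: X must be finite")
    if (k < 1 || k >= n)
        stop("knnGeodesic: k must satisfy 1 <= k < nrow(X)")
    De <- as.matrix(stats::dist(X))

    ## union-symmetrized kNN adjacency
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        ord <- order(De[i, ])
        ord <- ord[ord != i][seq_len(k)]
        adj[i, ord] <- TRUE
    }
    adj <- adj | t(adj)

    ## reconnect components via an MST over components
    comp <- .components(adj)
    if (max(comp) > 1L) {
        warning(sprintf(
            "knnGeodesic: kNN graph has %d components; reconnecting via shortest Euclidean edges",
            max(comp)))
        nc <- max(comp)
        ## best inter-component edge for every component pair
        bestW <- matrix(Inf, nc, nc)
        bestI <- matrix(0L, nc, nc); bestJ <- matrix(0L, nc, nc)
        for (a in seq_len(nc - 1L)) for (b in seq(a + 1L, nc)) {
            ia <- which(comp == a); ib <- which(comp == b)
            sub <- De[ia, ib, drop = FALSE]
            w <- which.min(sub)
            ri <- (w - 1L) %% length(ia) + 1L
            ci <- (w - 1L) %/% length(ia) + 1L
            bestW[a, b] <- sub[ri, ci]
            bestI[a, b] <- ia[ri]; bestJ[a, b] <- ib[ci]
        }
        cg <- igraph::graph_from_adjacency_matrix(
            pmin(bestW, t(bestW), Inf), mode = "undirected",
            weighted = TRUE, diag = FALSE)
        mstEdges <- igraph::as_edgelist(igraph::mst(cg), names = FALSE)
        for (e in seq_len(nrow(mstEdges))) {
            a <- min(mstEdges[e, ]); b <- max(mstEdges[e, ])
            adj[bestI[a, b], bestJ[a, b]] <- TRUE
            adj[bestJ[a, b], bestI[a, b]] <- TRUE
        }
    }

    W <- matrix(0, n, n)
    W[adj] <- if (weighted) De[adj] else 1
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ## zero-weight edges (duplicate points) are dropped by the weighted
    ## adjacency constructor; add them back explicitly
    dup <- which(adj & De == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(dup))
        g <- igraph::add_edges(g, t(dup), weight = rep(0, nrow(dup)))
    D <- igraph::distances(g, algorithm = "dijkstra")
    DistanceMatrix(D)
}

## connected components of a logical adjacency matrix (BFS)
.components <- function(adj) {
    n <- nrow(adj)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cur <- cur + 1L
        queue <- s; comp[s] <- cur
        while (length(queue)) {
            v <- queue[[1L]]; queue <- queue[-1L]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}

#' Scale a distance matrix to unit maximum
#'
#' Divides all distances by the largest one so that the entropic weight
#' `eps` is comparable across domains whose raw scales differ. Applied by
#' default inside the GW pipeline (toggleable).
#'
#' @param D a [DistanceMatrix-class] or square numeric matrix.
#' @return a [DistanceMatrix-class] with maximum entry 1 (an all-zero
#'   matrix is returned unchanged with a warning).
#' @export
normalizeDistances <- function(D) {
    v <- if (is(D, "DistanceMatrix")) D@values else as.matrix(D)
    mx <- max(v)
    if (mx <= 0) {
        warning("normalizeDistances: all distances are zero; returning unchanged")
        return(DistanceMatrix(v))
    }
    DistanceMatrix(v / mx)
}

#' Principal component reduction
#'
#' Centers the data and projects onto the leading principal components,
#' ordered by decreasing explained variance. The sign of each component
#' is fixed so that its largest-magnitude loading is positive, making the
#' output deterministic.
#'
#' @param X numeric matrix, samples as rows.
#' @param nComponents number of components, at most `min(dim(X))`.
#' @return the `nrow(X)` by `nComponents` score matrix.
#' @export
reducePCA <- function(X, nComponents) {
    X <- as.matrix(X)
    if (nComponents < 1 || nComponents > min(dim(X)))
        stop("reducePCA: nComponents must be in [1, min(n, d)]")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
    scores <- pc$x[, seq_len(nComponents), drop = FALSE]
    for (j in seq_len(nComponents)) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) {
            rot[, j] <- -rot[, j]
            scores[, j] <- -scores[, j]
        }
    }
    unname(scores)
}
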