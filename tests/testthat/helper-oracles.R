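## Independent oracles used by the dual-route tests. These are
## deliberately naive (enumeration, quadruple loops, per-source Dijkstra)
## and share no code with the implementation they check.

# all permutations of 1..n (n small)
allPerms <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (p in allPerms(n - 1L))
        for (pos in seq_len(n))
            out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    out
}

# exact optimal transport cost for uniform marginals on a square cost
# matrix: the LP optimum is attained at a permutation vertex (Birkhoff)
exactOTCostUniform <- function(C) {
    n <- nrow(C)
    best <- Inf
    for (p in allPerms(n))
        best <- min(best, sum(C[cbind(seq_len(n), p)]) / n)
    best
}

# quadruple-loop GW local cost
naiveCostGW <- function(DX, DY, plan) {
    nx <- nrow(DX); ny <- nrow(DY)
    C <- matrix(0, nx, ny)
    for (i in seq_len(nx)) for (k in seq_len(ny))
        for (j in seq_len(nx)) for (l in seq_len(ny))
            C[i, k] <- C[i, k] + (DX[i, j] - DY[k, l])^2 * plan[j, l]
    C
}

# quadruple-loop COOT local cost over samples
naiveCostCOOTSamples <- function(X, Y, Q) {
    nx <- nrow(X); ny <- nrow(Y)
    C <- matrix(0, nx, ny)
    for (i in seq_len(nx)) for (k in seq_len(ny))
        for (j in seq_len(ncol(X))) for (l in seq_len(ncol(Y)))
            C[i, k] <- C[i, k] + (X[i, j] - Y[k, l])^2 * Q[j, l]
    C
}

naiveCostCOOTFeatures <- function(X, Y, P) {
    dx <- ncol(X); dy <- ncol(Y)
    C <- matrix(0, dx, dy)
    for (a in seq_len(dx)) for (b in seq_len(dy))
        for (i in seq_len(nrow(X))) for (k in seq_len(nrow(Y)))
            C[a, b] <- C[a, b] + (X[i, a] - Y[k, b])^2 * P[i, k]
    C
}

# per-source Dijkstra on a dense weighted adjacency (Inf = no edge)
naiveDijkstra <- function(W) {
    n <- nrow(W)
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        dist <- rep(Inf, n); dist[s] <- 0
        done <- rep(FALSE, n)
        for (step in seq_len(n)) {
            u <- which(!done)[which.min(dist[!done])]
            if (!length(u) || !is.finite(dist[u])) break
            done[u] <- TRUE
            for (v in which(is.finite(W[u, ])))
                if (dist[u] + W[u, v] < dist[v])
                    dist[v] <- dist[u] + W[u, v]
        }
        D[s, ] <- dist
    }
    D
}

# double-loop FOSCTTM, averaged over both directions
naiveFoscttm <- function(A, B) {
    n <- nrow(A)
    oneDir <- function(A, B) {
        tot <- 0
        for (i in seq_len(n)) {
            dTrue <- sqrt(sum((A[i, ] - B[i, ])^2))
            cnt <- 0
            for (j in seq_len(n)[-i])
                if (sqrt(sum((A[i, ] - B[j, ])^2)) < dTrue) cnt <- cnt + 1
            tot <- tot + cnt / (n - 1)
        }
        tot / n
    }
    (oneDir(A, B) + oneDir(B, A)) / 2
}

# small aligned problem instance for solver tests
makeInstance <- function(n, seed, d = 3) {
    set.seed(seed)
    X <- matrix(rnorm(n * d), n, d)
    Y <- X + matrix(rnorm(n * d, sd = 0.05), n, d)
    DX <- normalizeDistances(DistanceMatrix(as.matrix(dist(X))))
    DY <- normalizeDistances(DistanceMatrix(as.matrix(dist(Y))))
    list(X = X, Y = Y, DX = DX, DY = DY)
}
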