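## internal numerical helpers

# row-wise log-sum-exp, stable for large negative entries; max.col is
# C-level and much faster than apply() in the Sinkhorn inner loop
rowLSE <- function(A) {
    m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
    m0 <- ifelse(is.finite(m), m, 0)
    m0 + log(rowSums(exp(A - m0)))
}

colLSE <- function(A) rowLSE(t(A))

# sum p*log(p/r) with the 0*log(0) := 0 convention; p, r conforming arrays
plogpr <- function(p, r) {
    pos <- p > 0
    sum(p[pos] * log(p[pos] / r[pos]))
}

# extract a plan matrix from a Coupling or pass a matrix through
asPlan <- function(x) {
    if (is(x, "Coupling")) x@plan else as.matrix(x)
}

otaLog <- function(..., verbose = TRUE) {
    if (isTRUE(verbose))
        message(sprintf("[OTAlign %s] ", format(Sys.time(), "%H:%M:%S")), ...)
    invisible(NULL)
}
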