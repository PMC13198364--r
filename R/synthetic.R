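## Synthetic co-assay-like multi-modal data with known ground truth.

#' Generate a paired multi-modal dataset
#'
#' Draws cells in a low-dimensional latent space (a Gaussian mixture over
#' `nTypes` well-separated cluster centres by default, or a 1-D
#' trajectory) and maps them into two feature spaces:
#' \deqn{X = Z A^\top + \textrm{noise}, \qquad Y = g(Z B^\top) +
#' \textrm{noise},}
#' where `g` is an optional elementwise nonlinearity. The loading
#' matrices cycle the latent axes over the features, so feature `a` of
#' `X` and feature `a` of `Y` load on the same latent axis for
#' `a <= min(dx, dy)`; these are the ground-truth feature pairs. When
#' `dx` and `dy` are multiples of `latentDim` (and the map is linear and
#' noiseless) each loading matrix is a scaled isometry of the latent
#' space, so both domains inherit exactly the latent geometry. Every cell
#' is measured in both domains, giving the identity cell pairing; cluster
#' membership provides identical cell-type labels in both domains.
#'
#' This emulates the structure of co-assayed multi-omics (shared latent
#' state, modality-specific feature maps, known 1-1 correspondence and
#' known feature pairs). It does not emulate count sparsity, sequencing
#' depth, or dropout; conclusions from it concern alignment geometry,
#' not count-level preprocessing.
#'
#' @param nCells number of cells.
#' @param nTypes number of latent clusters / cell types.
#' @param dx,dy feature-space dimensions of the two modalities.
#' @param nonlinearity `"none"`, `"tanh"` or `"quadratic"` map applied
#'   elementwise to domain Y.
#' @param noiseSd standard deviation of additive Gaussian noise.
#' @param seed integer seed; the output is fully reproducible from it.
#' @param latentDim latent dimensionality (default 2).
#' @param mode `"clusters"` (Gaussian mixture, default) or
#'   `"trajectory"` (1-D curve; labels then mark trajectory thirds).
#' @return a [SyntheticMultiOmic-class].
#' @examples
#' d <- makeMultiOmic(nCells = 60, nTypes = 3, dx = 6, dy = 6,
#'                    noiseSd = 0.1, seed = 7)
#' d
#' @export
makeMultiOmic <- function(nCells = 100, nTypes = 3, dx = 10, dy = 10,
                          nonlinearity = c("none", "tanh", "quadratic"),
                          noiseSd = 0.1, seed = 1, latentDim = 2,
                          mode = c("clusters", "trajectory")) {
    nonlinearity <- match.arg(nonlinearity)
    mode <- match.arg(mode)
    if (nTypes > nCells)
        stop("makeMultiOmic: nTypes must not exceed nCells")
    if (dx < 2 || dy < 2 || latentDim < 1)
        stop("makeMultiOmic: dimensions must be at least 2 (latentDim >= 1)")
    if (noiseSd < 0)
        stop("makeMultiOmic: noiseSd must be nonnegative")

    withr_seed <- function(expr) {   # local RNG scope, restore afterwards
        old <- if (exists(".Random.seed", envir = globalenv()))
                   get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
        expr
    }
    withr_seed({
        if (mode == "clusters") {
            centers <- matrix(stats::rnorm(nTypes * latentDim, sd = 3),
                              nTypes, latentDim)
            type <- rep(seq_len(nTypes), length.out = nCells)
            type <- type[order(stats::runif(nCells))]
            Z <- centers[type, , drop = FALSE] +
                matrix(stats::rnorm(nCells * latentDim, sd = 0.5),
                       nCells, latentDim)
        } else {
            tpos <- sort(stats::runif(nCells))
            Z <- matrix(0, nCells, latentDim)
            Z[, 1] <- 6 * tpos - 3
            if (latentDim >= 2) Z[, 2] <- sin(pi * tpos)
            type <- cut(tpos, breaks = nTypes, labels = FALSE)
        }
        labels <- factor(paste0("type", type))

        loading <- function(d) {
            A <- matrix(0, d, latentDim)
            for (a in seq_len(d))
                A[a, (a - 1L) %% latentDim + 1L] <- 1
            A
        }
        A <- loading(dx); B <- loading(dy)
        Xm <- Z %*% t(A)
        Ym <- Z %*% t(B)
        Ym <- switch(nonlinearity,
                     none = Ym,
                     tanh = tanh(Ym),
                     quadratic = Ym + 0.25 * Ym^2)
        if (noiseSd > 0) {
            Xm <- Xm + matrix(stats::rnorm(length(Xm), sd = noiseSd),
                              nrow(Xm), ncol(Xm))
            Ym <- Ym + matrix(stats::rnorm(length(Ym), sd = noiseSd),
                              nrow(Ym), ncol(Ym))
        }
        ids <- sprintf("cell%03d", seq_len(nCells))
        X <- OmicsDataset(Xm, sampleIds = ids,
                          featureIds = sprintf("geneA%02d", seq_len(dx)),
                          labels = labels)
        Y <- OmicsDataset(Ym, sampleIds = ids,
                          featureIds = sprintf("featB%02d", seq_len(dy)),
                          labels = labels)
        m <- min(dx, dy)
        new("SyntheticMultiOmic", X = X, Y = Y,
            cellPairs = cbind(seq_len(nCells), seq_len(nCells)),
            featurePairs = cbind(seq_len(m), seq_len(m)),
            latent = Z, seed = as.integer(seed))
    })
}

#' Downsample a dataset by cell type
#'
#' For every cell type draws an independent fraction
#' `f ~ Uniform(0, maxFraction)` and removes `round(f * nType)` cells of
#' that type, chosen uniformly at random. Applying this independently
#' (with different seeds) to the two modalities of a paired dataset
#' produces the unbalanced regime of disproportionate cell-type
#' representation. Rounding is R's round-half-even.
#'
#' @param data an [OmicsDataset-class] with labels.
#' @param maxFraction upper bound of the removed fraction, in `[0, 1]`.
#' @param seed integer seed.
#' @return a list with `dataset` (the surviving [OmicsDataset-class]) and
#'   `kept` (integer indices into the original cells, for correspondence
#'   bookkeeping).
#' @export
downsampleByType <- function(data, maxFraction = 0.5, seed = 1) {
    if (is.null(cellLabels(data)))
        stop("downsampleByType: dataset has no labels")
    if (maxFraction < 0 || maxFraction > 1)
        stop("downsampleByType: maxFraction must lie in [0, 1]")
    labels <- cellLabels(data)
    old <- if (exists(".Random.seed", envir = globalenv()))
               get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    drop <- integer(0)
    for (t in levels(labels)) {
        idx <- which(labels == t)
        f <- stats::runif(1, 0, maxFraction)
        nRemove <- round(f * length(idx))
        if (nRemove >= length(idx))
            stop(sprintf("downsampleByType: type '%s' reduced to zero cells", t))
        if (nRemove > 0)
            drop <- c(drop, sample(idx, nRemove))
    }
    kept <- setdiff(seq_along(labels), drop)
    list(dataset = data[kept], kept = kept)
}
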