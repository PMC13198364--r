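## File I/O: dense TSV/CSV and MatrixMarket MTX with id sidecars, dense
## coupling files, JSON run configurations.

.sidecarPaths <- function(path) {
    stem <- sub("\\.mtx$", "", path)
    list(rows = paste0(stem, "_rows.txt"), cols = paste0(stem, "_cols.txt"))
}

#' Read one modality from disk
#'
#' Dense TSV/CSV files are expected with a header row of feature ids and
#' a first column of cell ids; MatrixMarket `.mtx` files follow the
#' coordinate standard and are densified, with cell and feature ids read
#' from the `<stem>_rows.txt` / `<stem>_cols.txt` sidecars (one id per
#' line). Orientation is cells-as-rows everywhere; use `transpose = TRUE`
#' for genes-as-rows files.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   file extension.
#' @param labelsPath optional file of per-cell labels: either one label
#'   per line, or two tab-separated columns `id<TAB>label`.
#' @param transpose transpose the matrix after reading.
#' @return an [OmicsDataset-class].
#' @export
readDataset <- function(path, format = NULL, labelsPath = NULL,
                        transpose = FALSE) {
    if (!file.exists(path))
        stop(sprintf("readDataset: file not found: %s", path))
    if (is.null(format))
        format <- switch(tolower(tools::file_ext(path)),
                         tsv = "tsv", txt = "tsv", csv = "csv",
                         mtx = "mtx",
                         stop("readDataset: cannot guess format of ", path))
    format <- match.arg(format, c("tsv", "csv", "mtx"))
    if (format == "mtx") {
        side <- .sidecarPaths(path)
        for (f in unlist(side))
            if (!file.exists(f))
                stop(sprintf("readDataset: missing id sidecar: %s", f))
        m <- as.matrix(Matrix::readMM(path))
        rows <- readLines(side$rows)
        cols <- readLines(side$cols)
        if (length(rows) != nrow(m) || length(cols) != ncol(m))
            stop(sprintf(
                "readDataset: sidecar id counts (%d, %d) disagree with %s (%d x %d)",
                length(rows), length(cols), path, nrow(m), ncol(m)))
        rownames(m) <- rows; colnames(m) <- cols
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                row.names = 1, check.names = FALSE,
                                stringsAsFactors = FALSE)
        m <- as.matrix(df)
        if (!is.numeric(m)) {
            bad <- which(!vapply(df, is.numeric, logical(1)))[1]
            stop(sprintf(
                "readDataset: non-numeric values in column '%s' of %s",
                colnames(df)[bad], path))
        }
    }
    if (transpose) m <- t(m)
    labels <- NULL
    if (!is.null(labelsPath)) {
        lab <- utils::read.table(labelsPath, header = FALSE, sep = "\t",
                                 stringsAsFactors = FALSE)
        labels <- if (ncol(lab) >= 2) {
            ord <- match(rownames(m), lab[[1]])
            if (anyNA(ord))
                stop(sprintf(
                    "readDataset: %d cell id(s) missing from label file %s",
                    sum(is.na(ord)), labelsPath))
            lab[[2]][ord]
        } else lab[[1]]
        if (length(labels) != nrow(m))
            stop(sprintf(
                "readDataset: label count (%d) disagrees with cell count (%d) in %s",
                length(labels), nrow(m), labelsPath))
    }
    OmicsDataset(m, labels = labels)
}

#' Write one modality to disk
#'
#' Inverse of [readDataset()]; round trips are lossless to full double
#' precision for TSV/CSV and exact for MTX.
#'
#' @param data an [OmicsDataset-class].
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"` (default from extension).
#' @param labelsPath optional path for a two-column `id<TAB>label` file.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(data, path, format = NULL, labelsPath = NULL) {
    if (is.null(format))
        format <- switch(tolower(tools::file_ext(path)),
                         tsv = "tsv", txt = "tsv", csv = "csv",
                         mtx = "mtx",
                         stop("writeDataset: cannot guess format of ", path))
    format <- match.arg(format, c("tsv", "csv", "mtx"))
    m <- dataMatrix(data)
    if (format == "mtx") {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        side <- .sidecarPaths(path)
        writeLines(sampleIds(data), side$rows)
        writeLines(featureIds(data), side$cols)
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- data.frame(id = sampleIds(data),
                         format(m, digits = 17, trim = TRUE,
                                scientific = TRUE),
                         check.names = FALSE)
        colnames(df) <- c("id", featureIds(data))
        utils::write.table(df, path, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(labelsPath) && !is.null(cellLabels(data)))
        utils::write.table(
            data.frame(sampleIds(data), as.character(cellLabels(data))),
            labelsPath, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write / read a coupling as dense TSV
#'
#' Couplings are written dense with row and column ids so that they can
#' be inspected directly; `readCoupling` reproduces row and column sums
#' to full precision.
#'
#' @param P a [Coupling-class] or plan matrix.
#' @param path TSV file path.
#' @param rowIds,colIds optional identifier vectors.
#' @return `writeCoupling` returns `path` invisibly; `readCoupling`
#'   returns a [Coupling-class].
#' @export
writeCoupling <- function(P, path, rowIds = NULL, colIds = NULL) {
    p <- asPlan(P)
    if (is.null(rowIds)) rowIds <- rownames(p)
    if (is.null(rowIds)) rowIds <- paste0("r", seq_len(nrow(p)))
    if (is.null(colIds)) colIds <- colnames(p)
    if (is.null(colIds)) colIds <- paste0("c", seq_len(ncol(p)))
    df <- data.frame(id = rowIds,
                     format(p, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     check.names = FALSE)
    colnames(df) <- c("id", colIds)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCoupling
#' @export
readCoupling <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE)
    Coupling(as.matrix(df))
}

## ---------------------------------------------------------------------------
## RunConfig: plain serializable list with a validator
## ---------------------------------------------------------------------------

#' Assemble a pipeline run configuration
#'
#' A `RunConfig` is a plain named list (JSON-serializable, lossless round
#' trip) bundling the alignment mode, solver hyperparameters,
#' preprocessing options and metric toggles consumed by
#' [runPipeline()].
#'
#' @param mode alignment formulation, see [alignOT()].
#' @param alpha,epsGW,epsCOOT,rhoGW,rhoCOOT,betaSample,betaFeature solver
#'   hyperparameters (`rhoGW`/`rhoCOOT` set both sides; `NULL` rho =
#'   balanced).
#' @param nOuter,innerMaxIter,innerTol iteration budgets.
#' @param k kNN graph size for geodesic distances (`NULL`: `max(5,
#'   round(n/5))`, capped at `n - 1`).
#' @param pcaComponents optional number of principal components applied
#'   to both domains before alignment.
#' @param normalize per-domain preprocessing: `"none"`, `"l2"` (cells to
#'   unit norm) or `"zscore"` (features standardized).
#' @param normalizeDistances divide each geodesic matrix by its maximum.
#' @param metrics character vector among `"foscttm"`, `"lta"`,
#'   `"featureMass"`, `"density"`.
#' @param inputX,inputY,labelsX,labelsY optional input file paths (used
#'   by [runPipeline()] when no in-memory datasets are supplied).
#' @param transpose transpose input matrices on read (genes-as-rows
#'   files).
#' @param outDir optional output directory for couplings, projections
#'   and the metrics report.
#' @param seed integer seed recorded and used by any stochastic stage.
#' @return a named list of class `RunConfig`.
#' @export
runConfig <- function(mode = "gw", alpha = NULL,
                      epsGW = 1e-3, epsCOOT = 1e-3,
                      rhoGW = NULL, rhoCOOT = NULL,
                      betaSample = 0, betaFeature = 0,
                      nOuter = 50L, innerMaxIter = 1000L, innerTol = 1e-9,
                      k = NULL, pcaComponents = NULL,
                      normalize = "none", normalizeDistances = TRUE,
                      metrics = c("foscttm", "lta", "density"),
                      inputX = NULL, inputY = NULL,
                      labelsX = NULL, labelsY = NULL,
                      transpose = FALSE, outDir = NULL,
                      seed = 0L) {
    mode <- match.arg(mode, c("gw", "ugw", "coot", "ucoot", "agw", "uagw"))
    normalize <- match.arg(normalize, c("none", "l2", "zscore"))
    num <- function(x) if (is.null(x)) NULL else as.double(x)
    int <- function(x) if (is.null(x)) NULL else as.integer(x)
    cfg <- list(mode = mode, alpha = num(alpha), epsGW = as.double(epsGW),
                epsCOOT = as.double(epsCOOT),
                rhoGW = num(rhoGW), rhoCOOT = num(rhoCOOT),
                betaSample = as.double(betaSample),
                betaFeature = as.double(betaFeature),
                nOuter = as.integer(nOuter),
                innerMaxIter = as.integer(innerMaxIter),
                innerTol = as.double(innerTol), k = int(k),
                pcaComponents = int(pcaComponents), normalize = normalize,
                normalizeDistances = normalizeDistances,
                metrics = metrics,
                inputX = inputX, inputY = inputY,
                labelsX = labelsX, labelsY = labelsY,
                transpose = isTRUE(transpose), outDir = outDir,
                seed = as.integer(seed))
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Serialize / deserialize a RunConfig
#'
#' JSON round trips are lossless: `readRunConfig(writeRunConfig(x, f))`
#' reproduces `x`.
#'
#' @param config a `RunConfig` (see [runConfig()]).
#' @param path JSON file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig`
#'   returns the `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    raw$metrics <- as.character(raw$metrics)
    do.call(runConfig, raw[!vapply(raw, is.null, logical(1))])
}

## expand a RunConfig into a SolverConfig + mode
.solverConfigFromRun <- function(cfg) {
    alpha <- cfg$alpha
    if (is.null(alpha))
        alpha <- switch(cfg$mode, gw = 1, ugw = 1, coot = 0, ucoot = 0, 0.3)
    rg <- if (is.null(cfg$rhoGW)) Inf else cfg$rhoGW
    rc <- if (is.null(cfg$rhoCOOT)) Inf else cfg$rhoCOOT
    SolverConfig(alpha = alpha, epsGW = cfg$epsGW, epsCOOT = cfg$epsCOOT,
                 rhoGW1 = rg, rhoGW2 = rg, rhoCOOT1 = rc, rhoCOOT2 = rc,
                 betaSample = cfg$betaSample, betaFeature = cfg$betaFeature,
                 nOuter = cfg$nOuter, innerMaxIter = cfg$innerMaxIter,
                 innerTol = cfg$innerTol, seed = cfg$seed)
}
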