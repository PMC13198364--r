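## End-to-end pipeline and grid-search runners.

.preprocess <- function(m, cfg) {
    m <- switch(cfg$normalize,
                none = m,
                l2 = {
                    nrm <- sqrt(rowSums(m^2)); nrm[nrm == 0] <- 1
                    m / nrm
                },
                zscore = {
                    s <- apply(m, 2L, stats::sd); s[s == 0] <- 1
                    sweep(sweep(m, 2L, colMeans(m)), 2L, s, "/")
                })
    if (!is.null(cfg$pcaComponents))
        m <- reducePCA(m, min(cfg$pcaComponents, dim(m)))
    m
}

.defaultK <- function(n) min(n - 1L, max(5L, round(n / 5)))

#' Run the full alignment pipeline
#'
#' Executes normalize -> optional PCA -> kNN geodesic distances (when the
#' formulation has a GW term) -> alignment -> barycentric projection ->
#' metrics. Datasets are taken from `X` / `Y` when supplied, otherwise
#' read from the paths in the configuration. When `config$outDir` is set,
#' the couplings (dense TSV), the projected data, the loss trace, the
#' configuration and a flat JSON metrics report are written there, and
#' every hyperparameter plus the package version is logged.
#'
#' FOSCTTM is only computed when the two domains have equal cell counts
#' (rows are then assumed to correspond 1-1, as in a co-assay);
#' label-transfer accuracy needs labels on both domains. Both are skipped
#' silently otherwise.
#'
#' @param config a `RunConfig`, see [runConfig()].
#' @param X,Y optional [OmicsDataset-class] inputs overriding the
#'   configured paths.
#' @param featurePairs optional two-column matrix of ground-truth feature
#'   pairs for the `featureMass` metric.
#' @param verbose print stage logs.
#' @return a list with `result` (an [AlignmentResult-class]), `metrics`
#'   (flat named list), `projected` (the projected matrix) and `config`.
#' @export
runPipeline <- function(config, X = NULL, Y = NULL, featurePairs = NULL,
                        verbose = FALSE) {
    stage <- "configuration"
    tryCatch({
        if (!inherits(config, "RunConfig"))
            stop("runPipeline: 'config' must be a RunConfig")
        stage <- "input"
        if (is.null(X)) {
            if (is.null(config$inputX))
                stop("no in-memory X and no inputX path configured")
            X <- readDataset(config$inputX, labelsPath = config$labelsX,
                             transpose = config$transpose)
        }
        if (is.null(Y)) {
            if (is.null(config$inputY))
                stop("no in-memory Y and no inputY path configured")
            Y <- readDataset(config$inputY, labelsPath = config$labelsY,
                             transpose = config$transpose)
        }
        scf <- .solverConfigFromRun(config)
        otaLog(sprintf(
            "pipeline: mode=%s alpha=%g epsGW=%g epsCOOT=%g rhoGW=%g rhoCOOT=%g k=%s seed=%d (OTAlign %s)",
            config$mode, scf@alpha, scf@epsGW, scf@epsCOOT,
            scf@rhoGW1, scf@rhoCOOT1,
            if (is.null(config$k)) "auto" else config$k, config$seed,
            as.character(utils::packageVersion("OTAlign"))),
            verbose = verbose)

        stage <- "preprocessing"
        Xm <- .preprocess(dataMatrix(X), config)
        Ym <- .preprocess(dataMatrix(Y), config)

        stage <- "geodesic distances"
        DX <- DY <- NULL
        if (scf@alpha > 0) {
            kx <- if (is.null(config$k)) .defaultK(nrow(Xm))
                  else min(config$k, nrow(Xm) - 1L)
            ky <- if (is.null(config$k)) .defaultK(nrow(Ym))
                  else min(config$k, nrow(Ym) - 1L)
            DX <- knnGeodesic(Xm, kx)
            DY <- knnGeodesic(Ym, ky)
            if (isTRUE(config$normalizeDistances)) {
                DX <- normalizeDistances(DX)
                DY <- normalizeDistances(DY)
            }
        }

        stage <- "alignment"
        res <- alignOT(config$mode, X = Xm, Y = Ym, DX = DX, DY = DY,
                       config = scf, verbose = verbose)

        stage <- "projection"
        projected <- suppressWarnings(
            barycentricProject(sampleCoupling(res), Ym))

        stage <- "metrics"
        metrics <- list(mode = config$mode,
                        finalObjective = utils::tail(lossTrace(res), 1),
                        converged = hasConverged(res),
                        massP = totalMass(sampleCoupling(res)))
        if ("density" %in% config$metrics) {
            metrics$densityP <- couplingDensity(sampleCoupling(res))
            if (!is.null(featureCoupling(res)))
                metrics$densityQ <- couplingDensity(featureCoupling(res))
        }
        if ("foscttm" %in% config$metrics && nrow(Xm) == nrow(Ym) &&
            !anyNA(projected))
            metrics$foscttm <- foscttm(projected, Ym)
        if ("lta" %in% config$metrics && !is.null(cellLabels(X)) &&
            !is.null(cellLabels(Y)) && !anyNA(projected))
            metrics$lta <- labelTransferAccuracy(
                Ym, cellLabels(Y), projected, cellLabels(X))
        if ("featureMass" %in% config$metrics &&
            !is.null(featureCoupling(res)) && !is.null(featurePairs))
            metrics$featureMass <- featureMassOnPairs(
                featureCoupling(res), featurePairs)

        stage <- "output"
        if (!is.null(config$outDir)) {
            dir.create(config$outDir, recursive = TRUE,
                       showWarnings = FALSE)
            out <- function(f) file.path(config$outDir, f)
            writeCoupling(sampleCoupling(res), out("coupling_P.tsv"),
                          sampleIds(X), sampleIds(Y))
            writeCoupling(sampleCouplingPrime(res),
                          out("coupling_Pprime.tsv"),
                          sampleIds(X), sampleIds(Y))
            if (!is.null(featureCoupling(res)))
                writeCoupling(featureCoupling(res), out("coupling_Q.tsv"),
                              featureIds(X), featureIds(Y))
            utils::write.table(
                data.frame(sweep = seq_along(lossTrace(res)) - 1L,
                           objective = lossTrace(res)),
                out("loss_trace.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
            proj <- projected
            rownames(proj) <- sampleIds(X); colnames(proj) <- featureIds(Y)
            writeDataset(OmicsDataset(proj), out("projected.tsv"))
            jsonlite::write_json(metrics, out("metrics.json"),
                                 auto_unbox = TRUE, digits = NA)
            writeRunConfig(config, out("config.json"))
        }
        list(result = res, metrics = metrics, projected = projected,
             config = config)
    }, error = function(e) {
        stop(sprintf("runPipeline failed at stage '%s': %s",
                     stage, conditionMessage(e)), call. = FALSE)
    })
}

#' Hyperparameter grid search
#'
#' Runs [runPipeline()] for every combination of the supplied
#' hyperparameter values, records the requested metrics together with the
#' coupling-density diagnostic, and returns the results ranked by the
#' chosen metric (ascending for FOSCTTM, descending otherwise). A failing
#' combination is recorded as a failed row; the grid continues. A
#' practical recipe: search `epsGW` / `epsCOOT` on a log grid (for
#' example `10^seq(-3, -1, by = 0.1)`) until the sample and feature
#' couplings reach a reasonable density, then search `rhoGW` / `rhoCOOT`
#' over `c(0.01, 0.1, 1)` if the populations are unbalanced, and finally
#' a narrow range of `alpha` (0.1 to 0.5) for the augmented
#' formulations.
#'
#' @param config base `RunConfig`.
#' @param grid named list of vectors over any of `epsGW`, `epsCOOT`,
#'   `rhoGW`, `rhoCOOT`, `alpha` (also accepts `k`, `betaSample`,
#'   `betaFeature`).
#' @param X,Y optional in-memory datasets.
#' @param rankBy metric column used for ranking (default `"foscttm"`,
#'   falling back to `"densityP"` when FOSCTTM is unavailable).
#' @param verbose print one log line per combination.
#' @return a `data.frame`, one row per combination, with hyperparameters,
#'   metric columns, `error` (NA on success) and an attribute `"configs"`
#'   holding the per-run `RunConfig`s.
#' @export
gridSearch <- function(config, grid, X = NULL, Y = NULL,
                       rankBy = "foscttm", verbose = FALSE) {
    if (!length(grid))
        stop("gridSearch: empty grid")
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    rows <- vector("list", nrow(combos))
    cfgs <- vector("list", nrow(combos))
    for (i in seq_len(nrow(combos))) {
        cfg <- config
        for (nm in names(combos)) cfg[[nm]] <- combos[i, nm]
        cfg$outDir <- NULL
        cfgs[[i]] <- cfg
        res <- tryCatch(runPipeline(cfg, X = X, Y = Y),
                        error = function(e) e)
        if (inherits(res, "error")) {
            rows[[i]] <- cbind(.run = i, combos[i, , drop = FALSE],
                               error = conditionMessage(res))
        } else {
            met <- res$metrics
            met <- met[vapply(met, is.numeric, logical(1))]
            rows[[i]] <- cbind(.run = i, combos[i, , drop = FALSE],
                               as.data.frame(met), error = NA_character_)
        }
        if (verbose)
            otaLog(sprintf("grid %d/%d done", i, nrow(combos)))
    }
    out <- do.call(rbind, lapply(rows, function(r) {
        allCols <- unique(unlist(lapply(rows, names)))
        for (m in setdiff(allCols, names(r))) r[[m]] <- NA
        r[allCols]
    }))
    rownames(out) <- NULL
    if (!rankBy %in% names(out) && "densityP" %in% names(out))
        rankBy <- "densityP"
    if (rankBy %in% names(out)) {
        decreasing <- rankBy != "foscttm"
        out <- out[order(out[[rankBy]], decreasing = decreasing,
                         na.last = TRUE), , drop = FALSE]
        rownames(out) <- NULL
    }
    attr(out, "configs") <- cfgs[out$.run]
    out$.run <- NULL
    out
}
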