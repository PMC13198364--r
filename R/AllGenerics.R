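#' @import methods
NULL

#' Transport plan of a coupling
#'
#' @param x a [Coupling-class] object.
#' @return For `plan`, the nonnegative transport-plan matrix. `marginal1`
#'   and `marginal2` return its row- and column-sum pushforwards,
#'   `totalMass` the sum of all entries.
#' @aliases marginal1 marginal2 totalMass
#' @examples
#' cp <- Coupling(matrix(0.25, 2, 2))
#' plan(cp)
#' totalMass(cp)
#' @export
setGeneric("plan", function(x) standardGeneric("plan"))

#' @rdname plan
#' @export
setGeneric("marginal1", function(x) standardGeneric("marginal1"))

#' @rdname plan
#' @export
setGeneric("marginal2", function(x) standardGeneric("marginal2"))

#' @rdname plan
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' Accessors for alignment results
#'
#' @param x an [AlignmentResult-class] object.
#' @return `sampleCoupling` and `sampleCouplingPrime` return the two
#'   sample-level [Coupling-class] objects, `featureCoupling` the feature
#'   coupling (or `NULL` when the run had no co-optimal-transport term),
#'   `lossTrace` the per-sweep objective values, `hasConverged` a logical,
#'   and `solverConfig` the [SolverConfig-class] used.
#' @aliases sampleCouplingPrime featureCoupling lossTrace hasConverged
#'   solverConfig
#' @export
setGeneric("sampleCoupling", function(x) standardGeneric("sampleCoupling"))

#' @rdname sampleCoupling
#' @export
setGeneric("sampleCouplingPrime",
           function(x) standardGeneric("sampleCouplingPrime"))

#' @rdname sampleCoupling
#' @export
setGeneric("featureCoupling", function(x) standardGeneric("featureCoupling"))

#' @rdname sampleCoupling
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname sampleCoupling
#' @export
setGeneric("hasConverged", function(x) standardGeneric("hasConverged"))

#' @rdname sampleCoupling
#' @export
setGeneric("solverConfig", function(x) standardGeneric("solverConfig"))

#' Accessors for omics datasets
#'
#' @param x an [OmicsDataset-class] object.
#' @return `dataMatrix` returns the cells-by-features numeric matrix,
#'   `sampleIds` and `featureIds` the identifier vectors, `cellLabels` the
#'   per-cell type labels (factor, or `NULL` when absent), `nSamples` and
#'   `nFeatures` the dimensions.
#' @aliases sampleIds featureIds cellLabels nSamples nFeatures
#' @export
setGeneric("dataMatrix", function(x) standardGeneric("dataMatrix"))

#' @rdname dataMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname dataMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname dataMatrix
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname dataMatrix
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname dataMatrix
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Distance-matrix values
#'
#' @param x a [DistanceMatrix-class] object.
#' @return the symmetric numeric matrix of pairwise distances.
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))
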