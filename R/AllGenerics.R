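#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData "rowData<-"
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median quantile rgamma rnorm runif rpois rbinom sd var
#'   dpois dnorm integrate setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

#' Area identifiers
#'
#' @param x an object carrying a set of areas.
#' @return Character vector of area identifiers, in storage order.
#' @export
setGeneric("areaIds", function(x) standardGeneric("areaIds"))

#' Neighbor structure as an adjacency list
#'
#' @param x an [AreaGraph-class].
#' @return Named list; element `i` holds the integer indices of the
#'   neighbors of area `i`.
#' @export
setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))

#' Vertex degrees
#'
#' @param x an [AreaGraph-class].
#' @return Integer vector of neighbor counts, named by area id.
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' Connected-component labels
#'
#' @param x an [AreaGraph-class].
#' @return Integer vector assigning each area to a connected component
#'   (labels are 1-based and contiguous).
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' Number of connected components
#'
#' @param x an [AreaGraph-class].
#' @return Integer scalar.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Observed event counts
#'
#' @param x an [AreaExperiment-class].
#' @return Integer matrix, areas x strata.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Person-years at risk
#'
#' @param x an [AreaExperiment-class].
#' @return Numeric matrix, areas x strata.
#' @export
setGeneric("personYears", function(x) standardGeneric("personYears"))

#' Extract the area adjacency graph
#'
#' @param x an [AreaExperiment-class].
#' @return The [AreaGraph-class] stored with the experiment, or `NULL`.
#' @export
setGeneric("areaGraph", function(x) standardGeneric("areaGraph"))

#' @rdname areaGraph
#' @param value an [AreaGraph-class] whose `areaIds` match `rownames(x)`.
#' @export
setGeneric("areaGraph<-", function(x, value) standardGeneric("areaGraph<-"))

#' Posterior draws of a model quantity
#'
#' @param x a [BymFit-class].
#' @param parameter one of `"alpha"`, `"beta"`, `"u"`, `"v"`,
#'   `"tau_u"`, `"tau_v"`.
#' @return A matrix of retained draws (iterations x dimension), with chains
#'   stacked row-wise.
#' @export
setGeneric("posteriorDraws", function(x, parameter) {
  standardGeneric("posteriorDraws")
})
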