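#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom stats cor sd rnorm runif pnorm p.adjust kruskal.test quantile
#' @importFrom utils read.csv write.csv head
NULL

#' @export
setGeneric("blockId", function(x) standardGeneric("blockId"))

#' @export
setGeneric("measurements", function(x, ...) standardGeneric("measurements"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("featureUnits", function(x) standardGeneric("featureUnits"))

#' @export
setGeneric("blockIds", function(x) standardGeneric("blockIds"))

#' @export
setGeneric("getBlock", function(x, id) standardGeneric("getBlock"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("autoscale", function(x, ...) standardGeneric("autoscale"))

#' @export
setGeneric("scaleCenter", function(x) standardGeneric("scaleCenter"))

#' @export
setGeneric("scaleSd", function(x) standardGeneric("scaleSd"))
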