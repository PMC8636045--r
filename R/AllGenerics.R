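#' @rdname ChromExpression-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ChromExpression-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ChromExpression-accessors
#' @export
setGeneric("geneRanks", function(x) standardGeneric("geneRanks"))

#' @rdname ChromExpression-accessors
#' @export
setGeneric("geneStartBp", function(x) standardGeneric("geneStartBp"))

#' @rdname ChromExpression-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname ChromExpression-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname corValues
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname eigenSpectrum
#' @export
setGeneric("eigenSpectrum", function(x, ...) standardGeneric("eigenSpectrum"))

#' @rdname eigenvalues
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("clusterObjective", function(x) standardGeneric("clusterObjective"))

#' @rdname nndValues
#' @export
setGeneric("nndValues", function(x) standardGeneric("nndValues"))
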