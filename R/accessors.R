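#' Accessors for ChromExpression objects
#'
#' \code{exprValues} returns the genes x samples expression matrix;
#' \code{geneIds} the gene identifiers (matrix row order); \code{geneRanks}
#' the 0-based ordinal position of each gene along its chromosome after
#' sorting by start coordinate; \code{geneStartBp} the 0-based (BED
#' convention) start coordinate; \code{geneRanges} the underlying
#' \linkS4class{GRanges}; \code{phenotype} the phenotype label.
#'
#' @param x a \linkS4class{ChromExpression}, \linkS4class{CorrelationMatrix}
#'   or \linkS4class{DissimilarityMatrix}.
#' @return See the individual descriptions.
#' @name ChromExpression-accessors
#' @aliases exprValues geneIds geneRanks geneStartBp phenotype geneRanges
NULL

#' @rdname ChromExpression-accessors
#' @export
setMethod("exprValues", "ChromExpression", function(x) {
    m <- SummarizedExperiment::assay(x, "expr")
    rownames(m) <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$gene_id
    m
})

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneIds", "ChromExpression", function(x)
    S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$gene_id)

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneRanks", "ChromExpression", function(x)
    as.integer(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$rank))

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneStartBp", "ChromExpression", function(x)
    GenomicRanges::start(SummarizedExperiment::rowRanges(x)) - 1L)

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneRanges", "ChromExpression", function(x)
    SummarizedExperiment::rowRanges(x))

#' @rdname ChromExpression-accessors
#' @export
setMethod("phenotype", "ChromExpression", function(x) {
    p <- S4Vectors::metadata(x)$phenotype
    if (is.null(p)) NA_character_ else p
})

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneIds", "GRanges", function(x) S4Vectors::mcols(x)$gene_id)

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneRanks", "GRanges", function(x)
    as.integer(S4Vectors::mcols(x)$rank))

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneStartBp", "GRanges", function(x) GenomicRanges::start(x) - 1L)

#' Correlation / dissimilarity matrix values
#'
#' @param x a \linkS4class{CorrelationMatrix} or
#'   \linkS4class{DissimilarityMatrix}.
#' @return the numeric matrix, with gene ids as dimnames.
#' @name corValues
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@values)

#' @rdname corValues
#' @export
setMethod("corValues", "DissimilarityMatrix", function(x) x@values)

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneRanges", "CorrelationMatrix", function(x) x@genes)

#' @rdname ChromExpression-accessors
#' @export
setMethod("geneRanges", "DissimilarityMatrix", function(x) x@genes)

#' @rdname ChromExpression-accessors
#' @export
setMethod("phenotype", "CorrelationMatrix", function(x) x@phenotype)

#' Eigenvalues of a spectrum
#'
#' @param x an \linkS4class{EigenSpectrum} or \linkS4class{NullEnsemble};
#'   for an ensemble, the per-member largest eigenvalues are returned.
#' @return numeric vector.
#' @name eigenvalues
#' @export
setMethod("eigenvalues", "EigenSpectrum", function(x) x@values)

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "NullEnsemble", function(x) x@maxEigenvalues)

#' Accessors for ClusteringResult objects
#'
#' @param x a \linkS4class{ClusteringResult}.
#' @return \code{clusterLabels}: integer per-gene cluster ids in 1..k;
#'   \code{medoids}: integer gene indices of the k medoids;
#'   \code{clusterObjective}: the mean gene-to-medoid dissimilarity.
#' @name ClusteringResult-accessors
#' @aliases clusterLabels medoids clusterObjective
NULL

#' @rdname ClusteringResult-accessors
#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@labels)

#' @rdname ClusteringResult-accessors
#' @export
setMethod("medoids", "ClusteringResult", function(x) x@medoids)

#' @rdname ClusteringResult-accessors
#' @export
setMethod("clusterObjective", "ClusteringResult", function(x) x@objective)

#' Nearest-neighbor distance values
#'
#' @param x an \linkS4class{NNDDistribution}.
#' @return numeric vector of pooled per-gene nearest-neighbor distances.
#' @name nndValues
#' @export
setMethod("nndValues", "NNDDistribution", function(x) x@values)

setMethod("show", "ChromExpression", function(object) {
    cat("ChromExpression:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  phenotype:", phenotype(object), "\n")
    chs <- unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))
    cat("  chromosomes:", paste(chs, collapse = ", "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix:", nrow(object@values), "genes",
        sprintf("(phenotype %s, %s samples)\n", object@phenotype,
                object@nSamples))
})

setMethod("show", "EigenSpectrum", function(object) {
    cat("EigenSpectrum:", object@nGenes, "eigenvalues, largest",
        format(object@values[1], digits = 4), "\n")
})

setMethod("show", "NullEnsemble", function(object) {
    cat("NullEnsemble:", object@nMatrices, "shuffled matrices; max eigenvalue",
        "range", paste(format(range(object@maxEigenvalues), digits = 4),
                       collapse = " .. "), "\n")
})

setMethod("show", "ClusteringResult", function(object) {
    cat("ClusteringResult: k =", object@k, "clusters over",
        length(object@labels), "genes; objective",
        format(object@objective, digits = 6),
        sprintf("(%d restarts)\n", object@nRestarts))
})

setMethod("show", "NNDDistribution", function(object) {
    cat("NNDDistribution:", length(object@values), "values (",
        object@metric, "units ),", length(object@clusterSizes), "clusters,",
        object@nSingletons, "singletons excluded\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf("SyntheticSpec: %s mode, %d genes x %d samples, seed %d\n",
                object@mode, object@nGenes, object@nSamples, object@seed))
})
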