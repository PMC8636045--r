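#' @import methods
#' @importFrom stats cor median quantile rnorm setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

#' ChromExpression: per-chromosome gene expression bound to coordinates
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one assay
#' (\code{"expr"}) of log2-normalized expression values (genes x samples).
#' Row ranges carry the genomic position of each gene; row metadata columns
#' \code{gene_id} and \code{rank} give the gene identifier and its 0-based
#' ordinal position after sorting by start coordinate within its chromosome.
#' The phenotype label (e.g. \code{"control"}, \code{"basal"}) lives in
#' \code{metadata(x)$phenotype}.
#'
#' Objects are created by [ChromExpression()], [readExpressionTable()] or
#' [simulateExpression()].
#'
#' @seealso [pearsonMatrix()], [filterLowExpression()],
#'   [splitByChromosome()]
#' @export
setClass("ChromExpression", contains = "RangedSummarizedExperiment")

.validChromExpression <- function(object) {
    msg <- character()
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "expr")
        if (anyNA(v)) msg <- c(msg, "expression values contain NA")
        if (!is.numeric(v)) msg <- c(msg, "expression values must be numeric")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    if (!all(c("gene_id", "rank") %in% colnames(mc))) {
        msg <- c(msg, "rowRanges must carry 'gene_id' and 'rank' columns")
    } else {
        sp <- split(seq_along(rr), as.character(GenomicRanges::seqnames(rr)))
        for (idx in sp) {
            ids <- mc$gene_id[idx]
            if (anyDuplicated(ids))
                msg <- c(msg, "duplicate gene_id within a chromosome")
            rk <- mc$rank[idx]
            if (!identical(sort(as.integer(rk)), seq_along(idx) - 1L))
                msg <- c(msg, "ranks must be a contiguous 0..N-1 sequence per chromosome")
            o <- order(GenomicRanges::start(rr)[idx], ids)
            if (!identical(as.integer(rk[o]), seq_along(idx) - 1L))
                msg <- c(msg, "ranks inconsistent with ascending start coordinate")
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("ChromExpression", .validChromExpression)

#' CorrelationMatrix: symmetric unit-diagonal Pearson matrix over ordered genes
#'
#' Stores the gene-gene Pearson correlation matrix of one chromosome and
#' phenotype, together with the gene coordinates it was computed over and the
#' number of samples that entered the estimate.
#'
#' @slot values symmetric numeric matrix in [-1, 1] with unit diagonal.
#' @slot genes \linkS4class{GRanges} of the genes, in matrix order, with
#'   metadata columns \code{gene_id} and \code{rank}.
#' @slot phenotype single character label.
#' @slot nSamples integer; number of samples behind the estimate (NA if
#'   unknown, e.g. a matrix read from file).
#' @seealso [pearsonMatrix()], [eigenSpectrum()],
#'   [correlationToDissimilarity()]
#' @export
setClass("CorrelationMatrix",
    representation(values = "matrix", genes = "GRanges",
                   phenotype = "character", nSamples = "integer"))

setValidity("CorrelationMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (nrow(v) != length(object@genes))
        msg <- c(msg, "gene annotation length must match matrix dimension")
    if (nrow(v) > 0) {
        if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix not symmetric (tol 1e-12)")
        if (max(abs(diag(v) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
        if (min(v) < -1 - 1e-12 || max(v) > 1 + 1e-12)
            msg <- c(msg, "entries must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' EigenSpectrum: eigenvalues of a correlation matrix, sorted descending
#'
#' @slot values numeric eigenvalues, descending. Their sum equals the matrix
#'   trace (the number of genes).
#' @slot nGenes,nSamples integer dimensions of the underlying data
#'   (nSamples may be NA).
#' @seealso [eigenSpectrum()], [countDeviatingEigenvalues()]
#' @export
setClass("EigenSpectrum",
    representation(values = "numeric", nGenes = "integer", nSamples = "integer"))

setValidity("EigenSpectrum", function(object) {
    v <- object@values
    msg <- character()
    if (length(v) != object@nGenes)
        msg <- c(msg, "number of eigenvalues must equal nGenes")
    if (is.unsorted(rev(v))) msg <- c(msg, "eigenvalues must be sorted descending")
    if (length(v) && min(v) < -1e-10)
        msg <- c(msg, "correlation-matrix eigenvalues must be >= -1e-10")
    if (length(v) && abs(sum(v) - object@nGenes) > 1e-8 * object@nGenes)
        msg <- c(msg, "eigenvalue sum must equal the trace (nGenes)")
    if (length(msg)) msg else TRUE
})

#' NullEnsemble: spectra of correlation matrices of shuffled expression data
#'
#' The random-matrix null for one chromosome and phenotype: each member is the
#' Pearson correlation matrix of an independent within-sample shuffle of the
#' expression table, summarized by its eigenvalue spectrum. The per-member
#' largest eigenvalues calibrate the deviating-eigenvalue threshold.
#'
#' @slot spectra list of \linkS4class{EigenSpectrum}.
#' @slot maxEigenvalues numeric largest eigenvalue of each member.
#' @slot nMatrices integer ensemble size (default 100).
#' @slot seed integer seed the ensemble was generated from.
#' @seealso [buildNullEnsemble()], [countDeviatingEigenvalues()]
#' @export
setClass("NullEnsemble",
    representation(spectra = "list", maxEigenvalues = "numeric",
                   nMatrices = "integer", seed = "integer"))

setValidity("NullEnsemble", function(object) {
    msg <- character()
    if (length(object@spectra) != object@nMatrices)
        msg <- c(msg, "length(spectra) must equal nMatrices")
    if (length(object@maxEigenvalues) != object@nMatrices)
        msg <- c(msg, "length(maxEigenvalues) must equal nMatrices")
    if (length(msg)) msg else TRUE
})

#' DissimilarityMatrix: 1 - |C| distances between genes
#'
#' @slot values numeric matrix in [0, 1], zero diagonal, symmetric.
#' @slot genes \linkS4class{GRanges} in matrix order.
#' @seealso [correlationToDissimilarity()], [kmedoidsBest()]
#' @export
setClass("DissimilarityMatrix",
    representation(values = "matrix", genes = "GRanges"))

setValidity("DissimilarityMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (nrow(v) != length(object@genes))
        msg <- c(msg, "gene annotation length must match matrix dimension")
    if (nrow(v) > 0) {
        if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix not symmetric")
        if (max(abs(diag(v))) > 1e-12) msg <- c(msg, "diagonal must be 0")
        if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
            msg <- c(msg, "entries must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' ClusteringResult: a k-medoids partition of the genes of one chromosome
#'
#' @slot k integer number of clusters.
#' @slot medoids integer indices (1-based, ascending) of the medoid genes.
#' @slot labels integer per-gene cluster id in 1..k; a medoid's label is its
#'   own cluster.
#' @slot objective mean over genes of the dissimilarity to their medoid, the
#'   quantity minimized and used to pick the best restart.
#' @slot nRestarts,seed integers recording how the result was obtained.
#' @seealso [kmedoidsOnce()], [kmedoidsBest()], [writeClusterTable()]
#' @export
setClass("ClusteringResult",
    representation(k = "integer", medoids = "integer", labels = "integer",
                   objective = "numeric", nRestarts = "integer",
                   seed = "integer"))

setValidity("ClusteringResult", function(object) {
    msg <- character()
    k <- object@k
    if (length(object@medoids) != k) msg <- c(msg, "need exactly k medoids")
    if (anyDuplicated(object@medoids)) msg <- c(msg, "medoids must be distinct")
    if (k > 0) {
        if (!all(sort(unique(object@labels)) == seq_len(k)))
            msg <- c(msg, "labels must use every cluster id 1..k")
        if (!all(object@labels[object@medoids] == seq_len(k)))
            msg <- c(msg, "each medoid must belong to its own cluster")
    }
    if (length(msg)) msg else TRUE
})

#' NNDDistribution: pooled intra-cluster nearest-neighbor distances
#'
#' For every gene in a cluster of size >= 2, the minimum distance (rank units
#' or base pairs) to another gene of the same cluster, pooled over the
#' clusters of a chromosome. Summarized by Shannon entropy
#' ([shannonEntropy()]) and an empirical CDF ([nndCDF()]); phenotypes are
#' contrasted with [comparePhenotypes()].
#'
#' @slot values numeric per-gene nearest-neighbor distances (>= 1 in rank
#'   units).
#' @slot clusterSizes integer sizes of the clusters that contributed.
#' @slot nSingletons integer count of singleton clusters excluded (no
#'   neighbor exists).
#' @slot metric \code{"rank"} or \code{"bp"}.
#' @export
setClass("NNDDistribution",
    representation(values = "numeric", clusterSizes = "integer",
                   nSingletons = "integer", metric = "character"))

setValidity("NNDDistribution", function(object) {
    msg <- character()
    if (length(object@values) == 0) msg <- c(msg, "at least one NND value required")
    if (length(object@values) && min(object@values) <= 0)
        msg <- c(msg, "NND values must be positive")
    if (length(object@values) != sum(object@clusterSizes[object@clusterSizes >= 2L]))
        msg <- c(msg, "one NND value per gene in clusters of size >= 2")
    if (length(msg)) msg else TRUE
})

#' SyntheticSpec: configuration of the synthetic expression generator
#'
#' Describes one synthetic chromosome. Gene positions are drawn uniformly
#' without replacement on \code{[0, chromosomeLengthBp)} and sorted; the
#' expression values then follow one of four generative modes:
#' \describe{
#'   \item{null}{i.i.d. standard Gaussian values; no structure.}
#'   \item{blocks}{genes partitioned into \code{nBlocks} contiguous runs;
#'     each run shares a per-sample latent factor. Cancer-like: co-expressed
#'     genes are physically contiguous.}
#'   \item{decay}{a Gaussian process over positions with covariance
#'     \code{loading * exp(-d / decayScaleBp)} plus independent noise:
#'     correlation decays smoothly with genomic distance.}
#'   \item{control}{genes assigned to \code{nBlocks} latent factors uniformly
#'     at random, ignoring position, with a \code{negFraction} of genes
#'     entering with negated loading; distance-independent positive and
#'     negative correlations.}
#' }
#' With unit \code{noiseSd}, the population correlation of two genes sharing
#' a factor is \code{loading}; [expectedCorrelation()] returns the exact
#' value for any pair. All randomness derives from \code{seed}; positions,
#' structural assignments and values use separate sub-streams so changing
#' \code{nSamples} never moves the gene positions.
#'
#' @slot nGenes,nSamples,chromosomeLengthBp,nBlocks positive integers.
#' @slot mode one of \code{"blocks"}, \code{"decay"}, \code{"control"},
#'   \code{"null"}.
#' @slot loading numeric in [0, 1]: shared-factor variance fraction, i.e. the
#'   within-cluster population correlation at unit noise.
#' @slot decayScaleBp positive numeric, the correlation decay length in bp.
#' @slot negFraction numeric in [0, 1] (control mode).
#' @slot noiseSd positive numeric standard deviation of the idiosyncratic
#'   noise (default 1).
#' @slot seed integer master seed.
#' @seealso [simulateExpression()], [expectedCorrelation()]
#' @export
setClass("SyntheticSpec",
    representation(nGenes = "integer", nSamples = "integer",
                   chromosomeLengthBp = "integer", mode = "character",
                   nBlocks = "integer", loading = "numeric",
                   decayScaleBp = "numeric", negFraction = "numeric",
                   noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
    if (object@chromosomeLengthBp < object@nGenes)
        msg <- c(msg, "chromosomeLengthBp must be >= nGenes (positions are distinct)")
    if (!object@mode %in% c("blocks", "decay", "control", "null"))
        msg <- c(msg, "mode must be blocks, decay, control or null")
    if (object@mode %in% c("blocks", "control") && object@nBlocks > object@nGenes)
        msg <- c(msg, "nBlocks must not exceed nGenes")
    if (object@loading < 0 || object@loading > 1)
        msg <- c(msg, "loading must lie in [0, 1]")
    if (object@negFraction < 0 || object@negFraction > 1)
        msg <- c(msg, "negFraction must lie in [0, 1]")
    if (object@decayScaleBp <= 0) msg <- c(msg, "decayScaleBp must be positive")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (length(msg)) msg else TRUE
})
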