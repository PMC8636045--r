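#' Shuffle expression values to destroy gene-gene correlation
#'
#' The randomization behind the random-matrix null ensemble. Two axes are
#' available. \code{within = "gene"} (default) permutes each gene's values
#' independently across samples: every gene keeps exactly the marginal
#' distribution that enters the correlation estimate, and all cross-gene
#' dependence — including any shared sample-level component — is destroyed,
#' so the null spectrum follows the Marchenko-Pastur law.
#' \code{within = "sample"} permutes the gene values independently within
#' each sample (column), preserving each sample's value multiset instead;
#' note that with this axis any variation of the per-sample mean survives
#' the shuffle as a common mode across genes and inflates the null's top
#' eigenvalue, so it is only appropriate for strictly sample-normalized
#' data.
#'
#' @param x a \linkS4class{ChromExpression}.
#' @param seed integer seed; the call is deterministic given it.
#' @param within \code{"gene"} (default: permute samples within each gene)
#'   or \code{"sample"} (permute genes within each sample).
#' @return a \linkS4class{ChromExpression} with the same genes, samples and
#'   phenotype but shuffled values.
#' @export
shuffleExpression <- function(x, seed, within = c("gene", "sample")) {
    within <- match.arg(within)
    m <- exprValues(x)
    shuffled <- .shuffleValues(m, seed, match.arg(within))
    dimnames(shuffled) <- dimnames(m)
    ann <- geneAnnotationTable(x)[, c("gene_id", "chromosome", "start_bp")]
    ChromExpression(shuffled, ann, phenotype = phenotype(x))
}

# matrix-level shuffle shared by shuffleExpression() and the ensemble
# builders (which skip the per-member container round-trip for speed)
.shuffleValues <- function(m, seed, within) {
    s <- withSeed(seed, {
        if (within == "sample")
            apply(m, 2, function(col) col[sample.int(length(col))])
        else
            t(apply(m, 1, function(row) row[sample.int(length(row))]))
    })
    if (is.null(dim(s))) s <- matrix(s, nrow = nrow(m))   # 1-gene edge case
    s
}

# correlation of a shuffled copy, exactly as pearsonMatrix computes it
.shuffledCor <- function(m, seed, within) {
    v <- .shuffleValues(m, seed, within)
    C <- cor(t(v))
    C <- (C + t(C)) / 2
    C[C > 1] <- 1
    C[C < -1] <- -1
    diag(C) <- 1
    C
}

#' Eigenvalue spectrum of a correlation matrix
#'
#' Full symmetric eigendecomposition, eigenvalues sorted descending. The
#' spectrum of the shuffled null follows the Marchenko-Pastur law (see
#' [mpDensity()]); empirical eigenvalues above the null's largest ones carry
#' the correlation structure used to choose the cluster number.
#'
#' @param x a \linkS4class{CorrelationMatrix} or a plain symmetric matrix.
#' @param nSamples sample count recorded in the spectrum when \code{x} is a
#'   plain matrix.
#' @return an \linkS4class{EigenSpectrum}.
#' @name eigenSpectrum
#' @export
setMethod("eigenSpectrum", "CorrelationMatrix", function(x, ...) {
    .eigenSpectrum(x@values, x@nSamples)
})

#' @rdname eigenSpectrum
#' @export
setMethod("eigenSpectrum", "matrix", function(x, nSamples = NA_integer_, ...) {
    .eigenSpectrum(x, as.integer(nSamples))
})

.eigenSpectrum <- function(v, nSamples) {
    if (max(abs(v - t(v))) > 1e-8) stop("matrix is not symmetric")
    ev <- eigen((v + t(v)) / 2, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)            # clip eigen()'s -1e-15-scale noise
    ev <- ev * (nrow(v) / sum(ev))   # restore exact trace after clipping
    methods::new("EigenSpectrum", values = ev, nGenes = nrow(v),
                 nSamples = nSamples)
}

#' Build the shuffled-data random-matrix null ensemble
#'
#' Generates \code{nMatrices} independent shuffles of the expression
#' matrix, computes the Pearson correlation matrix of each, and
#' stores the eigenvalue spectra. Member \code{m} uses sub-seed
#' \code{seed + m}, so the ensemble is reproducible and individual members
#' can be regenerated. The default ensemble size is 100 matrices per
#' chromosome and phenotype.
#'
#' @param x a \linkS4class{ChromExpression}.
#' @param nMatrices ensemble size (default 100).
#' @param seed integer seed.
#' @param within shuffle axis, see [shuffleExpression()].
#' @return a \linkS4class{NullEnsemble}.
#' @seealso [countDeviatingEigenvalues()], [nullCorrelations()]
#' @export
buildNullEnsemble <- function(x, nMatrices = 100L, seed = 1L,
                              within = c("gene", "sample")) {
    stopifnot(nMatrices >= 1)
    within <- match.arg(within)
    vals <- exprValues(x)
    if (ncol(vals) < 3) stop("at least 3 samples are required")
    spectra <- lapply(seq_len(nMatrices), function(m)
        .eigenSpectrum(.shuffledCor(vals, seed + m, within), ncol(vals)))
    methods::new("NullEnsemble", spectra = spectra,
                 maxEigenvalues = vapply(spectra, function(s) s@values[1],
                                         numeric(1)),
                 nMatrices = as.integer(nMatrices), seed = as.integer(seed))
}

#' Correlation matrices of shuffled data
#'
#' Regenerates \code{n} members of the shuffled null as full correlation
#' matrices (rather than spectra), using the same sub-seed scheme as
#' [buildNullEnsemble()]; used by the piece-wise KS comparison of
#' correlation values against the null.
#'
#' @param x a \linkS4class{ChromExpression}.
#' @param n number of matrices.
#' @param seed integer seed.
#' @param within shuffle axis, see [shuffleExpression()].
#' @return list of \linkS4class{CorrelationMatrix}.
#' @export
nullCorrelations <- function(x, n = 10L, seed = 1L,
                             within = c("gene", "sample")) {
    within <- match.arg(within)
    vals <- exprValues(x)
    genes <- SummarizedExperiment::rowRanges(x)
    lapply(seq_len(n), function(m)
        methods::new("CorrelationMatrix",
                     values = .shuffledCor(vals, seed + m, within),
                     genes = genes, phenotype = phenotype(x),
                     nSamples = ncol(vals)))
}

#' Count eigenvalues deviating from the shuffled null
#'
#' The threshold is the empirical \code{(1 - alpha)} quantile (lower order
#' statistic, quantile type 1) of the ensemble's per-member largest
#' eigenvalues; the returned \code{k} is the number of empirical eigenvalues
#' strictly above it. \code{k} is the number of clusters passed to
#' k-medoids; \code{alpha = 0} degenerates to the strict
#' max-of-ensemble rule. The smallest eigenvalues, which are the most
#' noise-sensitive, play no role.
#'
#' @param empirical an \linkS4class{EigenSpectrum} of the observed matrix.
#' @param ensemble a \linkS4class{NullEnsemble}.
#' @param alpha tail probability in (0, 0.5); default 0.01. The ensemble
#'   should have at least \code{1/alpha} members for the quantile to be
#'   meaningful (warned otherwise).
#' @return integer \code{k >= 0}, with the threshold in attribute
#'   \code{"threshold"}.
#' @export
countDeviatingEigenvalues <- function(empirical, ensemble, alpha = 0.01) {
    if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
    if (ensemble@nMatrices < 1 / alpha)
        warning("ensemble smaller than 1/alpha; threshold quantile is coarse")
    thr <- unname(quantile(ensemble@maxEigenvalues, 1 - alpha, type = 1))
    k <- sum(empirical@values > thr)
    structure(as.integer(k), threshold = thr)
}

#' Marchenko-Pastur density and CDF
#'
#' The limiting eigenvalue distribution of sample correlation matrices of
#' i.i.d. data with aspect ratio \code{q = nGenes / nSamples} (q < 1):
#' density \eqn{\sqrt{(\lambda_+ - x)(x - \lambda_-)} / (2\pi q x)} on the
#' support \eqn{[\lambda_-, \lambda_+]}, \eqn{\lambda_\pm = (1 \pm
#' \sqrt{q})^2}. The shuffled null ensemble's pooled spectrum follows this
#' law; the functions serve as its analytic reference.
#'
#' @param x numeric vector of evaluation points.
#' @param q aspect ratio genes/samples, in (0, 1).
#' @return \code{mpDensity}: density values; \code{mpCDF}: distribution
#'   function values (numerical integration of the density).
#' @export
mpDensity <- function(x, q) {
    stopifnot(q > 0, q < 1)
    lo <- (1 - sqrt(q))^2
    hi <- (1 + sqrt(q))^2
    d <- numeric(length(x))
    i <- x > lo & x < hi
    d[i] <- sqrt((hi - x[i]) * (x[i] - lo)) / (2 * pi * q * x[i])
    d
}

#' @rdname mpDensity
#' @export
mpCDF <- function(x, q) {
    stopifnot(q > 0, q < 1)
    lo <- (1 - sqrt(q))^2
    hi <- (1 + sqrt(q))^2
    vapply(x, function(xi) {
        if (xi <= lo) return(0)
        if (xi >= hi) return(1)
        stats::integrate(mpDensity, lo, xi, q = q, rel.tol = 1e-9,
                         subdivisions = 500L)$value
    }, numeric(1))
}

#' Kolmogorov distance between a sample and a reference CDF
#'
#' One-sample sup-distance \eqn{\sup_x |F_n(x) - F(x)|}, evaluated exactly
#' at the sample points (both one-sided limits of the empirical step
#' function).
#'
#' @param x numeric sample.
#' @param cdf vectorized reference CDF, e.g. \code{function(v) mpCDF(v, q)}.
#' @return the KS statistic in [0, 1].
#' @export
ksDistanceToCDF <- function(x, cdf) {
    n <- length(x)
    stopifnot(n > 0)
    xs <- sort(x)
    Fx <- cdf(xs)
    max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}
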