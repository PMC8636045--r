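#' Pearson correlation matrix of a chromosome
#'
#' Computes the gene-gene Pearson correlation matrix
#' \deqn{C_{ij} = \frac{\mathrm{Cov}(g_i, g_j)}{\sigma_{g_i}\sigma_{g_j}}}
#' over the samples of an expression matrix. The population (1/N_s)
#' normalization of covariance and standard deviations is used; the
#' normalization cancels in the ratio, so the matrix is identical to the
#' usual sample correlation. The result is exactly symmetrized and its
#' diagonal set to 1 to remove floating-point asymmetry.
#'
#' @param x a \linkS4class{ChromExpression} with at least 3 samples and no
#'   zero-variance genes.
#' @return a \linkS4class{CorrelationMatrix}.
#' @examples
#' sim <- simulateExpression(syntheticSpec(nGenes = 20, nSamples = 50,
#'                                         mode = "blocks", seed = 1))
#' cm <- pearsonMatrix(sim$expr)
#' range(corValues(cm))
#' @export
pearsonMatrix <- function(x) {
    m <- exprValues(x)
    if (ncol(m) < 3) stop("at least 3 samples are required")
    v <- apply(m, 1, stats::var)
    if (any(v == 0))
        stop("zero variance for gene(s): ",
             paste(utils::head(geneIds(x)[v == 0], 5), collapse = ", "))
    C <- cor(t(m))
    C <- (C + t(C)) / 2
    C[C > 1] <- 1
    C[C < -1] <- -1
    diag(C) <- 1
    methods::new("CorrelationMatrix", values = C,
                 genes = SummarizedExperiment::rowRanges(x),
                 phenotype = phenotype(x), nSamples = ncol(m))
}

#' Pairwise gene distances along a chromosome
#'
#' @param genes a \linkS4class{GRanges} with rank metadata, or a
#'   \linkS4class{ChromExpression} / \linkS4class{CorrelationMatrix}.
#' @param metric \code{"bp"} (absolute difference of start coordinates, the
#'   physical distance) or \code{"rank"} (absolute difference of ordinal
#'   positions, the index distance used by the nearest-neighbor statistics).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairDistances <- function(genes, metric = c("bp", "rank")) {
    metric <- match.arg(metric)
    if (methods::is(genes, "ChromExpression"))
        genes <- SummarizedExperiment::rowRanges(genes)
    if (methods::is(genes, "CorrelationMatrix")) genes <- genes@genes
    p <- if (metric == "bp") as.numeric(GenomicRanges::start(genes) - 1L)
         else as.numeric(S4Vectors::mcols(genes)$rank)
    abs(outer(p, p, "-"))
}

# Equal-occupancy window assignment for the upper-triangle pairs of a
# distance matrix: pairs are ordered by distance (ties kept stable) and cut
# into nWindows index blocks of near-equal size. Returns, per pair, the
# window id plus the [d_low, d_high] span of each window.
.distanceWindows <- function(d, nWindows) {
    ord <- order(d)
    n <- length(d)
    if (n < nWindows) stop("fewer gene pairs than windows")
    win <- integer(n)
    win[ord] <- ceiling(seq_len(n) / (n / nWindows))
    win[win > nWindows] <- nWindows
    lows <- tapply(d, win, min)
    highs <- tapply(d, win, max)
    list(window = win, d_low = as.numeric(lows), d_high = as.numeric(highs))
}

#' Correlation-versus-distance profile
#'
#' Bins the upper-triangle gene pairs of a correlation matrix into
#' equal-occupancy distance windows and summarizes, separately for positive
#' (C > 0) and negative (C < 0) correlations, the median and quartiles per
#' window. Zero correlations belong to neither stratum. This is the
#' whole-landscape view in which the cancer-like loss of long-range
#' co-expression appears as a decaying positive-median profile while
#' control-like structure stays flat.
#'
#' @param c a \linkS4class{CorrelationMatrix}.
#' @param distances symmetric pair-distance matrix from [pairDistances()].
#' @param nWindows number of equal-occupancy windows (default 50).
#' @return data.frame with two rows per window (sign \code{"positive"} /
#'   \code{"negative"}): columns window, d_low, d_high, sign, median, q1,
#'   q3, count (summary columns NA when the stratum is empty).
#' @export
distanceProfile <- function(c, distances, nWindows = 50L) {
    stopifnot(nWindows >= 2)
    v <- c@values
    ut <- upper.tri(v)
    cv <- v[ut]
    dv <- distances[ut]
    w <- .distanceWindows(dv, nWindows)
    res <- lapply(seq_len(nWindows), function(k) {
        inWin <- w$window == k
        strat <- function(sel, lab) {
            x <- cv[inWin & sel]
            if (length(x) == 0)
                data.frame(window = k, d_low = w$d_low[k], d_high = w$d_high[k],
                           sign = lab, median = NA_real_, q1 = NA_real_,
                           q3 = NA_real_, count = 0L)
            else
                data.frame(window = k, d_low = w$d_low[k], d_high = w$d_high[k],
                           sign = lab, median = median(x),
                           q1 = unname(quantile(x, 0.25)),
                           q3 = unname(quantile(x, 0.75)),
                           count = length(x))
        }
        rbind(strat(cv > 0, "positive"), strat(cv < 0, "negative"))
    })
    do.call(rbind, res)
}
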