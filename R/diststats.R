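#' Intra-cluster nearest-neighbor distance distribution
#'
#' For each gene in a cluster of size >= 2, the minimum distance
#' \deqn{D^{nn}_i = \min_{j \in C_k, j \neq i} |j - i|} to any other gene of
#' the same cluster, pooled over all clusters of the chromosome. Distances
#' are ordinal rank differences by default (genes indexed after sorting by
#' start coordinate) or base pairs. Singleton clusters have no neighbor and
#' are excluded; their count is recorded.
#'
#' @param labels per-gene integer cluster ids (any coding), aligned with
#'   \code{genes}; typically \code{clusterLabels()} of a
#'   \linkS4class{ClusteringResult}.
#' @param genes \linkS4class{GRanges} with rank metadata, or a
#'   \linkS4class{ChromExpression}.
#' @param metric \code{"rank"} (default) or \code{"bp"}.
#' @return an \linkS4class{NNDDistribution}.
#' @seealso [shannonEntropy()], [nndCDF()], [comparePhenotypes()]
#' @export
nndDistribution <- function(labels, genes, metric = c("rank", "bp")) {
    metric <- match.arg(metric)
    if (methods::is(genes, "ChromExpression"))
        genes <- SummarizedExperiment::rowRanges(genes)
    if (length(labels) != length(genes))
        stop("labels must align with genes")
    pos <- if (metric == "rank") as.numeric(S4Vectors::mcols(genes)$rank)
           else as.numeric(GenomicRanges::start(genes) - 1L)
    byCl <- split(pos, labels)
    sizes <- lengths(byCl)
    if (all(sizes < 2)) stop("NND undefined: all clusters are singletons")
    vals <- unlist(lapply(byCl[sizes >= 2], function(p) {
        # per gene, min distance to any other member of its cluster
        vapply(seq_along(p), function(i) min(abs(p[-i] - p[i])), numeric(1))
    }), use.names = FALSE)
    methods::new("NNDDistribution", values = vals,
                 clusterSizes = as.integer(sizes),
                 nSingletons = sum(sizes == 1L), metric = metric)
}

#' Shannon entropy of an NND distribution
#'
#' \deqn{H = -\sum_x p(x) \log p(x)} over the empirical frequencies of the
#' distinct nearest-neighbor distance values (no binning). Low entropy means
#' the NND mass is concentrated — spatially tight, localized clusters; high
#' entropy means the within-cluster distances are spread out along the
#' chromosome. A degenerate (single-valued) distribution has entropy 0.
#'
#' @param nnd an \linkS4class{NNDDistribution} or a bare numeric vector.
#' @param base \code{"e"} (natural log, default) or \code{"2"} (bits).
#' @return non-negative numeric entropy.
#' @export
shannonEntropy <- function(nnd, base = c("e", "2")) {
    base <- match.arg(base)
    x <- if (methods::is(nnd, "NNDDistribution")) nnd@values else nnd
    if (length(x) == 0) stop("entropy of an empty distribution")
    p <- as.numeric(table(x)) / length(x)
    lg <- if (base == "e") log(p) else log2(p)
    -sum(p * lg)
}

#' Empirical CDF of an NND distribution
#'
#' @param nnd an \linkS4class{NNDDistribution}.
#' @return data.frame with columns \code{value} (sorted distinct NNDs) and
#'   \code{prob} (cumulative probability, ending at 1).
#' @export
nndCDF <- function(nnd) {
    tab <- table(nnd@values)
    data.frame(value = as.numeric(names(tab)),
               prob = cumsum(as.numeric(tab)) / length(nnd@values))
}

#' Exact two-sample Kolmogorov-Smirnov distance
#'
#' The sup-distance between two empirical CDFs,
#' \deqn{D_{KS}(F_n, F_m) = \sup_x |F_n(x) - F_m(x)|,} evaluated exactly at
#' the pooled jump points (ties handled correctly). Symmetric in its
#' arguments and bounded in [0, 1].
#'
#' @param a,b non-empty numeric samples.
#' @return list with elements \code{statistic}, \code{n.a}, \code{n.b}
#'   (\code{p.value = NULL}; see [ksPermutationTest()] for significance).
#' @export
ksDistance <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na == 0 || nb == 0) stop("both samples must be non-empty")
    pts <- sort(unique(c(a, b)))
    Fa <- findInterval(pts, sort(a)) / na
    Fb <- findInterval(pts, sort(b)) / nb
    list(statistic = max(abs(Fa - Fb)), p.value = NULL, n.a = na, n.b = nb)
}

# Tie-aware KS for the permutation loop: `o` is the order of the pooled
# sample, `isLast` marks the last index of each tie group in that order,
# and `z` a 0/1 group-A indicator aligned with the *sorted* positions.
# max |F_a - F_b| occurs at tie-group boundaries of the pooled sorted values.
.ksFromSorted <- function(z, isLast, na, nb) {
    d <- cumsum(z) / na - cumsum(1 - z) / nb
    max(abs(d[isLast]))
}

#' Permutation test for the two-sample KS distance
#'
#' Recomputes the KS statistic on \code{nResamples} random splits of the
#' pooled sample at the original sizes; the p-value uses the add-one
#' correction \eqn{(b + 1)/(n_{res} + 1)} so it is never exactly zero.
#'
#' @param a,b numeric samples.
#' @param nResamples number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{statistic}, \code{p.value}, \code{n.a},
#'   \code{n.b}, \code{n.resamples}.
#' @export
ksPermutationTest <- function(a, b, nResamples = 1000L, seed = 1L) {
    na <- length(a); nb <- length(b)
    if (na == 0 || nb == 0) stop("both samples must be non-empty")
    pooled <- c(a, b)
    o <- order(pooled)
    ps <- pooled[o]
    isLast <- c(ps[-1] != ps[-length(ps)], TRUE)
    z0 <- as.numeric(o <= na)
    obs <- .ksFromSorted(z0, isLast, na, nb)
    exceed <- withSeed(seed, {
        sum(vapply(seq_len(nResamples), function(r) {
            z <- z0[sample.int(na + nb)]
            .ksFromSorted(z, isLast, na, nb)
        }, numeric(1)) >= obs - 1e-12)
    })
    list(statistic = obs, p.value = (exceed + 1) / (nResamples + 1),
         n.a = na, n.b = nb, n.resamples = as.integer(nResamples))
}

#' Piece-wise KS comparison of correlation values against the shuffled null
#'
#' Bins the upper-triangle gene pairs into equal-occupancy distance windows
#' and, per window, computes the KS distance between the empirical
#' correlation values and the pooled correlation values of the shuffled null
#' matrices for the same pairs, with a permutation p-value. A decaying
#' statistic-versus-distance trend is the signature of cancer-like loss of
#' long-range co-expression; in control-like data the deviation from the
#' null persists at all distances.
#'
#' @param c a \linkS4class{CorrelationMatrix}.
#' @param null list of \linkS4class{CorrelationMatrix} of shuffled data
#'   (see [nullCorrelations()]).
#' @param distances pair-distance matrix from [pairDistances()].
#' @param nWindows number of equal-occupancy windows (default 50).
#' @param nResamples permutations per window (default 1000); 0 skips
#'   p-values.
#' @param seed integer seed.
#' @return list with \code{windows} — data.frame(window, d_low, d_high,
#'   statistic, n_empirical, n_null, p_value, p_adjust) where
#'   \code{p_adjust} is Benjamini-Hochberg across windows — and
#'   \code{mean_p_value}, the across-window average p-value (reported for
#'   comparability; it is a summary, not a test).
#' @export
piecewiseKSvsNull <- function(c, null, distances, nWindows = 50L,
                              nResamples = 1000L, seed = 1L) {
    if (length(null) == 0) stop("null ensemble must be non-empty")
    ut <- upper.tri(c@values)
    cv <- c@values[ut]
    dv <- distances[ut]
    nullv <- lapply(null, function(nc) nc@values[ut])
    w <- .distanceWindows(dv, nWindows)
    rows <- lapply(seq_len(nWindows), function(k) {
        inWin <- w$window == k
        emp <- cv[inWin]
        nul <- unlist(lapply(nullv, function(v) v[inWin]), use.names = FALSE)
        if (length(emp) < 2 || length(nul) < 2) {
            message("window ", k, " has < 2 values on one side; p-value NA")
            return(data.frame(window = k, d_low = w$d_low[k],
                              d_high = w$d_high[k], statistic = NA_real_,
                              n_empirical = length(emp), n_null = length(nul),
                              p_value = NA_real_))
        }
        if (nResamples > 0) {
            kt <- ksPermutationTest(emp, nul, nResamples = nResamples,
                                    seed = deriveSeed(seed, "kswin", k))
            p <- kt$p.value
        } else {
            kt <- ksDistance(emp, nul)
            p <- NA_real_
        }
        data.frame(window = k, d_low = w$d_low[k], d_high = w$d_high[k],
                   statistic = kt$statistic, n_empirical = length(emp),
                   n_null = length(nul), p_value = p)
    })
    out <- do.call(rbind, rows)
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    list(windows = out, mean_p_value = mean(out$p_value, na.rm = TRUE))
}

#' Contrast the NND distributions of two phenotypes
#'
#' KS distance between the pooled nearest-neighbor distance samples of a
#' control and a case phenotype, plus the entropy difference
#' \code{H(control) - H(case)}. Tight, contiguous case clusters concentrate
#' the NND mass at small values, giving a positive entropy difference and a
#' large KS distance.
#'
#' @param nndControl,nndCase \linkS4class{NNDDistribution} objects.
#' @param base entropy log base, see [shannonEntropy()].
#' @return list with \code{ks} (as [ksDistance()]) and
#'   \code{delta_entropy}.
#' @export
comparePhenotypes <- function(nndControl, nndCase, base = c("e", "2")) {
    base <- match.arg(base)
    list(ks = ksDistance(nndControl@values, nndCase@values),
         delta_entropy = shannonEntropy(nndControl, base) -
                         shannonEntropy(nndCase, base))
}
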