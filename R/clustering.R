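#' Signed-correlation dissimilarity
#'
#' Transforms a correlation matrix into the clustering dissimilarity
#' \deqn{D_{ij} = 1 - |C_{ij}|,} so that strong correlation or
#' anticorrelation both mean small distance and uncorrelated pairs are
#' maximally distant. The diagonal is exactly 0.
#'
#' @param c a \linkS4class{CorrelationMatrix}.
#' @return a \linkS4class{DissimilarityMatrix}.
#' @export
correlationToDissimilarity <- function(c) {
    d <- 1 - abs(c@values)
    diag(d) <- 0
    methods::new("DissimilarityMatrix", values = d, genes = c@genes)
}

# Assignment step: nearest medoid per gene (ties -> lowest medoid index,
# guaranteed by which.min over medoids kept in ascending order), plus the
# second-nearest distances needed for O(N) swap deltas.
.assign <- function(D, med) {
    dm <- D[, med, drop = FALSE]
    nIdx <- apply(dm, 1, which.min)
    dn <- dm[cbind(seq_len(nrow(D)), nIdx)]
    ds <- if (length(med) == 1) rep(Inf, nrow(D)) else {
        dm2 <- dm
        dm2[cbind(seq_len(nrow(D)), nIdx)] <- Inf
        apply(dm2, 1, min)
    }
    list(nIdx = nIdx, dn = dn, ds = ds)
}

#' Single k-medoids (PAM) run from a random initialization
#'
#' Partitioning Around Medoids on a precomputed dissimilarity matrix:
#' \code{k} initial medoids are sampled uniformly without replacement, then
#' assignment (each gene to its nearest medoid, ties to the lowest medoid
#' index) alternates with a swap step that accepts the single best
#' objective-improving medoid/non-medoid exchange, until no swap improves.
#' The objective — the mean dissimilarity of genes to their assigned medoid
#' — is non-increasing across iterations, so the run terminates.
#'
#' @param d a \linkS4class{DissimilarityMatrix} (or plain symmetric matrix).
#' @param k number of clusters, 1 <= k <= N.
#' @param seed integer seed for the initialization.
#' @return a \linkS4class{ClusteringResult}.
#' @seealso [kmedoidsBest()] for the restarted version.
#' @export
kmedoidsOnce <- function(d, k, seed = 1L) {
    D <- if (methods::is(d, "DissimilarityMatrix")) d@values else d
    N <- nrow(D)
    k <- as.integer(k)
    if (k <= 0) stop("k must be positive")
    if (k > N) stop("k cannot exceed the number of genes")
    med <- withSeed(seed, sort(sample.int(N, k)))
    a <- .assign(D, med)
    obj <- mean(a$dn)
    repeat {
        # best single swap: removing medoid slot p and adding non-medoid h
        # gives per-gene distance min(base_p, D[, h]) where base_p is the
        # nearest-medoid distance with p's members falling back to their
        # second-nearest; vectorized over all h per slot
        best <- list(obj = obj, p = NA_integer_, h = NA_integer_)
        nonMed <- setdiff(seq_len(N), med)
        if (length(nonMed) == 0) break
        for (p in seq_len(k)) {
            base <- a$dn
            isP <- a$nIdx == p
            base[isP] <- a$ds[isP]
            objs <- colMeans(pmin(D[, nonMed, drop = FALSE], base))
            j <- which.min(objs)   # ties -> lowest candidate index
            if (objs[j] < best$obj - 1e-15)
                best <- list(obj = objs[j], p = p, h = nonMed[j])
        }
        if (is.na(best$p)) break
        med[best$p] <- best$h
        med <- sort(med)
        a <- .assign(D, med)
        obj <- mean(a$dn)
    }
    labels <- as.integer(a$nIdx)
    labels[med] <- seq_len(k)   # a medoid is always its own cluster, even
                                # when another medoid sits at distance 0
    methods::new("ClusteringResult", k = k, medoids = med,
                 labels = labels, objective = obj,
                 nRestarts = 1L, seed = as.integer(seed))
}

#' Best-of-restarts k-medoids clustering
#'
#' Runs [kmedoidsOnce()] \code{nRestarts} times (restart \code{r} uses seed
#' \code{seed + r}) and returns the run with the minimal mean gene-to-medoid
#' dissimilarity; ties go to the lowest restart index. The default of 100
#' restarts compensates for the random initialization. \code{k = 0} — a
#' chromosome whose spectrum never leaves the null — is a legitimate
#' outcome and returns \code{NULL} with a message rather than an error.
#'
#' @param d a \linkS4class{DissimilarityMatrix} (or plain symmetric matrix).
#' @param k number of clusters (typically [countDeviatingEigenvalues()]).
#' @param nRestarts number of random restarts (default 100).
#' @param seed integer master seed.
#' @return a \linkS4class{ClusteringResult}, or \code{NULL} when
#'   \code{k = 0}.
#' @export
kmedoidsBest <- function(d, k, nRestarts = 100L, seed = 1L) {
    stopifnot(nRestarts >= 1)
    if (k == 0) {
        message("k = 0 deviating eigenvalues: no clustering performed")
        return(NULL)
    }
    best <- NULL
    for (r in seq_len(nRestarts)) {
        res <- kmedoidsOnce(d, k, seed = seed + r)
        if (is.null(best) || res@objective < best@objective - 1e-15)
            best <- res
    }
    best@nRestarts <- as.integer(nRestarts)
    best@seed <- as.integer(seed)
    best
}
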