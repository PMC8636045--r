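#' Create a synthetic generator specification
#'
#' See \linkS4class{SyntheticSpec} for the generative modes. Defaults give a
#' chromosome-sized arm (100 Mb) with 5 planted factors at loading 0.7 and
#' unit noise — the regime in which the spectral null recovers the factor
#' count and k-medoids recovers the planted partition.
#'
#' @param nGenes,nSamples matrix dimensions.
#' @param chromosomeLengthBp chromosome length in base pairs.
#' @param mode "blocks", "decay", "control" or "null".
#' @param nBlocks number of latent factors (blocks / control modes).
#' @param loading shared-factor variance fraction in [0, 1].
#' @param decayScaleBp correlation decay length in bp (decay mode).
#' @param negFraction fraction of genes with negated loading (control mode).
#' @param noiseSd idiosyncratic noise standard deviation.
#' @param seed integer master seed.
#' @return a validated \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- syntheticSpec(nGenes = 60, nSamples = 100, mode = "blocks",
#'                       nBlocks = 3, seed = 1)
#' sim <- simulateExpression(spec)
#' table(sim$truth)
#' @export
syntheticSpec <- function(nGenes = 150L, nSamples = 300L,
                          chromosomeLengthBp = 1e8,
                          mode = c("blocks", "decay", "control", "null"),
                          nBlocks = 5L, loading = 0.7,
                          decayScaleBp = chromosomeLengthBp / 10,
                          negFraction = 0.3, noiseSd = 1, seed = 1L) {
    mode <- match.arg(mode)
    methods::new("SyntheticSpec", nGenes = as.integer(nGenes),
                 nSamples = as.integer(nSamples),
                 chromosomeLengthBp = as.integer(chromosomeLengthBp),
                 mode = mode, nBlocks = as.integer(nBlocks),
                 loading = loading, decayScaleBp = as.numeric(decayScaleBp),
                 negFraction = negFraction, noiseSd = noiseSd,
                 seed = as.integer(seed))
}

# Structural draws shared by simulateExpression() and expectedCorrelation():
# positions (sub-stream seed), factor assignment and signs (seed + 1).
# Regenerated deterministically from the spec so the two functions always
# agree without storing state.
.synthStructure <- function(spec) {
    n <- spec@nGenes
    pos <- withSeed(spec@seed,
        sort(sample.int(spec@chromosomeLengthBp, n, replace = FALSE)) - 1L)
    block <- NULL
    sign <- rep(1, n)
    if (spec@mode == "blocks") {
        # contiguous, nearly equal runs along the chromosome
        block <- if (spec@nBlocks == 1L) rep(1L, n)
                 else as.integer(cut(seq_len(n), breaks = spec@nBlocks,
                                     labels = FALSE))
    } else if (spec@mode == "control") {
        st <- withSeed(spec@seed + 1L, {
            b <- sample.int(spec@nBlocks, n, replace = TRUE)
            neg <- sample.int(n, size = round(spec@negFraction * n))
            list(b = b, neg = neg)
        })
        block <- st$b
        sign[st$neg] <- -1
    }
    list(positions = pos, block = block, sign = sign)
}

#' Simulate a synthetic expression matrix with known correlation structure
#'
#' Draws gene positions uniformly without replacement on the chromosome and
#' generates expression values under the spec's mode (see
#' \linkS4class{SyntheticSpec}). Identical seeds give identical output;
#' positions, structure and values use separate sub-streams of the master
#' seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param phenotype label for the returned object; defaults to the mode.
#' @return a list with elements \code{expr} (a
#'   \linkS4class{ChromExpression}) and \code{truth} (per-gene integer
#'   labels: block id in blocks mode, signed factor id in control mode,
#'   \code{NULL} for null and decay modes).
#' @seealso [expectedCorrelation()]
#' @export
simulateExpression <- function(spec, phenotype = spec@mode) {
    methods::validObject(spec)
    n <- spec@nGenes
    ns <- spec@nSamples
    st <- .synthStructure(spec)
    lam <- spec@loading

    vals <- withSeed(spec@seed + 2L, switch(spec@mode,
        null = matrix(rnorm(n * ns), nrow = n),
        blocks = ,
        control = {
            f <- matrix(rnorm(spec@nBlocks * ns), nrow = spec@nBlocks)
            eps <- matrix(rnorm(n * ns, sd = spec@noiseSd), nrow = n)
            st$sign * sqrt(lam) * f[st$block, , drop = FALSE] +
                sqrt(1 - lam) * eps
        },
        decay = {
            d <- abs(outer(st$positions, st$positions, "-"))
            K <- lam * exp(-d / spec@decayScaleBp) +
                diag((1 - lam) * spec@noiseSd^2, n)
            L <- tryCatch(chol(K + diag(1e-10, n)), error = function(e)
                stop("decay covariance not positive definite after jitter"))
            t(L) %*% matrix(rnorm(n * ns), nrow = n)
        }))

    truth <- switch(spec@mode,
        blocks = st$block,
        control = as.integer(st$sign * st$block),
        NULL)
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                        chromosome = "chrS", start_bp = st$positions)
    list(expr = ChromExpression(vals, genes, phenotype = phenotype),
         truth = truth)
}

#' Population correlation implied by a synthetic spec
#'
#' Returns the exact correlation of genes \code{i} and \code{j} (indices in
#' position order) under the generative model: for factor modes,
#' \code{s_i s_j loading / (loading + (1 - loading) noiseSd^2)} when the two
#' genes share a factor and 0 otherwise; for decay mode,
#' \code{loading exp(-d_bp / decayScaleBp)} scaled by the same noise factor.
#'
#' @param spec a \linkS4class{SyntheticSpec} with mode blocks, decay or
#'   control.
#' @param i,j gene indices (1-based, position order).
#' @return the population correlation, a single numeric.
#' @export
expectedCorrelation <- function(spec, i, j) {
    if (spec@mode == "null")
        stop("null mode has no correlation structure")
    st <- .synthStructure(spec)
    if (i == j) return(1)
    lam <- spec@loading
    atten <- lam + (1 - lam) * spec@noiseSd^2   # per-gene variance
    if (spec@mode == "decay") {
        d <- abs(st$positions[i] - st$positions[j])
        return(lam * exp(-d / spec@decayScaleBp) / atten)
    }
    if (st$block[i] != st$block[j]) return(0)
    st$sign[i] * st$sign[j] * lam / atten
}
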