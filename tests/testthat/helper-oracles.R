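# Independent oracles used to check the package's computational paths.
# Each is a deliberately naive implementation kept free of package code.

# Pearson correlation by direct evaluation of the covariance/sd ratio with
# population (1/N) normalization, one pair at a time.
naivePearson <- function(m) {
    n <- nrow(m)
    C <- diag(1, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        x <- m[i, ]; y <- m[j, ]
        cv <- mean((x - mean(x)) * (y - mean(y)))
        C[i, j] <- cv / (sqrt(mean((x - mean(x))^2)) *
                         sqrt(mean((y - mean(y))^2)))
    }
    C
}

# Two-sample KS by brute-force evaluation of both empirical CDFs at every
# pooled point.
bruteKS <- function(a, b) {
    pts <- c(a, b)
    d <- vapply(pts, function(p)
        abs(mean(a <= p) - mean(b <= p)), numeric(1))
    max(d)
}

# Exhaustive k-medoids optimum: enumerate every size-k medoid set.
enumPAMObjective <- function(D, k) {
    n <- nrow(D)
    sets <- utils::combn(n, k)
    best <- Inf
    for (s in seq_len(ncol(sets))) {
        med <- sets[, s]
        obj <- mean(apply(D[, med, drop = FALSE], 1, min))
        if (obj < best) best <- obj
    }
    best
}

# Random dissimilarity matrix in [0,1], zero diagonal, symmetric.
randomDissim <- function(n, seed) {
    set.seed(seed)
    v <- matrix(runif(n * n), n, n)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    v
}

# Small deterministic on-disk expression + BED fixture; returns the paths
# and the matrix/annotation it wrote.
writeExprFixture <- function(dir = NULL, nGenes = 6, nSamples = 5, seed = 42,
                             dropFromBed = character()) {
    if (is.null(dir)) {
        dir <- tempfile("fixture")
        dir.create(dir)
    }
    set.seed(seed)
    ids <- sprintf("gene%02d", seq_len(nGenes))
    m <- matrix(round(rnorm(nGenes * nSamples, mean = 8, sd = 2), 6),
                nrow = nGenes,
                dimnames = list(ids, sprintf("samp%d", seq_len(nSamples))))
    starts <- sort(sample.int(1e6, nGenes))
    exprPath <- file.path(dir, "expr.tsv")
    bedPath <- file.path(dir, "genes.bed")
    df <- data.frame(gene_id = ids, m, check.names = FALSE)
    write.table(df, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
    keep <- !ids %in% dropFromBed
    write.table(data.frame("chr1", starts[keep], starts[keep] + 1000,
                           ids[keep]),
                bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    list(expr = exprPath, bed = bedPath, values = m, ids = ids,
         starts = starts)
}

# Tiny in-memory ChromExpression with explicit positions.
makeChromExpression <- function(values, starts, chrom = "chr1",
                                phenotype = "test") {
    genes <- data.frame(gene_id = rownames(values), chromosome = chrom,
                        start_bp = starts)
    ChromExpression(values, genes, phenotype = phenotype)
}
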