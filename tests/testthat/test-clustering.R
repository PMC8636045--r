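test_that("the signed-correlation dissimilarity follows 1 - |C|", {
    C <- matrix(c(1, 0.5, -0.8, 0.5, 1, 0, -0.8, 0, 1), 3)
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 101, 201), width = 1),
        gene_id = c("a", "b", "c"), rank = 0:2)
    cm <- methods::new("CorrelationMatrix", values = C, genes = genes,
                       phenotype = "t", nSamples = NA_integer_)
    D <- corValues(correlationToDissimilarity(cm))
    expect_equal(D[1, 2], 0.5)
    expect_equal(D[1, 3], 0.2)   # anticorrelation is also close
    expect_equal(D[2, 3], 1)     # uncorrelated is maximally distant
    expect_true(all(diag(D) == 0))
})

test_that("k = N and k = 1 limits are exact", {
    D <- randomDissim(9, seed = 10)
    full <- kmedoidsOnce(D, k = 9, seed = 1)
    expect_equal(clusterObjective(full), 0)
    expect_identical(sort(medoids(full)), 1:9)
    one <- kmedoidsOnce(D, k = 1, seed = 1)
    # brute-force 1-median
    expect_identical(medoids(one), which.min(colSums(D)))
    expect_equal(clusterObjective(one), min(colMeans(D)))
    expect_error(kmedoidsOnce(D, k = 0), "positive")
    expect_error(kmedoidsOnce(D, k = 10), "exceed")
})

test_that("restarted search finds the exhaustive optimum on small instances", {
    hits <- 0L
    for (seed in 1:20) {
        D <- randomDissim(8, seed = 100 + seed)
        best <- kmedoidsBest(D, k = 3, nRestarts = 100, seed = seed)
        opt <- enumPAMObjective(D, 3)
        expect_gte(clusterObjective(best), opt - 1e-12)
        if (abs(clusterObjective(best) - opt) < 1e-12) hits <- hits + 1L
    }
    expect_gte(hits, 18L)
})

test_that("best-of-restarts is the minimum over its restarts", {
    D <- randomDissim(20, seed = 5)
    best <- kmedoidsBest(D, k = 4, nRestarts = 15, seed = 30)
    singles <- vapply(1:15, function(r)
        clusterObjective(kmedoidsOnce(D, 4, seed = 30 + r)), numeric(1))
    expect_equal(clusterObjective(best), min(singles))
    expect_true(all(clusterObjective(best) <= singles + 1e-15))
    # determinism
    best2 <- kmedoidsBest(D, k = 4, nRestarts = 15, seed = 30)
    expect_identical(medoids(best), medoids(best2))
    expect_identical(clusterLabels(best), clusterLabels(best2))
})

test_that("objective recomputes from labels and medoids", {
    D <- randomDissim(15, seed = 9)
    cl <- kmedoidsBest(D, k = 3, nRestarts = 10, seed = 2)
    recomputed <- mean(D[cbind(seq_len(15),
                               medoids(cl)[clusterLabels(cl)])])
    expect_equal(clusterObjective(cl), recomputed, tolerance = 1e-12)
    # every cluster non-empty and medoids labeled as themselves
    expect_identical(sort(unique(clusterLabels(cl))), 1:3)
    expect_identical(clusterLabels(cl)[medoids(cl)], 1:3)
})

test_that("clustering is blind to the sign of a gene's expression", {
    sim <- simulateExpression(syntheticSpec(nGenes = 30, nSamples = 50,
                                            mode = "blocks", nBlocks = 3,
                                            loading = 0.8, seed = 17))
    m <- exprValues(sim$expr)
    x1 <- makeChromExpression(m, starts = geneStartBp(sim$expr))
    m2 <- m
    m2[c(3, 11, 25), ] <- -m2[c(3, 11, 25), ]
    x2 <- makeChromExpression(m2, starts = geneStartBp(sim$expr))
    D1 <- correlationToDissimilarity(pearsonMatrix(x1))
    D2 <- correlationToDissimilarity(pearsonMatrix(x2))
    expect_lt(max(abs(corValues(D1) - corValues(D2))), 1e-10)
    c1 <- kmedoidsBest(D1, 3, nRestarts = 5, seed = 3)
    c2 <- kmedoidsBest(D2, 3, nRestarts = 5, seed = 3)
    expect_identical(clusterLabels(c1), clusterLabels(c2))
})

test_that("objective is non-increasing in k for the restarted search", {
    violations <- 0L
    for (seed in 1:10) {
        D <- randomDissim(25, seed = 400 + seed)
        objs <- vapply(2:5, function(k)
            clusterObjective(kmedoidsBest(D, k, nRestarts = 20,
                                          seed = seed)), numeric(1))
        violations <- violations + sum(diff(objs) > 1e-12)
    }
    expect_lte(violations, 1L)
})

test_that("k = 0 short-circuits to no clustering", {
    D <- randomDissim(6, seed = 2)
    expect_message(res <- kmedoidsBest(D, 0, nRestarts = 5, seed = 1),
                   "no clustering")
    expect_null(res)
})

test_that("objectives match cluster::pam on shared instances", {
    skip_if_not_installed("cluster")
    for (seed in 1:5) {
        D <- randomDissim(30, seed = 700 + seed)
        ours <- clusterObjective(kmedoidsBest(D, 4, nRestarts = 50,
                                              seed = seed))
        pam <- cluster::pam(stats::as.dist(D), k = 4, diss = TRUE)
        pamObj <- mean(apply(D[, pam$id.med, drop = FALSE], 1, min))
        expect_lte(ours, pamObj + 1e-10)
    }
})
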