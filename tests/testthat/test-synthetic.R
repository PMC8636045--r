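test_that("simulation is deterministic and positions ignore sample size", {
    spec <- syntheticSpec(nGenes = 30, nSamples = 40, mode = "blocks",
                          nBlocks = 3, seed = 11)
    a <- simulateExpression(spec)
    b <- simulateExpression(spec)
    expect_identical(exprValues(a$expr), exprValues(b$expr))
    expect_identical(a$truth, b$truth)
    # changing nSamples must not move the gene positions
    spec2 <- syntheticSpec(nGenes = 30, nSamples = 90, mode = "blocks",
                           nBlocks = 3, seed = 11)
    expect_identical(geneStartBp(a$expr),
                     geneStartBp(simulateExpression(spec2)$expr))
})

test_that("degenerate loadings give the expected correlations", {
    # loading 1: same-block genes are perfectly correlated
    s1 <- syntheticSpec(nGenes = 20, nSamples = 30, mode = "blocks",
                        nBlocks = 2, loading = 1, seed = 2)
    sim <- simulateExpression(s1)
    C <- cor(t(exprValues(sim$expr)))
    sameBlock <- outer(sim$truth, sim$truth, "==") & upper.tri(C)
    expect_true(all(abs(C[sameBlock] - 1) < 1e-10))
    # loading 0: mean absolute off-diagonal correlation is noise-sized
    s0 <- syntheticSpec(nGenes = 40, nSamples = 1000, mode = "blocks",
                        nBlocks = 4, loading = 0, seed = 3)
    C0 <- cor(t(exprValues(simulateExpression(s0)$expr)))
    expect_lt(mean(abs(C0[upper.tri(C0)])), 3 / sqrt(1000))
})

test_that("within-block sample correlation approaches the loading", {
    spec <- syntheticSpec(nGenes = 50, nSamples = 500, mode = "blocks",
                          nBlocks = 5, loading = 0.6, seed = 5)
    sim <- simulateExpression(spec)
    C <- cor(t(exprValues(sim$expr)))
    sameBlock <- outer(sim$truth, sim$truth, "==") & upper.tri(C)
    expect_lt(abs(mean(C[sameBlock]) - 0.6), 0.05)
})

test_that("empirical correlations converge to expectedCorrelation", {
    # entrywise error shrinks like 1/sqrt(nSamples) across two sample sizes
    err <- vapply(c(200L, 800L), function(ns) {
        spec <- syntheticSpec(nGenes = 30, nSamples = ns, mode = "blocks",
                              nBlocks = 3, loading = 0.7, seed = 9)
        sim <- simulateExpression(spec)
        C <- cor(t(exprValues(sim$expr)))
        expected <- outer(seq_len(30), seq_len(30),
                          Vectorize(function(i, j)
                              expectedCorrelation(spec, i, j)))
        mean(abs(C - expected)[upper.tri(C)])
    }, numeric(1))
    expect_lt(err[2], err[1])          # decreasing in nSamples
    expect_lt(err[1], 4 / sqrt(200))   # at the O(1/sqrt(n)) scale
})

test_that("expectedCorrelation follows the generative model", {
    spec <- syntheticSpec(nGenes = 12, nSamples = 10, mode = "blocks",
                          nBlocks = 3, loading = 0.7, seed = 1)
    truth <- simulateExpression(spec)$truth
    ij <- which(outer(truth, truth, "!=") & upper.tri(diag(12)),
                arr.ind = TRUE)[1, ]
    expect_identical(expectedCorrelation(spec, ij[1], ij[2]), 0)
    same <- which(outer(truth, truth, "==") & upper.tri(diag(12)),
                  arr.ind = TRUE)[1, ]
    expect_equal(expectedCorrelation(spec, same[1], same[2]), 0.7)

    # decay kernel at negligible lag equals the loading
    specD <- syntheticSpec(nGenes = 10, nSamples = 10, mode = "decay",
                           loading = 0.8, decayScaleBp = 1e12, seed = 1)
    expect_equal(expectedCorrelation(specD, 1, 10), 0.8, tolerance = 1e-4)

    # control mode: opposite signs sharing a factor give -loading
    specC <- syntheticSpec(nGenes = 40, nSamples = 10, mode = "control",
                           nBlocks = 2, loading = 0.7, negFraction = 0.5,
                           seed = 4)
    truthC <- simulateExpression(specC)$truth
    pair <- which(outer(truthC, -truthC, "==") & abs(outer(truthC, truthC)) > 0 &
                  upper.tri(diag(40)), arr.ind = TRUE)[1, ]
    expect_equal(expectedCorrelation(specC, pair[1], pair[2]), -0.7)

    expect_error(expectedCorrelation(
        syntheticSpec(mode = "null", seed = 1), 1, 2), "null mode")
})

test_that("decay mode decays and control mode does not", {
    specD <- syntheticSpec(nGenes = 80, nSamples = 300, mode = "decay",
                           loading = 0.9, decayScaleBp = 1e7, seed = 21)
    simD <- simulateExpression(specD)
    cm <- pearsonMatrix(simD$expr)
    prof <- distanceProfile(cm, pairDistances(cm, "bp"), nWindows = 8)
    med <- subset(prof, sign == "positive")$median
    # allow window-median sampling noise on an otherwise monotone profile
    expect_true(all(diff(med) < 0.02))
    expect_gt(med[1] - med[8], 0.3)

    specC <- syntheticSpec(nGenes = 80, nSamples = 300, mode = "control",
                           nBlocks = 5, loading = 0.7, negFraction = 0.3,
                           seed = 22)
    simC <- simulateExpression(specC)
    cmC <- pearsonMatrix(simC$expr)
    profC <- distanceProfile(cmC, pairDistances(cmC, "bp"), nWindows = 8)
    medC <- subset(profC, sign == "positive")$median
    expect_lt(abs(medC[1] - medC[8]), 0.05)
})
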