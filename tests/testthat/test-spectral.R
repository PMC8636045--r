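test_that("shuffling preserves the marginal multisets it should", {
    sim <- simulateExpression(syntheticSpec(nGenes = 15, nSamples = 20,
                                            mode = "blocks", nBlocks = 3,
                                            seed = 4))
    m <- exprValues(sim$expr)
    sSamp <- exprValues(shuffleExpression(sim$expr, 1, within = "sample"))
    for (j in seq_len(ncol(m)))
        expect_identical(sort(unname(sSamp[, j])), sort(unname(m[, j])))
    sGene <- exprValues(shuffleExpression(sim$expr, 1, within = "gene"))
    for (i in seq_len(nrow(m)))
        expect_identical(sort(unname(sGene[i, ])), sort(unname(m[i, ])))
    # labels and coordinates untouched
    expect_identical(geneIds(shuffleExpression(sim$expr, 2)),
                     geneIds(sim$expr))
})

test_that("a single-gene matrix is invariant under within-sample shuffling", {
    x <- makeChromExpression(matrix(rnorm(8), 1,
                                    dimnames = list("gA", NULL)),
                             starts = 50)
    expect_identical(exprValues(shuffleExpression(x, 3, within = "sample")),
                     exprValues(x))
})

test_that("shuffled-data correlations are noise-sized", {
    sim <- simulateExpression(syntheticSpec(nGenes = 50, nSamples = 1000,
                                            mode = "blocks", nBlocks = 5,
                                            loading = 0.8, seed = 6))
    C <- corValues(nullCorrelations(sim$expr, n = 1, seed = 9)[[1]])
    expect_lt(mean(abs(C[upper.tri(C)])), 3 / sqrt(1000))
})

test_that("eigen spectra satisfy the closed forms and trace conservation", {
    n <- 7
    idSpec <- eigenSpectrum(diag(1, n))
    expect_equal(eigenvalues(idSpec), rep(1, n))
    rho <- 0.4
    two <- eigenSpectrum(matrix(c(1, rho, rho, 1), 2))
    expect_equal(eigenvalues(two), c(1 + rho, 1 - rho))
    sim <- simulateExpression(syntheticSpec(nGenes = 40, nSamples = 60,
                                            mode = "blocks", seed = 2))
    sp <- eigenSpectrum(pearsonMatrix(sim$expr))
    expect_lt(abs(sum(eigenvalues(sp)) - 40), 1e-8 * 40)
    expect_true(all(diff(eigenvalues(sp)) <= 0))
    expect_error(eigenSpectrum(matrix(c(1, 0.5, 0.1, 1), 2)),
                 "not symmetric")
})

test_that("null ensembles are reproducible from their seed", {
    sim <- simulateExpression(syntheticSpec(nGenes = 20, nSamples = 30,
                                            mode = "null", seed = 8))
    e1 <- buildNullEnsemble(sim$expr, nMatrices = 5, seed = 77)
    e2 <- buildNullEnsemble(sim$expr, nMatrices = 5, seed = 77)
    expect_identical(eigenvalues(e1), eigenvalues(e2))
    e3 <- buildNullEnsemble(sim$expr, nMatrices = 5, seed = 78)
    expect_false(identical(eigenvalues(e1), eigenvalues(e3)))
})

test_that("deviating-eigenvalue count behaves like a spiked-model detector", {
    # a single strong factor yields exactly one deviating eigenvalue
    sim <- simulateExpression(syntheticSpec(nGenes = 60, nSamples = 150,
                                            mode = "blocks", nBlocks = 1,
                                            loading = 0.9, seed = 14))
    ens <- buildNullEnsemble(sim$expr, nMatrices = 100, seed = 15)
    sp <- eigenSpectrum(pearsonMatrix(sim$expr))
    k <- countDeviatingEigenvalues(sp, ens, alpha = 0.01)
    expect_identical(as.integer(k), 1L)
    expect_true(attr(k, "threshold") > 1)
    expect_lte(as.integer(k), 60L)

    # k is monotone in alpha (larger alpha, lower threshold, larger k)
    k5 <- countDeviatingEigenvalues(sp, ens, alpha = 0.05)
    expect_gte(as.integer(k5), as.integer(k))

    expect_error(countDeviatingEigenvalues(sp, ens, alpha = 0), "alpha")
    expect_error(countDeviatingEigenvalues(sp, ens, alpha = 0.7), "alpha")
    expect_warning(countDeviatingEigenvalues(
        sp, buildNullEnsemble(sim$expr, nMatrices = 10, seed = 1),
        alpha = 0.01), "coarse")
})

test_that("Marchenko-Pastur density integrates to one on its support", {
    for (q in c(0.2, 0.5, 0.8)) {
        expect_equal(mpCDF((1 + sqrt(q))^2, q), 1, tolerance = 1e-6)
        expect_equal(mpCDF((1 - sqrt(q))^2, q), 0)
        mid <- mpCDF(1, q)
        expect_true(mid > 0 && mid < 1)
    }
    # ksDistanceToCDF is exact for a sample from a discrete grid
    expect_equal(ksDistanceToCDF(c(0.25, 0.75), function(x) x), 0.25)
})
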