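.grAt <- function(ranks, starts = NULL) {
    n <- length(ranks)
    if (is.null(starts)) starts <- ranks * 1000L
    GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = starts + 1L, width = 1L),
        gene_id = sprintf("g%03d", seq_len(n)), rank = as.integer(ranks))
}

test_that("nearest-neighbor distances follow the rank definition", {
    # one cluster at ranks 2, 5, 9
    g <- .grAt(c(2L, 5L, 9L))
    nnd <- nndDistribution(rep(1L, 3), g, metric = "rank")
    expect_identical(sort(nndValues(nnd)), c(3, 3, 4))
    # consecutive ranks: every NND is 1
    g2 <- .grAt(0:5)
    expect_true(all(nndValues(nndDistribution(rep(1L, 6), g2)) == 1))
    # two alternating clusters: every NND is 2
    g3 <- .grAt(0:7)
    lab <- rep(c(1L, 2L), 4)
    expect_true(all(nndValues(nndDistribution(lab, g3)) == 2))
})

test_that("bp metric, singleton exclusion and degenerate input behave", {
    g <- .grAt(0:3, starts = c(0L, 100L, 5000L, 5400L))
    nnd <- nndDistribution(c(1L, 1L, 2L, 1L), g, metric = "bp")
    # cluster 2 is a singleton: excluded, counted
    expect_identical(nnd@nSingletons, 1L)
    expect_identical(length(nndValues(nnd)), 3L)
    expect_identical(sort(nndValues(nnd)), c(100, 100, 5300))
    expect_error(nndDistribution(c(1L, 2L, 3L, 4L), g), "singletons")
    expect_error(nndDistribution(c(1L, 1L), g), "align")
})

test_that("Shannon entropy hits its closed forms", {
    g <- .grAt(0:5)
    flat <- nndDistribution(rep(1L, 6), g)           # all NNDs are 1
    expect_equal(shannonEntropy(flat), 0)
    expect_equal(shannonEntropy(c(2, 2, 3, 3, 5, 5, 9, 9)), log(4))
    expect_equal(shannonEntropy(c(1, 1, 2, 3), base = "2"), 1.5)
    # invariant to permutation of values
    v <- c(1, 1, 4, 2, 2, 2, 8)
    expect_equal(shannonEntropy(v), shannonEntropy(sample(v)))
    # maximal iff uniform over the support
    expect_lt(shannonEntropy(c(1, 1, 1, 2, 3, 4)), log(4))
})

test_that("nndCDF ends at one and steps at the observed values", {
    g <- .grAt(c(0L, 1L, 5L, 6L, 20L))
    nnd <- nndDistribution(rep(1L, 5), g)
    cdf <- nndCDF(nnd)
    expect_equal(cdf$prob[length(cdf$prob)], 1)
    expect_true(all(diff(cdf$value) > 0))
    expect_true(all(diff(cdf$prob) > 0))
})

test_that("KS distance is exact on closed-form cases", {
    expect_equal(ksDistance(c(1, 5, 7), c(1, 5, 7))$statistic, 0)
    expect_equal(ksDistance(c(1, 2), c(3, 4))$statistic, 1)
    expect_equal(ksDistance(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
    # symmetry
    a <- rnorm(20); b <- rnorm(35)
    expect_equal(ksDistance(a, b)$statistic, ksDistance(b, a)$statistic)
    expect_error(ksDistance(numeric(0), 1), "non-empty")
})

test_that("KS distance agrees with brute force and stats::ks.test", {
    set.seed(31)
    for (r in 1:25) {
        a <- sample(1:12, sample(3:30, 1), replace = TRUE)  # ties likely
        b <- sample(1:12, sample(3:30, 1), replace = TRUE) + runif(1, 0, 2)
        expect_identical(ksDistance(a, b)$statistic, bruteKS(a, b))
    }
    a <- rnorm(40); b <- rnorm(25, 0.5)   # continuous, tie-free
    expect_equal(ksDistance(a, b)$statistic,
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
})

test_that("permutation p-values detect shifts and respect add-one bounds", {
    set.seed(7)
    kt <- ksPermutationTest(rnorm(40), rnorm(40, 2), nResamples = 199,
                            seed = 5)
    expect_equal(kt$p.value, 1 / 200)      # never exactly zero
    ktNull <- ksPermutationTest(rnorm(40), rnorm(40), nResamples = 199,
                                seed = 6)
    expect_gt(ktNull$p.value, 0.05)
    # the observed statistic matches the exact KS
    a <- sample(1:5, 20, TRUE); b <- sample(1:5, 30, TRUE)
    expect_identical(ksPermutationTest(a, b, 9, 1)$statistic,
                     ksDistance(a, b)$statistic)
})

test_that("piece-wise KS against the null separates decay from noise", {
    sim <- simulateExpression(syntheticSpec(nGenes = 60, nSamples = 200,
                                            mode = "decay", loading = 0.9,
                                            decayScaleBp = 1e7, seed = 19))
    cm <- pearsonMatrix(sim$expr)
    nulls <- nullCorrelations(sim$expr, n = 5, seed = 23)
    res <- piecewiseKSvsNull(cm, nulls, pairDistances(cm, "bp"),
                             nWindows = 6, nResamples = 99, seed = 3)
    expect_equal(nrow(res$windows), 6L)
    # strong short-range signal, weaker long-range signal
    expect_gt(res$windows$statistic[1], res$windows$statistic[6])
    expect_lt(res$windows$p_value[1], 0.05)
    expect_true(all(res$windows$p_adjust >= res$windows$p_value))
    expect_true(res$mean_p_value >= 0 && res$mean_p_value <= 1)
})

test_that("phenotype comparison reports KS and entropy difference", {
    g <- .grAt(0:9)
    tight <- nndDistribution(rep(1:2, each = 5), g)   # contiguous clusters
    scattered <- nndDistribution(rep(1:2, times = 5), g)
    same <- comparePhenotypes(tight, tight)
    expect_equal(same$ks$statistic, 0)
    expect_equal(same$delta_entropy, 0)
    cmp <- comparePhenotypes(scattered, tight)
    expect_gt(cmp$ks$statistic, 0)
    # symmetry of the KS distance in argument order
    expect_equal(comparePhenotypes(tight, scattered)$ks$statistic,
                 cmp$ks$statistic)
})
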