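#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the standard
#' defaults: a 100-member shuffled null ensemble, 100 k-medoids restarts,
#' deviating-eigenvalue significance alpha = 0.01, 50 equal-occupancy
#' distance windows and 1000 permutation resamples. Input is either a
#' (expression TSV, BED) pair per phenotype or a named list of
#' \linkS4class{SyntheticSpec} objects.
#'
#' @param phenotypes named list: each element either
#'   \code{list(expression = path, bed = path)} or a
#'   \linkS4class{SyntheticSpec}.
#' @param control name of the control phenotype in \code{phenotypes} that
#'   the others are contrasted against (NULL: no contrasts).
#' @param chromosomes chromosome labels to process (NULL: all present).
#' @param nNull shuffled-ensemble size (default 100).
#' @param nRestarts k-medoids restarts (default 100).
#' @param alpha deviating-eigenvalue tail probability (default 0.01).
#' @param nWindows equal-occupancy distance windows (default 50).
#' @param nResamples KS permutation resamples (default 1000).
#' @param nNullCorrelations shuffled matrices kept as full correlation
#'   matrices for the piece-wise KS stage (default 10; kept smaller than
#'   \code{nNull} since each contributes all its gene pairs per window).
#' @param metric \code{"rank"} or \code{"bp"} for the NND statistics.
#' @param entropyBase \code{"e"} or \code{"2"}.
#' @param expressionFilter numeric or NA; if not NA, genes at or below this
#'   mean expression are dropped (NA default: input assumed preprocessed).
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param outDir output directory (NULL: nothing written).
#' @return a \code{cisClustConfig} list.
#' @export
pipelineConfig <- function(phenotypes, control = NULL, chromosomes = NULL,
                           nNull = 100L, nRestarts = 100L, alpha = 0.01,
                           nWindows = 50L, nResamples = 1000L,
                           nNullCorrelations = 10L,
                           metric = c("rank", "bp"),
                           entropyBase = c("e", "2"),
                           expressionFilter = NA_real_,
                           seed = 1L, outDir = NULL) {
    stopifnot(is.list(phenotypes), length(phenotypes) >= 1,
              !is.null(names(phenotypes)))
    if (!is.null(control) && !control %in% names(phenotypes))
        stop("control phenotype not among the phenotypes")
    structure(list(phenotypes = phenotypes, control = control,
                   chromosomes = chromosomes, nNull = as.integer(nNull),
                   nRestarts = as.integer(nRestarts), alpha = alpha,
                   nWindows = as.integer(nWindows),
                   nResamples = as.integer(nResamples),
                   nNullCorrelations = as.integer(nNullCorrelations),
                   metric = match.arg(metric),
                   entropyBase = match.arg(entropyBase),
                   expressionFilter = expressionFilter,
                   seed = as.integer(seed), outDir = outDir),
              class = "cisClustConfig")
}

.loadPhenotype <- function(ph, name, cfg) {
    if (methods::is(ph, "SyntheticSpec"))
        x <- simulateExpression(ph, phenotype = name)$expr
    else
        x <- readExpressionTable(ph$expression, ph$bed, phenotype = name)
    if (!is.na(cfg$expressionFilter))
        x <- filterLowExpression(x, cfg$expressionFilter)
    x
}

# One (chromosome, phenotype) cell: correlation -> null ensemble ->
# spectrum -> k -> clustering -> NND/entropy -> profile + piece-wise KS.
.runCell <- function(x, chrom, pheno, cfg) {
    seedOf <- function(stage) deriveSeed(cfg$seed, stage, chrom, pheno)
    cm <- pearsonMatrix(x)
    ens <- buildNullEnsemble(x, nMatrices = cfg$nNull, seed = seedOf("null"))
    spec <- eigenSpectrum(cm)
    k <- countDeviatingEigenvalues(spec, ens, alpha = cfg$alpha)
    clus <- kmedoidsBest(correlationToDissimilarity(cm), k,
                         nRestarts = cfg$nRestarts, seed = seedOf("cluster"))
    dists <- pairDistances(cm, metric = "bp")
    prof <- distanceProfile(cm, dists, nWindows = cfg$nWindows)
    nullCors <- nullCorrelations(x, n = cfg$nNullCorrelations,
                                 seed = seedOf("nullcor"))
    ksn <- piecewiseKSvsNull(cm, nullCors, dists, nWindows = cfg$nWindows,
                             nResamples = cfg$nResamples,
                             seed = seedOf("ksnull"))
    nnd <- if (!is.null(clus))
        tryCatch(nndDistribution(clusterLabels(clus), geneRanges(cm),
                                 metric = cfg$metric),
                 error = function(e) NULL)
    else NULL
    list(correlation = cm, ensemble = ens, spectrum = spec,
         k = as.integer(k), threshold = attr(k, "threshold"),
         clustering = clus, nnd = nnd,
         entropy = if (!is.null(nnd)) shannonEntropy(nnd, cfg$entropyBase)
                   else NA_real_,
         profile = prof, ks_vs_null = ksn,
         seeds = list(null = seedOf("null"), cluster = seedOf("cluster"),
                      nullcor = seedOf("nullcor"), ksnull = seedOf("ksnull")))
}

.writeCell <- function(cell, chrom, pheno, cfg) {
    pre <- file.path(cfg$outDir, paste0(chrom, "_", pheno))
    meta <- list(seed = cfg$seed, stage_seeds = cell$seeds,
                 chromosome = chrom, phenotype = pheno, k = cell$k,
                 threshold = cell$threshold,
                 parameters = cfg[c("nNull", "nRestarts", "alpha", "nWindows",
                                    "nResamples", "nNullCorrelations",
                                    "metric", "entropyBase")])
    ev <- data.frame(index = seq_along(eigenvalues(cell$spectrum)),
                     eigenvalue = eigenvalues(cell$spectrum))
    writeStatsTable(ev, paste0(pre, "_spectrum.tsv"), meta)
    writeStatsTable(data.frame(member = seq_along(eigenvalues(cell$ensemble)),
                               max_eigenvalue = eigenvalues(cell$ensemble)),
                    paste0(pre, "_null_max_eigenvalues.tsv"), meta)
    writeStatsTable(cell$profile, paste0(pre, "_profile.tsv"), meta)
    writeStatsTable(cell$ks_vs_null$windows, paste0(pre, "_ks_vs_null.tsv"),
                    c(meta, list(mean_p_value = cell$ks_vs_null$mean_p_value)))
    if (!is.null(cell$clustering))
        writeClusterTable(cell$clustering, geneRanges(cell$correlation),
                          paste0(pre, "_clusters.tsv"))
    if (!is.null(cell$nnd))
        writeStatsTable(data.frame(nnd = nndValues(cell$nnd)),
                        paste0(pre, "_nnd.tsv"),
                        c(meta, list(entropy = cell$entropy,
                                     n_singletons = cell$nnd@nSingletons)))
    invisible(NULL)
}

#' Run the full intra-chromosomal co-expression analysis
#'
#' For every chromosome and phenotype: Pearson correlation matrix, shuffled
#' null ensemble, eigenvalue spectrum, deviating-eigenvalue count k,
#' k-medoids clustering on 1 - |C|, cluster table, NND distribution and
#' entropy, correlation-versus-distance profile and piece-wise KS against
#' the null; then, per chromosome, each case phenotype's NND distribution is
#' contrasted against the control's. A failing cell is logged and skipped
#' without aborting the others. Re-running with the same configuration and
#' seed reproduces identical tables.
#'
#' @param cfg a configuration from [pipelineConfig()].
#' @return invisibly, a nested list \code{result$cells[[chrom]][[pheno]]}
#'   (see the internal cell structure: correlation, spectrum, k, clustering,
#'   nnd, entropy, profile, ks_vs_null) plus
#'   \code{result$comparisons[[chrom]][[pheno]]} with KS and entropy-
#'   difference contrasts against the control, and \code{result$errors}.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "cisClustConfig"))
    if (!is.null(cfg$outDir) && !dir.exists(cfg$outDir))
        dir.create(cfg$outDir, recursive = TRUE)
    loaded <- lapply(names(cfg$phenotypes), function(nm)
        splitByChromosome(.loadPhenotype(cfg$phenotypes[[nm]], nm, cfg)))
    names(loaded) <- names(cfg$phenotypes)
    chroms <- cfg$chromosomes
    if (is.null(chroms))
        chroms <- sort(unique(unlist(lapply(loaded, names))))
    cells <- list(); errors <- list()
    for (chrom in chroms) {
        cells[[chrom]] <- list()
        for (pheno in names(loaded)) {
            x <- loaded[[pheno]][[chrom]]
            if (is.null(x)) next
            cell <- tryCatch(.runCell(x, chrom, pheno, cfg),
                             error = function(e) e)
            if (inherits(cell, "error")) {
                errors[[paste(chrom, pheno, sep = "/")]] <-
                    conditionMessage(cell)
                message("cell ", chrom, "/", pheno, " failed: ",
                        conditionMessage(cell))
                next
            }
            cells[[chrom]][[pheno]] <- cell
            if (!is.null(cfg$outDir)) .writeCell(cell, chrom, pheno, cfg)
        }
    }
    comparisons <- list()
    if (!is.null(cfg$control)) {
        for (chrom in names(cells)) {
            ctrl <- cells[[chrom]][[cfg$control]]
            if (is.null(ctrl) || is.null(ctrl$nnd)) next
            comparisons[[chrom]] <- list()
            for (pheno in setdiff(names(cells[[chrom]]), cfg$control)) {
                case <- cells[[chrom]][[pheno]]
                if (is.null(case) || is.null(case$nnd)) next
                cmp <- comparePhenotypes(ctrl$nnd, case$nnd,
                                         base = cfg$entropyBase)
                comparisons[[chrom]][[pheno]] <- cmp
                if (!is.null(cfg$outDir))
                    writeStatsTable(
                        data.frame(chromosome = chrom, control = cfg$control,
                                   case = pheno,
                                   ks_statistic = cmp$ks$statistic,
                                   delta_entropy = cmp$delta_entropy,
                                   entropy_control = ctrl$entropy,
                                   entropy_case = case$entropy),
                        file.path(cfg$outDir,
                                  paste0(chrom, "_", pheno, "_vs_",
                                         cfg$control, "_comparison.tsv")),
                        list(seed = cfg$seed, entropyBase = cfg$entropyBase))
            }
        }
    }
    invisible(list(cells = cells, comparisons = comparisons, errors = errors,
                   config = cfg))
}
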