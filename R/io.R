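#' Read an expression table with BED gene coordinates
#'
#' Reads a tab-separated expression table (first column \code{gene_id},
#' header row of sample identifiers, one row per gene) together with a BED
#' file of gene coordinates (chrom, chromStart, chromEnd, name). Genes
#' present in both files are retained, sorted by (chromosome, start,
#' gene_id), and given 0-based per-chromosome ranks; genes missing from
#' either file are dropped with a message reporting the count. The BED start
#' column (0-based, half-open convention) is used verbatim as the gene start
#' coordinate.
#'
#' Genes whose expression is constant across samples are dropped with a
#' warning: their Pearson correlation is undefined (zero variance).
#'
#' @param path expression TSV path.
#' @param annotationPath BED path (>= 4 columns; the name column must match
#'   the expression table's gene ids).
#' @param phenotype label stored in the returned object.
#' @param dropZeroVariance drop constant genes (default TRUE).
#' @return a \linkS4class{ChromExpression} (possibly multi-chromosome; see
#'   [splitByChromosome()]).
#' @seealso [writeExpressionTable()], [filterLowExpression()]
#' @export
readExpressionTable <- function(path, annotationPath,
                                phenotype = NA_character_,
                                dropZeroVariance = TRUE) {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = NA, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("expression table needs gene ids plus >= 1 sample")
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate gene ids in expression table: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- tab[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
        col <- vals[[j]]
        if (!is.numeric(col)) {
            suppressWarnings(num <- as.numeric(col))
            bad <- which(is.na(num) & !is.na(col))
            if (length(bad))
                stop(sprintf("non-numeric value in row '%s', column '%s'",
                             ids[bad[1]], colnames(vals)[j]))
            vals[[j]] <- num
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    if (anyNA(m)) stop("expression table contains missing values")

    bed <- rtracklayer::import(annotationPath, format = "BED")
    bedIds <- S4Vectors::mcols(bed)$name
    if (is.null(bedIds)) stop("BED file must have a name column (>= 4 columns)")
    keep <- intersect(ids, bedIds)
    nDropped <- length(ids) - length(keep) + sum(!bedIds %in% ids)
    if (length(keep) == 0)
        stop("no genes shared between expression table and BED annotation")
    if (nDropped > 0)
        message(nDropped, " gene(s) absent from expression table or BED dropped")
    bed <- bed[match(keep, bedIds)]
    genes <- data.frame(gene_id = keep,
                        chromosome = as.character(GenomicRanges::seqnames(bed)),
                        start_bp = GenomicRanges::start(bed) - 1L)
    x <- ChromExpression(m[keep, , drop = FALSE], genes, phenotype = phenotype)
    if (dropZeroVariance) {
        v <- apply(exprValues(x), 1, stats::var)
        if (any(v == 0)) {
            warning(sum(v == 0), " zero-variance gene(s) dropped: ",
                    paste(utils::head(geneIds(x)[v == 0], 5), collapse = ", "))
            x <- ChromExpression(exprValues(x)[v > 0, , drop = FALSE],
                                 as.data.frame(geneAnnotationTable(x))[v > 0,
                                     c("gene_id", "chromosome", "start_bp")],
                                 phenotype = phenotype)
        }
    }
    x
}

#' Gene annotation table of a ChromExpression
#'
#' @param x a \linkS4class{ChromExpression}.
#' @return data.frame with columns gene_id, chromosome, start_bp (0-based)
#'   and rank.
#' @export
geneAnnotationTable <- function(x) {
    gr <- SummarizedExperiment::rowRanges(x)
    data.frame(gene_id = S4Vectors::mcols(gr)$gene_id,
               chromosome = as.character(GenomicRanges::seqnames(gr)),
               start_bp = GenomicRanges::start(gr) - 1L,
               rank = as.integer(S4Vectors::mcols(gr)$rank),
               stringsAsFactors = FALSE)
}

#' Write an expression table (and optionally its BED annotation)
#'
#' Writes the TSV layout read by [readExpressionTable()]: first column
#' \code{gene_id}, then one column per sample. Numeric values are written at
#' full double precision, so write/read round-trips reproduce the matrix.
#'
#' @param x a \linkS4class{ChromExpression}.
#' @param path output TSV path.
#' @param bedPath optional path; if given, the gene coordinates are written
#'   as a 4-column BED alongside.
#' @export
writeExpressionTable <- function(x, path, bedPath = NULL) {
    m <- exprValues(x)
    df <- data.frame(gene_id = geneIds(x), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bedPath)) writeGeneBed(x, bedPath)
    invisible(path)
}

#' Write gene coordinates as BED
#'
#' @param x a \linkS4class{ChromExpression} or \linkS4class{GRanges} with a
#'   \code{gene_id} column.
#' @param path output BED path (chrom, chromStart, chromEnd, name).
#' @export
writeGeneBed <- function(x, path) {
    if (methods::is(x, "ChromExpression"))
        x <- SummarizedExperiment::rowRanges(x)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                     start = GenomicRanges::start(x) - 1L,
                     end = GenomicRanges::end(x),
                     name = S4Vectors::mcols(x)$gene_id)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Filter genes by mean expression
#'
#' Retains genes whose mean expression across samples is strictly greater
#' than \code{threshold} (the conventional pre-log mean > 10 filter for
#' RNA-Seq count-scale values), then recomputes per-chromosome ranks. On
#' already log-transformed input the caller should pass the threshold on the
#' matching scale, or skip the filter entirely if the table is already
#' preprocessed (the usual case; this is the default pipeline behaviour).
#'
#' @param x a \linkS4class{ChromExpression}.
#' @param threshold non-negative numeric; default 10.
#' @return a filtered \linkS4class{ChromExpression} (possibly with 0 genes,
#'   reported via a message).
#' @export
filterLowExpression <- function(x, threshold = 10) {
    stopifnot(threshold >= 0)
    keep <- rowMeans(exprValues(x)) > threshold
    if (!all(keep))
        message(sum(!keep), " gene(s) at or below mean expression ",
                threshold, " removed")
    if (!any(keep)) message("no genes retained after expression filter")
    ann <- geneAnnotationTable(x)[keep, c("gene_id", "chromosome", "start_bp")]
    ChromExpression(exprValues(x)[keep, , drop = FALSE], ann,
                    phenotype = phenotype(x))
}

#' Write / read a cluster assignment table
#'
#' The table has columns \code{gene_id}, \code{chromosome}, \code{start_bp},
#' \code{rank}, \code{cluster_id} (0-based, every id 0..k-1 present) and
#' \code{is_medoid}; it round-trips losslessly through
#' [readClusterTable()].
#'
#' @param result a \linkS4class{ClusteringResult}.
#' @param genes the \linkS4class{GRanges} (or \linkS4class{ChromExpression})
#'   the clustering was computed over, in matrix order.
#' @param path output TSV path.
#' @export
writeClusterTable <- function(result, genes, path) {
    if (methods::is(genes, "ChromExpression"))
        genes <- SummarizedExperiment::rowRanges(genes)
    if (length(genes) != length(result@labels))
        stop("label vector length must equal the gene list length")
    df <- data.frame(
        gene_id = S4Vectors::mcols(genes)$gene_id,
        chromosome = as.character(GenomicRanges::seqnames(genes)),
        start_bp = GenomicRanges::start(genes) - 1L,
        rank = as.integer(S4Vectors::mcols(genes)$rank),
        cluster_id = result@labels - 1L,
        is_medoid = seq_along(genes) %in% result@medoids)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeClusterTable
#' @return \code{readClusterTable}: the data.frame written by
#'   \code{writeClusterTable}.
#' @export
readClusterTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    needed <- c("gene_id", "chromosome", "start_bp", "rank", "cluster_id",
                "is_medoid")
    if (!all(needed %in% colnames(df)))
        stop("not a cluster table: missing column(s) ",
             paste(setdiff(needed, colnames(df)), collapse = ", "))
    df$is_medoid <- as.logical(df$is_medoid)
    df
}

#' Write a statistics table with a JSON sidecar of run metadata
#'
#' @param df data.frame to write as TSV.
#' @param path output path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @param metadata named list (seed, parameters, ...) recorded alongside;
#'   the package version is added automatically.
#' @export
writeStatsTable <- function(df, path, metadata = list()) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    metadata$package <- "cisClust"
    metadata$version <- as.character(utils::packageVersion("cisClust"))
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
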