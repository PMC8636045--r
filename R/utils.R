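# Run expr with a local RNG state seeded at `seed`; the caller's RNG
# state is restored afterwards so package functions never perturb it.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic 31-bit sub-seed from a master seed and a character tag
# (multiplicative fold over the tag bytes, exact in double arithmetic).
# Each pipeline stage / chromosome / phenotype draws from its own stream,
# so adding a cell never changes another cell's results.
deriveSeed <- function(seed, ...) {
    tag <- paste(..., sep = "/")
    h <- as.numeric(seed) %% 2147483647
    for (b in utf8ToInt(tag))
        h <- (h * 69069 + b) %% 2147483647
    as.integer(h)
}

#' Construct a ChromExpression object
#'
#' Binds a genes x samples expression matrix to gene coordinates, sorts genes
#' by (chromosome, start, gene_id) and assigns per-chromosome 0-based ranks.
#'
#' @param values numeric matrix, one row per gene, one column per sample.
#' @param genes either a \linkS4class{GRanges} with a \code{gene_id} metadata
#'   column, or a data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start_bp} (0-based start coordinate). Row order must match
#'   \code{values}.
#' @param phenotype single character label stored in the object metadata.
#' @return a \linkS4class{ChromExpression}.
#' @examples
#' genes <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                     chromosome = "chr1", start_bp = c(100, 5000, 900))
#' m <- matrix(rnorm(12), nrow = 3, dimnames = list(genes$gene_id, NULL))
#' x <- ChromExpression(m, genes, phenotype = "control")
#' geneRanks(x)   # ranks follow start_bp order: g1, g3, g2
#' @export
ChromExpression <- function(values, genes, phenotype = NA_character_) {
    values <- as.matrix(values)
    if (is.data.frame(genes)) {
        stopifnot(all(c("gene_id", "chromosome", "start_bp") %in% colnames(genes)))
        gr <- GenomicRanges::GRanges(
            seqnames = genes$chromosome,
            ranges = IRanges::IRanges(start = as.integer(genes$start_bp) + 1L,
                                      width = 1L),
            gene_id = as.character(genes$gene_id))
    } else {
        gr <- genes
        if (is.null(S4Vectors::mcols(gr)$gene_id))
            stop("GRanges 'genes' must carry a gene_id metadata column")
    }
    if (length(gr) != nrow(values))
        stop("number of annotations must equal the number of expression rows")
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), S4Vectors::mcols(gr)$gene_id)
    gr <- gr[o]
    values <- values[o, , drop = FALSE]
    # within a chromosome the indices are already position-ordered, so
    # ranks are 0..N-1 per chromosome
    S4Vectors::mcols(gr)$rank <- unsplit(
        lapply(split(seq_along(gr), as.character(GenomicRanges::seqnames(gr))),
               function(i) seq_along(i) - 1L),
        as.character(GenomicRanges::seqnames(gr)))
    names(gr) <- S4Vectors::mcols(gr)$gene_id
    rownames(values) <- S4Vectors::mcols(gr)$gene_id
    if (is.null(colnames(values)))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values), rowRanges = gr,
        metadata = list(phenotype = phenotype))
    methods::new("ChromExpression", se)
}

#' Split a multi-chromosome ChromExpression by chromosome
#'
#' @param x a \linkS4class{ChromExpression}.
#' @return a named list of single-chromosome \linkS4class{ChromExpression}
#'   objects, in chromosome label order.
#' @export
splitByChromosome <- function(x) {
    stopifnot(methods::is(x, "ChromExpression"))
    ch <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(x)))
    lapply(split(seq_along(ch), ch), function(i) x[i, ])
}
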