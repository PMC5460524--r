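#' Construct a CoexMatrix from a gene x sample matrix
#'
#' @param values numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames); no missing values
#' @param stage preprocessing stage tag, `"raw"` by default
#' @return a [CoexMatrix-class]
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' CoexMatrix(m)
#' @export
CoexMatrix <- function(values, stage = c("raw", "normalized", "logged")) {
    stage <- match.arg(stage)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values))
    new("CoexMatrix", se, stage = stage)
}

#' @describeIn CoexMatrix the preprocessing stage tag
#' @param x a `CoexMatrix`
#' @export
stage <- function(x) {
    stopifnot(is(x, "CoexMatrix"))
    x@stage
}

#' @describeIn CoexMatrix the expression values as a plain matrix
#' @export
exprValues <- function(x) {
    stopifnot(is(x, "CoexMatrix"))
    SummarizedExperiment::assay(x, "expr")
}

setMethod("show", "CoexMatrix", function(object) {
    cat(sprintf("CoexMatrix: %d genes x %d samples [stage: %s]\n",
                nrow(object), ncol(object), object@stage))
    invisible(NULL)
})

.replaceValues <- function(x, values, stage) {
    SummarizedExperiment::assay(x, "expr") <- values
    x@stage <- stage
    validObject(x)
    x
}

#' Remove samples with low sequencing depth
#'
#' Drops samples whose total estimated counts fall below `minTotal`
#' (default one million), keeping the surviving samples in their original
#' order. Depth totals come from the quantification step, not from the TPM
#' matrix itself, so they are passed separately.
#'
#' @param x a [CoexMatrix-class]
#' @param counts named numeric vector of per-sample total estimated counts;
#'   must cover every sample of `x`
#' @param minTotal depth cutoff; samples with `counts < minTotal` are removed
#' @return a [CoexMatrix-class] with the surviving samples
#' @export
filterSamplesByDepth <- function(x, counts, minTotal = 1e6) {
    stopifnot(is(x, "CoexMatrix"))
    if (!is.numeric(minTotal) || length(minTotal) != 1L || minTotal <= 0)
        stop("minTotal must be a single positive number")
    samples <- colnames(x)
    missing <- setdiff(samples, names(counts))
    if (length(missing) > 0L)
        stop("depth totals missing for sample(s): ",
             paste(missing, collapse = ", "))
    keep <- counts[samples] >= minTotal
    if (!any(keep))
        stop("all samples fall below the depth cutoff of ", minTotal)
    x[, samples[keep]]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same distribution: the reference
#' distribution is the across-sample mean of the column order statistics, and
#' each value is replaced by the reference value at its within-column rank.
#' Ties within a column receive the mean of the reference values over their
#' rank span, so tied inputs stay tied.
#'
#' @param x a [CoexMatrix-class] at stage `"raw"`, with at least two samples
#' @return a [CoexMatrix-class] at stage `"normalized"`
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' exprValues(quantileNormalize(CoexMatrix(m)))
#' @export
quantileNormalize <- function(x) {
    stopifnot(is(x, "CoexMatrix"))
    if (x@stage != "raw")
        stop("quantileNormalize expects a matrix at stage 'raw', got '",
             x@stage, "'")
    vals <- exprValues(x)
    if (ncol(vals) < 2L)
        stop("quantile normalization needs at least two samples")
    ref <- rowMeans(apply(vals, 2L, sort, method = "radix"))
    out <- apply(vals, 2L, function(col) {
        res <- numeric(length(col))
        res[order(col, method = "radix")] <- ref
        # tied entries share the mean reference value over their rank span
        stats::ave(res, match(col, col), FUN = mean)
    })
    dimnames(out) <- dimnames(vals)
    .replaceValues(x, out, "normalized")
}

#' Log-transform an expression matrix
#'
#' Replaces every value x by `log2(x + pseudoCount)`. The default pseudo-count
#' of 4 damps the log-scale variance of weakly expressed genes.
#'
#' @param x a [CoexMatrix-class] at stage `"normalized"` (a raw matrix is
#'   accepted with a warning)
#' @param pseudoCount positive offset added before taking log2
#' @return a [CoexMatrix-class] at stage `"logged"`
#' @export
logTransform <- function(x, pseudoCount = 4) {
    stopifnot(is(x, "CoexMatrix"))
    if (!is.numeric(pseudoCount) || length(pseudoCount) != 1L ||
        pseudoCount <= 0)
        stop("pseudoCount must be a single positive number")
    if (x@stage == "logged")
        stop("matrix is already log-transformed")
    if (x@stage == "raw")
        warning("log-transforming a raw (not quantile-normalized) matrix")
    .replaceValues(x, log2(exprValues(x) + pseudoCount), "logged")
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlates every pair of gene expression profiles (rows) across samples.
#' Genes with zero variance have no defined correlation; they are reported in
#' an error so the caller can drop them explicitly rather than let NaN values
#' leak into the ranked lists.
#'
#' @param x a [CoexMatrix-class] at stage `"logged"` with >= 3 samples
#' @return symmetric numeric matrix with unit diagonal, gene ids as dimnames
#' @export
correlationMatrix <- function(x) {
    stopifnot(is(x, "CoexMatrix"))
    if (x@stage != "logged")
        stop("correlationMatrix expects a matrix at stage 'logged', got '",
             x@stage, "'")
    vals <- exprValues(x)
    if (ncol(vals) < 3L)
        stop("at least three samples are required")
    v <- apply(vals, 1L, stats::var)
    if (any(v == 0))
        stop("zero-variance gene(s), drop them before correlating: ",
             paste(rownames(vals)[v == 0], collapse = ", "))
    cc <- stats::cor(t(vals), method = "pearson")
    cc <- (cc + t(cc)) / 2
    diag(cc) <- 1
    cc
}

#' Ranked gene list for a target gene
#'
#' All genes except the target, ordered by decreasing correlation with the
#' target. Ties are broken lexicographically (C locale) by gene id so the
#' order is identical across runs and platforms.
#'
#' @param corr symmetric correlation matrix as from [correlationMatrix()]
#' @param target a gene id present in `corr`
#' @return a [RankedGeneList-class] with n = nrow(corr) - 1 entries
#' @export
rankedGeneList <- function(corr, target) {
    if (!is.matrix(corr) || is.null(rownames(corr)))
        stop("corr must be a matrix with gene ids as dimnames")
    if (!target %in% rownames(corr))
        stop("target gene '", target, "' not present in the correlation matrix")
    r <- corr[target, colnames(corr) != target]
    o <- order(-r, names(r), method = "radix")
    new("RankedGeneList", target = target, genes = names(r)[o],
        correlations = unname(r[o]))
}

#' Accessors for RankedGeneList
#'
#' @param x a [RankedGeneList-class]
#' @return `targetGene()` the target id; `rankedGenes()` the ordered gene
#'   ids; `rankedCorrelations()` the parallel correlation values.
#' @name rankedlist-accessors
NULL

#' @rdname rankedlist-accessors
#' @export
targetGene <- function(x) x@target

#' @rdname rankedlist-accessors
#' @export
rankedGenes <- function(x) x@genes

#' @rdname rankedlist-accessors
#' @export
rankedCorrelations <- function(x) x@correlations

setMethod("show", "RankedGeneList", function(object) {
    n <- length(object@genes)
    cat(sprintf("RankedGeneList for '%s' (%d genes)\n", object@target, n))
    k <- min(3L, n)
    for (i in seq_len(k))
        cat(sprintf("  %d. %s (r = %.4f)\n", i, object@genes[i],
                    object@correlations[i]))
    if (n > k) cat("  ...\n")
    invisible(NULL)
})

#' UPGMA dendrogram of the samples
#'
#' Average-linkage (UPGMA) hierarchical clustering of the samples, using
#' distance d = 1 - Pearson correlation between sample expression profiles.
#' Used as a sanity check that samples group by biology (tissue, condition)
#' before trusting the gene-gene correlations.
#'
#' @param x a [CoexMatrix-class] with >= 2 samples (any stage)
#' @return an [ape::phylo] ultrametric tree whose tips are the sample ids;
#'   cophenetic tip-tip distances equal the UPGMA merge heights. Serialize
#'   with [ape::write.tree()].
#' @export
upgmaDendrogram <- function(x) {
    stopifnot(is(x, "CoexMatrix"))
    vals <- exprValues(x)
    if (ncol(vals) < 2L)
        stop("at least two samples are required")
    d <- stats::as.dist(1 - stats::cor(vals, method = "pearson"))
    ape::as.phylo(stats::hclust(d, method = "average"))
}

#' Read / write expression matrices as TSV
#'
#' The format is a header row of sample ids preceded by a `gene_id` column
#' name, then one row per gene. Lines starting with `#` are ignored on read;
#' values are written with 10 significant digits.
#'
#' @param path TSV file path
#' @param stage stage tag to attach to the matrix read
#' @return `readExpressionTSV()` a [CoexMatrix-class]; `writeExpressionTSV()`
#'   the path, invisibly
#' @export
readExpressionTSV <- function(path, stage = "raw") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression TSV needs a gene id column and >= 1 sample")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    CoexMatrix(m, stage = stage)
}

#' @rdname readExpressionTSV
#' @param x a [CoexMatrix-class]
#' @param comments optional character vector of comment lines (written with a
#'   leading `#`)
#' @export
writeExpressionTSV <- function(x, path, comments = NULL) {
    stopifnot(is(x, "CoexMatrix"))
    vals <- exprValues(x)
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comments))
        writeLines(paste0("# ", comments), con)
    writeLines(paste(c("gene_id", colnames(vals)), collapse = "\t"), con)
    body <- apply(format(vals, digits = 10, trim = TRUE, scientific = FALSE),
                  1L, paste, collapse = "\t")
    writeLines(paste(rownames(vals), body, sep = "\t"), con)
    invisible(path)
}
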