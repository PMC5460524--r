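#' Simulate an expression corpus with planted co-expressed pathways
#'
#' Draws gene expression from a multivariate normal with block-exchangeable
#' correlation: genes of planted block p share pairwise correlation
#' `pathwayRho[p]`, genes of different blocks (and background genes) share
#' `backgroundRho`, and each planted block is recorded as a gene set in the
#' ground-truth collection. The latent Gaussian values z are mapped to
#' non-negative expression units by `max(0, baseline + noiseSd * z)` so that
#' quantile normalization and the log2 pseudo-count transform remain
#' meaningful; no count-level (negative binomial, library size) realism is
#' attempted. The construction is a one-factor-per-block model, so the
#' correlation matrix is positive semi-definite exactly when
#' `0 <= backgroundRho <= min(pathwayRho) < 1`, which is validated before
#' sampling. The simulation is fully reproducible from the seed.
#'
#' @param nGenes total number of genes
#' @param nSamples number of samples
#' @param pathwaySizes integer vector of planted block sizes (may be empty;
#'   sizes must sum to at most `nGenes`)
#' @param pathwayRho within-block correlations, parallel to `pathwaySizes`,
#'   each in \[0, 1)
#' @param backgroundRho correlation between genes not sharing a block
#' @param noiseSd standard deviation of expression around the baseline
#' @param baseline mean expression level before flooring at zero
#' @param seed mandatory RNG seed (integer)
#' @return a [SyntheticDataset-class]
#' @examples
#' ds <- simulateDataset(nGenes = 60, nSamples = 20,
#'                       pathwaySizes = c(10, 10), pathwayRho = c(0.8, 0.1),
#'                       seed = 1)
#' ds
#' @export
simulateDataset <- function(nGenes, nSamples, pathwaySizes = integer(0),
                            pathwayRho = numeric(0), backgroundRho = 0,
                            noiseSd = 2, baseline = 10, seed) {
    if (missing(seed)) stop("a seed is mandatory for reproducibility")
    nGenes <- as.integer(nGenes)
    nSamples <- as.integer(nSamples)
    pathwaySizes <- as.integer(pathwaySizes)
    if (length(pathwaySizes) != length(pathwayRho))
        stop("pathwaySizes and pathwayRho must be parallel")
    if (sum(pathwaySizes) > nGenes)
        stop("planted pathway sizes exceed the number of genes")
    if (any(pathwayRho < 0) || any(pathwayRho >= 1))
        stop("within-block correlations must lie in [0, 1)")
    if (backgroundRho < 0 || backgroundRho >= 1)
        stop("backgroundRho must lie in [0, 1)")
    if (length(pathwayRho) > 0L && any(pathwayRho < backgroundRho))
        stop("covariance not positive semi-definite: every within-block ",
             "correlation must be >= backgroundRho")
    if (noiseSd <= 0) stop("noiseSd must be positive")

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(oldSeed)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else {
            assign(".Random.seed", oldSeed, envir = globalenv())
        }
    })
    set.seed(as.integer(seed))

    nP <- length(pathwaySizes)
    geneIds <- sprintf(paste0("g%0", nchar(nGenes), "d"), seq_len(nGenes))
    sampleIds <- sprintf(paste0("s%0", nchar(nSamples), "d"),
                         seq_len(nSamples))
    block <- rep(0L, nGenes)  # 0 = background
    if (nP > 0L)
        block[seq_len(sum(pathwaySizes))] <- rep(seq_len(nP),
                                                 times = pathwaySizes)

    shared <- matrix(stats::rnorm(nSamples), 1L, nSamples)
    blockFac <- if (nP > 0L)
        matrix(stats::rnorm(nP * nSamples), nP, nSamples) else NULL
    eps <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples)

    rhoGene <- ifelse(block == 0L, backgroundRho, c(0, pathwayRho)[block + 1L])
    z <- sqrt(backgroundRho) * matrix(shared, nGenes, nSamples,
                                      byrow = TRUE)[, , drop = FALSE]
    if (nP > 0L) {
        inBlock <- block > 0L
        z[inBlock, ] <- z[inBlock, , drop = FALSE] +
            sqrt(pathwayRho[block[inBlock]] - backgroundRho) *
            blockFac[block[inBlock], , drop = FALSE]
    }
    z <- z + sqrt(1 - rhoGene) * eps

    values <- pmax(baseline + noiseSd * z, 0)
    dimnames(values) <- list(geneIds, sampleIds)

    truthSets <- list()
    if (nP > 0L) {
        truthSets <- lapply(seq_len(nP), function(p) geneIds[block == p])
        names(truthSets) <- sprintf("planted%02d", seq_len(nP))
    }
    truth <- PathwaySet(
        truthSets,
        descriptions = if (nP > 0L)
            sprintf("planted block, size %d, rho %.3g", pathwaySizes,
                    pathwayRho) else NULL)

    config <- list(nGenes = nGenes, nSamples = nSamples,
                   pathwaySizes = pathwaySizes, pathwayRho = pathwayRho,
                   backgroundRho = backgroundRho, noiseSd = noiseSd,
                   baseline = baseline, seed = as.integer(seed))
    new("SyntheticDataset", expression = CoexMatrix(values, stage = "raw"),
        truth = truth, config = config)
}

setMethod("show", "SyntheticDataset", function(object) {
    cfg <- object@config
    cat(sprintf(
        "SyntheticDataset: %d genes x %d samples, %d planted pathway(s), seed %d\n",
        cfg$nGenes, cfg$nSamples, length(cfg$pathwaySizes), cfg$seed))
    invisible(NULL)
})

#' Accessors for SyntheticDataset
#'
#' @param x a [SyntheticDataset-class]
#' @return `syntheticExpression()` the raw [CoexMatrix-class];
#'   `syntheticTruth()` the planted [PathwaySet-class]; `syntheticConfig()`
#'   the configuration echo.
#' @name synthetic-accessors
NULL

#' @rdname synthetic-accessors
#' @export
syntheticExpression <- function(x) x@expression

#' @rdname synthetic-accessors
#' @export
syntheticTruth <- function(x) x@truth

#' @rdname synthetic-accessors
#' @export
syntheticConfig <- function(x) x@config

#' Condition-positive / condition-negative labels from the planted truth
#'
#' Labels every (gene, planted pathway) pair: 1 when the gene is a member of
#' the planted block, 0 otherwise — the labelling used for ROC evaluation of
#' the predictions.
#'
#' @param dataset a [SyntheticDataset-class]
#' @return data.frame with columns `gene_id`, `set_id`, `label` covering the
#'   full gene x pathway grid
#' @export
plantedTruthLabels <- function(dataset) {
    stopifnot(is(dataset, "SyntheticDataset"))
    genes <- rownames(exprValues(dataset@expression))
    ids <- pathwayIds(dataset@truth)
    grid <- expand.grid(gene_id = genes, set_id = ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$label <- as.integer(mapply(function(g, s)
        g %in% dataset@truth@sets[[s]], grid$gene_id, grid$set_id))
    grid
}
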