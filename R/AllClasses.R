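#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata
#' @importFrom stats setNames
#' @useDynLib coexPath, .registration = TRUE
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' PathwaySet: a collection of gene sets
#'
#' Holds named gene sets (pathways) as character vectors of gene identifiers,
#' an optional description per set, and an optional gene universe (the genes
#' measurable in the expression matrix). When a universe is present, the
#' effective size of a set is the size of its intersection with the universe;
#' [filterPathways()] materializes that intersection.
#'
#' @slot sets named list of character vectors (unique, non-empty members)
#' @slot descriptions named character vector parallel to `sets`
#' @slot universe character vector of measurable gene ids, or `NULL`
#'
#' @seealso [readGMT()], [writeGMT()], [filterPathways()]
#' @export
setClass("PathwaySet",
    slots = c(
        sets = "list",
        descriptions = "character",
        universe = "characterOrNULL"
    )
)

setValidity("PathwaySet", function(object) {
    msgs <- character()
    ids <- names(object@sets)
    if (length(object@sets) > 0L && (is.null(ids) || anyNA(ids) || any(ids == "")))
        msgs <- c(msgs, "every gene set must have a non-empty id")
    if (anyDuplicated(ids))
        msgs <- c(msgs, sprintf(
            "duplicate set ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")
        ))
    if (!identical(names(object@descriptions), ids))
        msgs <- c(msgs, "descriptions must be named parallel to sets")
    for (i in seq_along(object@sets)) {
        members <- object@sets[[i]]
        if (!is.character(members) || length(members) == 0L)
            msgs <- c(msgs, sprintf("set '%s' has no members", ids[i]))
        else if (anyDuplicated(members))
            msgs <- c(msgs, sprintf("set '%s' has duplicate members", ids[i]))
    }
    if (length(msgs)) msgs else TRUE
})

#' CoexMatrix: an expression matrix with a preprocessing stage tag
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper around one
#' gene x sample assay, tagged with the preprocessing stage it has reached:
#' `"raw"` (non-negative expression units such as TPM), `"normalized"`
#' (quantile-normalized) or `"logged"` (log2 after pseudo-count addition).
#' Downstream steps check the tag so that, e.g., correlations are only ever
#' computed on logged data.
#'
#' @slot stage one of `"raw"`, `"normalized"`, `"logged"`
#' @seealso [CoexMatrix()], [quantileNormalize()], [logTransform()],
#'   [correlationMatrix()]
#' @export
setClass("CoexMatrix",
    contains = "SummarizedExperiment",
    slots = c(stage = "character")
)

setValidity("CoexMatrix", function(object) {
    msgs <- character()
    if (length(object@stage) != 1L ||
        !object@stage %in% c("raw", "normalized", "logged"))
        msgs <- c(msgs, "stage must be one of 'raw', 'normalized', 'logged'")
    if (length(SummarizedExperiment::assays(object)) != 1L)
        msgs <- c(msgs, "exactly one assay expected")
    x <- SummarizedExperiment::assay(object)
    if (anyNA(x))
        msgs <- c(msgs, "expression values must not contain missing values")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        msgs <- c(msgs, "gene (row) and sample (column) ids are required")
    else {
        if (anyDuplicated(rownames(x)))
            msgs <- c(msgs, "gene ids must be unique")
        if (anyDuplicated(colnames(x)))
            msgs <- c(msgs, "sample ids must be unique")
    }
    if (length(msgs) == 0L && object@stage %in% c("raw", "normalized") &&
        any(x < 0))
        msgs <- c(msgs, "raw/normalized expression values must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' RankedGeneList: genes ordered by co-expression with one target gene
#'
#' For a target gene t, all other genes of the correlation matrix ordered by
#' decreasing Pearson correlation with t (ties broken lexicographically by
#' gene id so the order is reproducible).
#'
#' @slot target the target gene id
#' @slot genes character vector of the n = (#genes - 1) remaining genes
#' @slot correlations numeric vector parallel to `genes`, non-increasing
#' @seealso [rankedGeneList()]
#' @export
setClass("RankedGeneList",
    slots = c(
        target = "character",
        genes = "character",
        correlations = "numeric"
    )
)

setValidity("RankedGeneList", function(object) {
    msgs <- character()
    if (length(object@target) != 1L)
        msgs <- c(msgs, "exactly one target gene expected")
    if (length(object@genes) != length(object@correlations))
        msgs <- c(msgs, "genes and correlations must be parallel")
    if (object@target %in% object@genes)
        msgs <- c(msgs, "target must not appear among the ranked genes")
    if (anyDuplicated(object@genes))
        msgs <- c(msgs, "ranked genes must be unique")
    if (is.unsorted(-object@correlations))
        msgs <- c(msgs, "correlations must be non-increasing")
    if (length(msgs)) msgs else TRUE
})

#' KdeModel: Gaussian kernel density model of a pathway's observed scores
#'
#' A Gaussian mixture with one component per observed enrichment score and a
#' single bandwidth chosen by the Silverman rule of thumb. Its survival
#' function evaluated at a gene's enrichment score is the percentile
#' (p-)score.
#'
#' @slot setId the pathway this model belongs to
#' @slot centers observed enrichment scores (mixture centers)
#' @slot bandwidth the common kernel standard deviation, > 0
#' @seealso [fitKde()], [pScore()]
#' @export
setClass("KdeModel",
    slots = c(
        setId = "character",
        centers = "numeric",
        bandwidth = "numeric"
    )
)

setValidity("KdeModel", function(object) {
    msgs <- character()
    if (length(object@bandwidth) != 1L || !is.finite(object@bandwidth) ||
        object@bandwidth <= 0)
        msgs <- c(msgs, "bandwidth must be a single positive number")
    if (length(object@centers) < 2L)
        msgs <- c(msgs, "at least two observed values are required")
    if (anyNA(object@centers))
        msgs <- c(msgs, "centers must not contain missing values")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticDataset: a simulated expression corpus with planted pathways
#'
#' The raw expression matrix produced by [simulateDataset()], the ground-truth
#' pathway collection (one gene set per planted correlated block), and an echo
#' of the simulation configuration (including the seed).
#'
#' @slot expression a [CoexMatrix-class] at stage `"raw"`
#' @slot truth a [PathwaySet-class] of the planted blocks
#' @slot config named list echoing the simulation parameters
#' @seealso [simulateDataset()], [plantedTruthLabels()]
#' @export
setClass("SyntheticDataset",
    slots = c(
        expression = "CoexMatrix",
        truth = "PathwaySet",
        config = "list"
    )
)
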