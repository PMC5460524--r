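#' Collect per-pathway observed enrichment-score distributions
#'
#' Groups a corpus-wide enrichment-score table (one row per gene-pathway
#' pair, as produced by [gseaCorpus()]) into one observed distribution per
#' pathway. Every gene of the corpus contributes to every pathway's
#' distribution — including the pathway's own members and genes with negative
#' scores — so the table must be a complete gene x pathway grid.
#'
#' @param esTable data.frame with columns `gene_id`, `set_id`, `ES`
#' @return named list (by `set_id`) of numeric vectors of observed scores
#' @export
collectEsDistribution <- function(esTable) {
    need <- c("gene_id", "set_id", "ES")
    if (!all(need %in% names(esTable)))
        stop("esTable must have columns gene_id, set_id, ES")
    tab <- table(esTable$gene_id, esTable$set_id)
    if (any(tab != 1L)) {
        bad <- which(tab != 1L, arr.ind = TRUE)
        gaps <- paste(rownames(tab)[bad[, 1L]], colnames(tab)[bad[, 2L]],
                      sep = "/")
        stop("esTable is not a complete gene x pathway grid; ",
             "missing or duplicated pair(s): ",
             paste(utils::head(gaps, 10L), collapse = ", "),
             if (length(gaps) > 10L) ", ..." else "")
    }
    split(esTable$ES, esTable$set_id)
}

#' Fit a Gaussian kernel density model to observed enrichment scores
#'
#' One Gaussian component is centred on each observed score; the common
#' bandwidth follows the Silverman rule of thumb
#' h = 0.9 min(sd, IQR/1.34) N^(-1/5) with type-7 quartiles — the default of
#' R's [stats::density()] (`bw.nrd0`), including its fallbacks when the IQR
#' is zero. A distribution of identical values has no bandwidth and is an
#' error; callers may fall back to an empirical-CDF percentile in that case.
#'
#' @param esValues numeric vector of observed enrichment scores (>= 2
#'   distinct values)
#' @param setId optional pathway id recorded in the model
#' @return a [KdeModel-class]
#' @export
fitKde <- function(esValues, setId = NA_character_) {
    esValues <- as.numeric(esValues)
    if (length(esValues) < 2L)
        stop("at least two observed values are required")
    if (length(unique(esValues)) < 2L)
        stop("all observed values are identical: bandwidth would be zero")
    h <- stats::bw.nrd0(esValues)
    if (!is.finite(h) || h <= 0)
        stop("degenerate bandwidth for set '", setId, "'")
    new("KdeModel", setId = as.character(setId), centers = esValues,
        bandwidth = h)
}

#' Accessors for KdeModel
#'
#' @param x a [KdeModel-class]
#' @return `kdeCenters()` the observed scores; `kdeBandwidth()` the Silverman
#'   bandwidth.
#' @name kde-accessors
NULL

#' @rdname kde-accessors
#' @export
kdeCenters <- function(x) x@centers

#' @rdname kde-accessors
#' @export
kdeBandwidth <- function(x) x@bandwidth

setMethod("show", "KdeModel", function(object) {
    cat(sprintf("KdeModel%s: %d centers, bandwidth %.5g\n",
                if (is.na(object@setId)) "" else paste0(" [", object@setId, "]"),
                length(object@centers), object@bandwidth))
    invisible(NULL)
})

#' Percentile (p-)score of an enrichment score
#'
#' The survival probability Pr(ES >= es) under the pathway's observed-score
#' density model: because the model is a Gaussian mixture, the survival
#' function is available in closed form as the mean of the component normal
#' survival functions — no numerical integration. A gene whose score sits
#' high in the pathway's own observed distribution gets a small p-score,
#' regardless of how inflated that distribution is by the pathway's internal
#' correlation; this is what makes p-scores comparable across pathways.
#'
#' @param model a [KdeModel-class]
#' @param es enrichment score(s) at which to evaluate, vectorized
#' @return p-score(s) in (0, 1), strictly decreasing in `es`
#' @export
pScore <- function(model, es) {
    stopifnot(is(model, "KdeModel"))
    vapply(es, function(e) {
        mean(stats::pnorm(e, mean = model@centers, sd = model@bandwidth,
                          lower.tail = FALSE))
    }, numeric(1L))
}
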