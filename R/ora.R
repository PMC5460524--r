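#' One-sided Fisher's exact p-value for over-representation
#'
#' Upper-tail (enrichment) probability of the 2x2 table that cross-classifies
#' a background of `nBg` genes by pathway membership (`K` members) and
#' selection (`nSel` selected genes, `k` of them members):
#' p = P(X >= k) with X hypergeometric, i.e. the one-sided Fisher's exact
#' test in the "greater" direction.
#'
#' @param k overlap between the selection and the pathway
#' @param K pathway size within the background
#' @param nSel number of selected genes
#' @param nBg background size
#' @return p-value in (0, 1]
#' @examples
#' fisherGreaterPvalue(k = 5, K = 5, nSel = 5, nBg = 20)  # 1 / choose(20, 5)
#' @export
fisherGreaterPvalue <- function(k, K, nSel, nBg) {
    if (any(c(k, K, nSel, nBg) < 0) || any(c(k, K, nSel, nBg) %% 1 != 0))
        stop("all table entries must be non-negative integers")
    if (K > nBg || nSel > nBg)
        stop("K and nSel must not exceed the background size nBg")
    if (k > min(K, nSel))
        stop("overlap k cannot exceed min(K, nSel)")
    if (k == 0) return(1)
    stats::phyper(k - 1, K, nBg - K, nSel, lower.tail = FALSE)
}

#' Over-representation profile of a ranked gene list
#'
#' For every pathway and every selection threshold N, tests whether the
#' pathway is over-represented among the top N genes of the ranked list via
#' [fisherGreaterPvalue()]. The background is the n genes of the ranked list
#' itself (the target gene is excluded by construction), and the target is
#' likewise excluded from pathway membership counts so the 2x2 margins stay
#' consistent.
#'
#' @param ranked a [RankedGeneList-class]
#' @param pathways a [PathwaySet-class], already size-filtered against the
#'   correlation-matrix universe
#' @param thresholds integer vector of selection sizes; the defaults scan
#'   from the strongly co-expressed neighbourhood (100) to a broad one (3000)
#' @return data.frame with columns `set_id`, `threshold`, `k` (overlap),
#'   `K` (effective pathway size), `p_value`
#' @export
oraProfile <- function(ranked, pathways,
                       thresholds = c(100L, 500L, 1000L, 1500L, 2000L,
                                      2500L, 3000L)) {
    stopifnot(is(ranked, "RankedGeneList"), is(pathways, "PathwaySet"))
    genes <- ranked@genes
    n <- length(genes)
    thresholds <- as.integer(thresholds)
    if (any(thresholds < 1L) || any(thresholds > n))
        stop("thresholds must lie in [1, ", n, "] (the ranked-list length)")
    ids <- pathwayIds(pathways)
    res <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        members <- setdiff(pathways@sets[[i]], ranked@target)
        inSet <- genes %in% members
        K <- sum(inSet)
        hitsAt <- cumsum(inSet)
        k <- hitsAt[thresholds]
        p <- vapply(seq_along(thresholds), function(j) {
            fisherGreaterPvalue(k[j], K, thresholds[j], n)
        }, numeric(1L))
        res[[i]] <- data.frame(
            set_id = ids[i], threshold = thresholds, k = k, K = K,
            p_value = p, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
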