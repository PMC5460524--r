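#' Unweighted GSEA enrichment score
#'
#' Walks the ranked list accumulating +1/m at each of the m pathway members
#' and -1/(n-m) at each non-member; the enrichment score is the signed
#' maximum deviation of this running sum from zero. Internally the running
#' sum is rescaled by m(n-m) (member step +(n-m), non-member step -m) so
#' every prefix is an exact integer; the final prefix is always 0. The
#' reported position `k_star` is the smallest k at which |prefix| attains its
#' maximum, and when the maximal |prefix| is reached with both signs the
#' positive sign wins (top enrichment is the focus).
#'
#' @param ranked a [RankedGeneList-class] of n genes
#' @param members character vector of pathway member gene ids (the target
#'   gene, if present, is ignored — it is not part of the ranked list)
#' @return list with `m` (effective pathway size), `ES` in \[-1, 1\],
#'   `sign` (+1/-1), `k_star`, and `max_prefix` (the integer rescaled
#'   statistic max_k prefix_k, used as the exact p-value threshold)
#' @examples
#' corr <- diag(4); dimnames(corr) <- rep(list(paste0("g", 1:4)), 2)
#' corr["g1", ] <- corr[, "g1"] <- c(1, .9, .5, .1)
#' rl <- rankedGeneList(corr, "g1")
#' enrichmentScore(rl, c("g2", "g3"))  # top-loaded set: ES = 1
#' @export
enrichmentScore <- function(ranked, members) {
    stopifnot(is(ranked, "RankedGeneList"))
    genes <- ranked@genes
    n <- length(genes)
    hit <- genes %in% setdiff(members, ranked@target)
    m <- sum(hit)
    if (m == 0L || m == n)
        stop("enrichment score undefined: effective pathway size m = ", m,
             " with n = ", n)
    prefix <- cumsum(ifelse(hit, n - m, -m))
    if (prefix[n] != 0L)
        stop("internal error: rescaled running sum does not return to zero")
    amax <- max(abs(prefix))
    kStar <- which(abs(prefix) == amax)[1L]
    sgn <- if (any(prefix == amax)) 1 else -1
    list(
        m = m,
        ES = sgn * amax / (m * (n - m)),
        sign = sgn,
        k_star = as.integer(kStar),
        max_prefix = max(prefix)
    )
}

#' Exact p-value of a positive enrichment score
#'
#' Under the gene-permutation null the m pathway members are placed uniformly
#' at random among the n ranked positions. The p-value is the exact
#' probability that the maximum of the (rescaled) running sum reaches the
#' observed positive enrichment score: p = Pr(max_k prefix_k >= T) with
#' T = round(esPlus * m * (n - m)). It is computed by a lattice-path dynamic
#' programme that counts, in exact big-integer arithmetic, the arrangements
#' whose every prefix stays below T; p = 1 - (that count) / C(n, m).
#'
#' @param n ranked-list length
#' @param m effective pathway size, 1 <= m <= n - 1
#' @param esPlus positive enrichment score in (0, 1]; values <= 0 return
#'   p = 1 (the convention used for non-positive scores)
#' @return exact p-value in (0, 1]
#' @examples
#' exactPositivePvalue(4, 2, 1)    # 1/6: only the top-loaded arrangement
#' exactPositivePvalue(4, 2, 0.5)  # 2/3
#' @export
exactPositivePvalue <- function(n, m, esPlus) {
    n <- as.integer(n)
    m <- as.integer(m)
    if (m < 1L || m > n - 1L)
        stop("m must satisfy 1 <= m <= n - 1")
    if (!is.numeric(esPlus) || length(esPlus) != 1L || !is.finite(esPlus))
        stop("esPlus must be a single finite number")
    if (esPlus > 1)
        stop("esPlus cannot exceed 1")
    if (esPlus <= 0) return(1)
    .dpTailPvalue(n, m, round(esPlus * m * (n - m)))
}

#' GSEA of one ranked list against a pathway collection
#'
#' Computes the enrichment score of every pathway and, for positive scores,
#' its exact gene-permutation p-value ([exactPositivePvalue()]). Pathways
#' with non-positive scores get p = 1: only enrichment at the top of the
#' list (strong positive co-expression) is of interest.
#'
#' @param ranked a [RankedGeneList-class]
#' @param pathways a [PathwaySet-class], size-filtered against the ranked
#'   universe; pathways with no member among the ranked genes are an error
#' @return data.frame with columns `set_id`, `m`, `ES`, `k_star`, `p_value`
#' @export
gseaAllPathways <- function(ranked, pathways) {
    stopifnot(is(ranked, "RankedGeneList"), is(pathways, "PathwaySet"))
    ids <- pathwayIds(pathways)
    n <- length(ranked@genes)
    rows <- lapply(seq_along(ids), function(i) {
        es <- enrichmentScore(ranked, pathways@sets[[i]])
        p <- if (es$ES > 0) {
            .dpTailPvalue(n, es$m, es$max_prefix)
        } else {
            1
        }
        data.frame(set_id = ids[i], m = es$m, ES = es$ES,
                   k_star = es$k_star, p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
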