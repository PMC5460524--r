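#' Internal correlation of a pathway
#'
#' Mean Pearson correlation over all unordered pairs of the pathway's member
#' genes present in the correlation matrix. High internal correlation is the
#' property that inflates enrichment p-values for non-member genes.
#'
#' @param corr gene-gene correlation matrix
#' @param members character vector of member gene ids (>= 2 must be present
#'   in `corr`)
#' @return the mean pairwise correlation, in \[-1, 1\]
#' @export
internalCorrelation <- function(corr, members) {
    present <- intersect(members, rownames(corr))
    if (length(present) < 2L)
        stop("internal correlation needs >= 2 member genes in the matrix")
    sub <- corr[present, present]
    mean(sub[upper.tri(sub)])
}

#' Inflation diagnostic: enrichment significance vs internal correlation
#'
#' For each pathway, averages -log10(p) over the gene-pathway pairs whose
#' gene is NOT a member of the pathway, then correlates that average with the
#' pathway's internal correlation across pathways, separately for each
#' p-value table supplied. A positive correlation means the approach's
#' significance levels are inflated by internal correlation even for
#' unrelated genes.
#'
#' @param pvalueTables named list of data.frames, each with columns
#'   `gene_id`, `set_id`, `p_value` covering all gene-pathway pairs (one
#'   table per approach, e.g. `ora_500`, `gsea`)
#' @param pathways a [PathwaySet-class]
#' @param corr gene-gene correlation matrix
#' @return list with `perPathway` (data.frame: `set_id`,
#'   `internal_correlation`, one `mean_neglog10_p_<approach>` column per
#'   table) and `r` (named numeric: Pearson correlation between internal
#'   correlation and the per-pathway mean for each approach; `NA` when either
#'   variable has zero variance, which is reported rather than silently
#'   propagated)
#' @export
inflationDiagnostic <- function(pvalueTables, pathways, corr) {
    stopifnot(is(pathways, "PathwaySet"), is.list(pvalueTables))
    if (is.null(names(pvalueTables)) || any(names(pvalueTables) == ""))
        stop("pvalueTables must be a named list (one name per approach)")
    ids <- pathwayIds(pathways)
    if (length(ids) < 2L)
        stop("at least two pathways are required (r is undefined otherwise)")
    ic <- vapply(ids, function(id)
        internalCorrelation(corr, pathways@sets[[id]]), numeric(1L))
    per <- data.frame(set_id = ids, internal_correlation = unname(ic),
                      stringsAsFactors = FALSE)
    rs <- numeric(0)
    for (approach in names(pvalueTables)) {
        tab <- pvalueTables[[approach]]
        if (!all(c("gene_id", "set_id", "p_value") %in% names(tab)))
            stop("table '", approach,
                 "' must have columns gene_id, set_id, p_value")
        means <- vapply(ids, function(id) {
            members <- pathways@sets[[id]]
            rows <- tab$set_id == id & !(tab$gene_id %in% members)
            if (!any(rows))
                stop("no non-member pairs for pathway '", id,
                     "' in table '", approach, "'")
            mean(-log10(tab$p_value[rows]))
        }, numeric(1L))
        per[[paste0("mean_neglog10_p_", approach)]] <- unname(means)
        r <- if (stats::sd(ic) == 0 || stats::sd(means) == 0) {
            NA_real_  # explicit undefined marker
        } else {
            stats::cor(ic, means)
        }
        rs[approach] <- r
    }
    list(perPathway = per, r = rs)
}

#' Combined pathway ranking for one gene
#'
#' Orders pathways primarily by increasing over-representation p-value at the
#' top-500 threshold and secondarily by increasing p-score, with the set id
#' as the final lexicographic tie-break. Pathways with no overlap at the ORA
#' threshold share p = 1 and are therefore ordered among themselves by their
#' p-scores — the gap the p-score is designed to fill.
#'
#' @param oraP named numeric vector of ORA p-values (one per pathway)
#' @param pScores named numeric vector of p-scores over the same pathways
#' @return data.frame with columns `set_id`, `ora_p`, `p_score`,
#'   `final_rank` (a permutation of 1..#pathways), ordered by rank
#' @export
combinedPathwayRanking <- function(oraP, pScores) {
    if (is.null(names(oraP)) || is.null(names(pScores)))
        stop("both score vectors must be named by set id")
    if (!setequal(names(oraP), names(pScores)))
        stop("oraP and pScores must cover the same pathways")
    ids <- sort(names(oraP), method = "radix")
    oraP <- oraP[ids]
    pScores <- pScores[ids]
    o <- order(oraP, pScores, ids, method = "radix")
    data.frame(
        set_id = ids[o],
        ora_p = unname(oraP[o]),
        p_score = unname(pScores[o]),
        final_rank = seq_along(ids),
        stringsAsFactors = FALSE
    )
}

#' ROC curve and AUC for gene-pathway predictions
#'
#' Gene-pathway pairs are labelled condition positive when the gene is an
#' annotated member of the pathway, condition negative otherwise. Sweeping a
#' threshold over the scores yields the ROC curve; the AUC is the trapezoidal
#' area, which handles tied scores by counting them half (so uninformative
#' constant scores give AUC 0.5). Two scoring modes are typical: pooled
#' p-values (`orientation = "smaller"`) and per-gene pathway ranks pooled
#' across genes (`orientation = "smaller"`, rank 1 = strongest).
#'
#' @param labels binary (0/1 or logical) vector: 1 = condition positive
#' @param scores numeric vector of the same length
#' @param orientation `"smaller"` when small scores indicate a positive
#'   (p-values, ranks), `"larger"` otherwise
#' @return list with `points` (data.frame `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`
#' @export
rocAuc <- function(labels, scores, orientation = c("smaller", "larger")) {
    orientation <- match.arg(orientation)
    labels <- as.integer(as.logical(labels))
    if (length(labels) != length(scores))
        stop("labels and scores must have the same length")
    if (anyNA(labels) || anyNA(scores))
        stop("labels and scores must not contain missing values")
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present (", nPos, " positives, ",
             nNeg, " negatives)")
    s <- if (orientation == "smaller") -scores else scores
    o <- order(-s)
    s <- s[o]
    lab <- labels[o]
    # collapse tied scores into single thresholds
    last <- c(s[-1L] != s[-length(s)], TRUE)
    tp <- cumsum(lab)[last]
    fp <- cumsum(1L - lab)[last]
    fpr <- c(0, fp / nNeg)
    tpr <- c(0, tp / nPos)
    auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
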