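# corpus-wide drivers: every gene of the correlation matrix in turn becomes
# the target of a ranked list, mirroring how the full compendium is analyzed

.esFromHits <- function(hit) {
    n <- length(hit)
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
    list(m = m, ES = sgn * amax / (m * (n - m)), sign = sgn,
         k_star = as.integer(kStar), max_prefix = max(prefix))
}

#' GSEA over a whole corpus of ranked gene lists
#'
#' Runs unweighted GSEA for every target gene of the correlation matrix (or a
#' subset): each target's ranked list is built, every pathway's enrichment
#' score is computed, and — optionally — the exact gene-permutation p-value
#' for positive scores (non-positive scores get p = 1). Scores for all
#' targets are what the per-pathway observed distributions (and hence
#' p-scores) are built from.
#'
#' @param corr gene-gene correlation matrix from [correlationMatrix()]
#' @param pathways a [PathwaySet-class] filtered against `rownames(corr)`
#' @param targets gene ids to analyze (default: every gene in `corr`)
#' @param exactPvalues compute exact p-values (`TRUE`) or leave `p_value` as
#'   `NA` when only the scores are needed (`FALSE`)
#' @return data.frame with one row per (target gene, pathway): `gene_id`,
#'   `set_id`, `m`, `ES`, `k_star`, `p_value`
#' @export
gseaCorpus <- function(corr, pathways, targets = NULL, exactPvalues = TRUE) {
    stopifnot(is(pathways, "PathwaySet"))
    genes <- rownames(corr)
    if (is.null(targets)) targets <- genes
    if (!all(targets %in% genes))
        stop("unknown target gene(s): ",
             paste(utils::head(setdiff(targets, genes), 5L), collapse = ", "))
    ids <- pathwayIds(pathways)
    nP <- length(ids)
    hitmat <- vapply(pathways@sets, function(s) genes %in% s,
                     logical(length(genes)))
    nT <- length(targets)
    total <- nT * nP
    geneCol <- character(total)
    setCol <- character(total)
    mCol <- integer(total)
    esCol <- numeric(total)
    kCol <- integer(total)
    pCol <- rep(NA_real_, total)
    row <- 0L
    idxAll <- seq_along(genes)
    for (t in targets) {
        ti <- match(t, genes)
        others <- idxAll[-ti]
        r <- corr[ti, ]
        ord <- others[order(-r[others], genes[others], method = "radix")]
        n <- length(ord)
        for (p in seq_len(nP)) {
            es <- .esFromHits(hitmat[ord, p])
            row <- row + 1L
            geneCol[row] <- t
            setCol[row] <- ids[p]
            mCol[row] <- es$m
            esCol[row] <- es$ES
            kCol[row] <- es$k_star
            if (exactPvalues) {
                pCol[row] <- if (es$ES > 0) {
                    .dpTailPvalue(n, es$m, es$max_prefix)
                } else {
                    1
                }
            }
        }
    }
    data.frame(gene_id = geneCol, set_id = setCol, m = mCol, ES = esCol,
               k_star = kCol, p_value = pCol, stringsAsFactors = FALSE)
}

#' ORA over a corpus of ranked gene lists
#'
#' Runs the multi-threshold over-representation profile ([oraProfile()]) for
#' each target gene.
#'
#' @inheritParams gseaCorpus
#' @param thresholds selection sizes passed to [oraProfile()]
#' @return data.frame with columns `gene_id`, `set_id`, `threshold`, `k`,
#'   `K`, `p_value`
#' @export
oraCorpus <- function(corr, pathways, targets = NULL,
                      thresholds = c(100L, 500L, 1000L, 1500L, 2000L,
                                     2500L, 3000L)) {
    stopifnot(is(pathways, "PathwaySet"))
    genes <- rownames(corr)
    if (is.null(targets)) targets <- genes
    rows <- lapply(targets, function(t) {
        prof <- oraProfile(rankedGeneList(corr, t), pathways, thresholds)
        cbind(gene_id = t, prof, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Full co-expression pathway analysis of an expression matrix
#'
#' The end-to-end in-memory analysis: preprocess the expression matrix
#' (quantile normalization then log2 with a pseudo-count, applied as needed
#' for the stage the matrix is at), compute the gene-gene correlation matrix,
#' size-filter the pathway collection against the measured genes, run GSEA
#' for every gene (scores always; exact p-values optionally), fit each
#' pathway's observed-score density model and compute p-scores for every
#' gene-pathway pair, run the multi-threshold ORA for the requested target
#' genes, and assemble each target's combined pathway ranking (ORA p at
#' `rankThreshold`, then p-score, then set id).
#'
#' @param expr a [CoexMatrix-class] at any stage
#' @param pathways a [PathwaySet-class] (unfiltered is fine)
#' @param thresholds ORA selection sizes; must not exceed n = #genes - 1
#' @param rankThreshold the ORA threshold used as the primary key of the
#'   combined ranking (must be one of `thresholds`)
#' @param minSize,maxSize pathway size filter bounds
#' @param pseudoCount offset for [logTransform()]
#' @param targets genes for which ORA and rank tables are produced
#'   (default: all); GSEA scores and p-scores always cover all genes
#' @param gseaPvalues compute exact GSEA p-values for all genes (`TRUE`) or
#'   skip them when only scores/p-scores are needed (`FALSE`)
#' @return list with elements `expression` (logged matrix), `correlation`,
#'   `pathways` (filtered), `gsea`, `ora`, `esDistributions`, `kdeModels`,
#'   `pscores`, `rankTables` (named by target gene), `thresholds`,
#'   `rankThreshold`
#' @export
analyzeCoexpression <- function(expr, pathways,
                                thresholds = c(100L, 500L, 1000L, 1500L,
                                               2000L, 2500L, 3000L),
                                rankThreshold = 500L,
                                minSize = 15L, maxSize = 500L,
                                pseudoCount = 4, targets = NULL,
                                gseaPvalues = TRUE) {
    stopifnot(is(expr, "CoexMatrix"), is(pathways, "PathwaySet"))
    if (!rankThreshold %in% thresholds)
        stop("rankThreshold must be one of the ORA thresholds")
    if (stage(expr) == "raw") expr <- quantileNormalize(expr)
    if (stage(expr) == "normalized")
        expr <- logTransform(expr, pseudoCount = pseudoCount)
    corr <- correlationMatrix(expr)
    universe <- rownames(corr)
    filtered <- filterPathways(pathways, universe, minSize, maxSize)
    if (length(filtered) == 0L)
        stop("no pathway passes the size filter [", minSize, ", ", maxSize,
             "] against the ", length(universe), "-gene universe")
    if (is.null(targets)) targets <- universe

    gsea <- gseaCorpus(corr, filtered, targets = NULL,
                       exactPvalues = gseaPvalues)
    dists <- collectEsDistribution(gsea)
    models <- lapply(names(dists), function(id) fitKde(dists[[id]], id))
    names(models) <- names(dists)
    ps <- unlist(lapply(names(dists), function(id) {
        sel <- gsea$set_id == id
        out <- pScore(models[[id]], gsea$ES[sel])
        names(out) <- gsea$gene_id[sel]
        out
    }), use.names = FALSE)
    pscores <- data.frame(
        gene_id = unlist(lapply(names(dists),
                                function(id) gsea$gene_id[gsea$set_id == id]),
                         use.names = FALSE),
        set_id = rep(names(dists), times = vapply(names(dists), function(id)
            sum(gsea$set_id == id), integer(1L))),
        ES = unlist(lapply(names(dists),
                           function(id) gsea$ES[gsea$set_id == id]),
                    use.names = FALSE),
        p_score = ps, stringsAsFactors = FALSE)

    ora <- oraCorpus(corr, filtered, targets = targets,
                     thresholds = thresholds)

    rankTables <- lapply(targets, function(t) {
        sel <- ora$gene_id == t & ora$threshold == rankThreshold
        oraP <- stats::setNames(ora$p_value[sel], ora$set_id[sel])
        pse <- pscores[pscores$gene_id == t, ]
        pVec <- stats::setNames(pse$p_score, pse$set_id)
        combinedPathwayRanking(oraP, pVec)
    })
    names(rankTables) <- targets

    list(expression = expr, correlation = corr, pathways = filtered,
         gsea = gsea, ora = ora, esDistributions = dists,
         kdeModels = models, pscores = pscores, rankTables = rankTables,
         thresholds = as.integer(thresholds),
         rankThreshold = as.integer(rankThreshold))
}
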