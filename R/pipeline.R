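# end-to-end pipeline over TSV/GMT artifacts, used by the exec/coexpath
# command-line script; all computation lives in the other modules

.fnv1a <- function(s) {
    # 32-bit polynomial rolling hash over the UTF-8 bytes, as a config
    # fingerprint (doubles keep exactness below 2^53, so mod 2^32 is exact)
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 2166136261
    for (b in bytes) h <- (h * 31 + b) %% 4294967296
    sprintf("%08x", as.integer(h %% 2147483648))
}

.configHash <- function(config) {
    # fingerprint the computation, not where its results land
    config <- config[setdiff(names(config), "outDir")]
    canon <- paste(deparse(config[order(names(config))], control = "exact"),
                   collapse = "")
    .fnv1a(canon)
}

.artifactHeader <- function(config) {
    c(sprintf("coexPath %s",
              as.character(utils::packageVersion("coexPath"))),
      sprintf("config_hash %s", .configHash(config)),
      sprintf("seed %s", if (is.null(config$seed)) "NA" else config$seed))
}

.writeTable <- function(df, path, comments) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", comments), con)
    utils::write.table(format(df, digits = 10, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readTable <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

.readMatrixTSV <- function(path) {
    df <- .readTable(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    m
}

.writeMatrixTSV <- function(m, path, comments, idColumn = "gene_id") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", comments), con)
    writeLines(paste(c(idColumn, colnames(m)), collapse = "\t"), con)
    body <- apply(format(m, digits = 10, trim = TRUE), 1L, paste,
                  collapse = "\t")
    writeLines(paste(rownames(m), body, sep = "\t"), con)
    invisible(path)
}

.defaultConfig <- function() {
    list(
        thresholds = c(100L, 500L, 1000L, 1500L, 2000L, 2500L, 3000L),
        rankThreshold = 500L,
        minSize = 15L,
        maxSize = 500L,
        pseudoCount = 4,
        minTotalCounts = 1e6,
        rocModes = c("pvalue", "rank"),
        seed = 1L
    )
}

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML/JSON file holding one) with at
#' least `expression` (TSV path), `geneSets` (GMT path) and `outDir`;
#' optional entries override the defaults: `thresholds`, `rankThreshold`,
#' `minSize`, `maxSize` (pathway size filter), `pseudoCount`,
#' `sampleCounts` (TSV of per-sample total counts: columns `sample_id`,
#' `total_counts`) with `minTotalCounts`, `rocModes` (subset of
#' `"pvalue"`/`"rank"`), `writeRankedLists`, and `seed`. All referenced paths
#' must resolve at validation time, before any computation starts.
#'
#' @param config named list, or path to a YAML (`.yml`/`.yaml`) or JSON
#'   (`.json`) file
#' @return the completed configuration list
#' @export
validateRunConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- if (grepl("\\.ya?ml$", config)) {
            yaml::read_yaml(config)
        } else if (grepl("\\.json$", config)) {
            jsonlite::fromJSON(config, simplifyVector = TRUE)
        } else {
            stop("config file must be .yaml/.yml or .json")
        }
    }
    if (!is.list(config)) stop("config must be a named list or a file path")
    full <- utils::modifyList(.defaultConfig(), config)
    for (field in c("expression", "geneSets", "outDir")) {
        if (is.null(full[[field]]))
            stop("config field '", field, "' is required")
    }
    for (field in c("expression", "geneSets", "sampleCounts")) {
        p <- full[[field]]
        if (!is.null(p) && !file.exists(p))
            stop("config path '", field, "' does not exist: ", p)
    }
    if (!all(full$rocModes %in% c("pvalue", "rank")))
        stop("rocModes must be a subset of c('pvalue', 'rank')")
    if (!full$rankThreshold %in% full$thresholds)
        stop("rankThreshold must be one of thresholds")
    full
}

#' Run the full co-expression pathway pipeline on disk artifacts
#'
#' Reads the expression matrix and gene-set collection named in the
#' configuration, runs [analyzeCoexpression()], and writes every stage
#' artifact to the output directory: the quantile-normalized and logged
#' matrices, the gene-gene correlation matrix, the UPGMA sample dendrogram
#' (Newick), the ORA and GSEA tables, the per-pathway density-model summary,
#' the p-score table, the per-gene pathway rank table, the
#' internal-correlation diagnostics, and ROC/AUC evaluations against the
#' gene-set membership labels. Every TSV carries a `#` header with the tool
#' version, a configuration fingerprint, and the seed, and a rerun with the
#' same configuration rewrites byte-identical files.
#'
#' @param config see [validateRunConfig()]
#' @param quiet suppress per-stage progress messages
#' @return (invisibly) the list returned by [analyzeCoexpression()], plus
#'   `diagnostics`, `roc`, and `outDir`
#' @export
runPipeline <- function(config, quiet = FALSE) {
    config <- validateRunConfig(config)
    say <- function(...) if (!quiet) message("[coexpath] ", ...)
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .artifactHeader(config)
    outfile <- function(name) file.path(config$outDir, name)

    expr <- readExpressionTSV(config$expression, stage = "raw")
    say("expression: ", nrow(expr), " genes x ", ncol(expr), " samples")
    if (!is.null(config$sampleCounts)) {
        ct <- .readTable(config$sampleCounts)
        counts <- stats::setNames(as.numeric(ct$total_counts), ct$sample_id)
        expr <- filterSamplesByDepth(expr, counts, config$minTotalCounts)
        say("depth filter (>= ", config$minTotalCounts, "): ",
            ncol(expr), " samples kept")
    }
    pathways <- readGMT(config$geneSets)
    say("gene sets: ", length(pathways), " read")

    normalized <- quantileNormalize(expr)
    writeExpressionTSV(normalized, outfile("normalized_matrix.tsv"), hdr)
    logged <- logTransform(normalized, pseudoCount = config$pseudoCount)
    writeExpressionTSV(logged, outfile("logged_matrix.tsv"), hdr)
    say("preprocessing done (pseudo-count ", config$pseudoCount, ")")

    res <- analyzeCoexpression(
        logged, pathways, thresholds = config$thresholds,
        rankThreshold = config$rankThreshold, minSize = config$minSize,
        maxSize = config$maxSize, pseudoCount = config$pseudoCount)
    say("pathways after size filter [", config$minSize, ", ",
        config$maxSize, "]: ", length(res$pathways))

    .writeMatrixTSV(res$correlation, outfile("correlation_matrix.tsv"), hdr)
    ape::write.tree(upgmaDendrogram(logged),
                    file = outfile("sample_dendrogram.nwk"))
    if (isTRUE(config$writeRankedLists)) {
        dir.create(outfile("ranked_lists"), showWarnings = FALSE)
        for (g in rownames(res$correlation)) {
            rl <- rankedGeneList(res$correlation, g)
            .writeTable(
                data.frame(gene_id = rankedGenes(rl),
                           correlation = rankedCorrelations(rl)),
                outfile(file.path("ranked_lists", paste0(g, ".tsv"))), hdr)
        }
    }
    .writeTable(res$ora, outfile("ora_results.tsv"), hdr)
    say("ORA: ", nrow(res$ora), " (gene, pathway, threshold) tests")
    .writeTable(res$gsea, outfile("gsea_results.tsv"), hdr)
    say("GSEA: ", nrow(res$gsea), " (gene, pathway) scores")

    kdeSummary <- data.frame(
        set_id = names(res$kdeModels),
        n = vapply(res$kdeModels, function(m) length(kdeCenters(m)),
                   integer(1L)),
        bandwidth = vapply(res$kdeModels, kdeBandwidth, numeric(1L)),
        stringsAsFactors = FALSE)
    .writeTable(kdeSummary, outfile("es_distributions.tsv"), hdr)
    .writeTable(res$pscores, outfile("pscore_table.tsv"), hdr)

    rankTable <- .assembleRankTable(res)
    .writeTable(rankTable, outfile("pathway_rank_table.tsv"), hdr)
    say("rank tables: ", length(res$rankTables), " genes")

    oraRank <- res$ora[res$ora$threshold == config$rankThreshold, ]
    diag <- inflationDiagnostic(
        list(ora = oraRank[, c("gene_id", "set_id", "p_value")],
             gsea = res$gsea[, c("gene_id", "set_id", "p_value")]),
        res$pathways, res$correlation)
    diagDf <- diag$perPathway
    diagDf$r_ora <- diag$r[["ora"]]
    diagDf$r_gsea <- diag$r[["gsea"]]
    .writeTable(diagDf, outfile("diagnostics.tsv"), hdr)

    labels <- .membershipLabels(res$pathways)
    roc <- list()
    if ("pvalue" %in% config$rocModes) {
        key <- paste(oraRank$gene_id, oraRank$set_id)
        roc$pvalue <- rocAuc(labels[key], oraRank$p_value, "smaller")
        .writeTable(roc$pvalue$points, outfile("roc_pvalue.tsv"),
                    c(hdr, sprintf("auc %.10g", roc$pvalue$auc)))
        say("ROC (pooled ORA-", config$rankThreshold, " p): AUC = ",
            round(roc$pvalue$auc, 4))
    }
    if ("rank" %in% config$rocModes) {
        rt <- rankTable
        key <- paste(rt$gene_id, rt$set_id)
        roc$rank <- rocAuc(labels[key], rt$final_rank, "smaller")
        .writeTable(roc$rank$points, outfile("roc_rank.tsv"),
                    c(hdr, sprintf("auc %.10g", roc$rank$auc)))
        say("ROC (pooled pathway ranks): AUC = ", round(roc$rank$auc, 4))
    }

    res$diagnostics <- diag
    res$roc <- roc
    res$outDir <- config$outDir
    invisible(res)
}

# wide per-gene rank table: one ora_p_<N> column per threshold, plus the
# GSEA score, its p-value, the p-score and the combined final rank
.assembleRankTable <- function(res) {
    thr <- res$thresholds
    rows <- lapply(names(res$rankTables), function(g) {
        rt <- res$rankTables[[g]]
        oraG <- res$ora[res$ora$gene_id == g, ]
        wide <- data.frame(gene_id = g, set_id = rt$set_id,
                           stringsAsFactors = FALSE)
        for (N in thr) {
            sub <- oraG[oraG$threshold == N, ]
            wide[[paste0("ora_p_", N)]] <-
                sub$p_value[match(rt$set_id, sub$set_id)]
        }
        gseaG <- res$gsea[res$gsea$gene_id == g, ]
        idx <- match(rt$set_id, gseaG$set_id)
        wide$ES <- gseaG$ES[idx]
        wide$gsea_p <- gseaG$p_value[idx]
        wide$p_score <- rt$p_score
        wide$final_rank <- rt$final_rank
        wide
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# named 0/1 vector over "gene set" keys for every pair in the filtered
# collection's universe
.membershipLabels <- function(pathways) {
    universe <- geneUniverse(pathways)
    ids <- pathwayIds(pathways)
    grid <- expand.grid(gene_id = universe, set_id = ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lab <- integer(nrow(grid))
    for (id in ids) {
        sel <- grid$set_id == id
        lab[sel] <- as.integer(grid$gene_id[sel] %in% pathways@sets[[id]])
    }
    stats::setNames(lab, paste(grid$gene_id, grid$set_id))
}

#' Pooled ROC evaluation of a score table against membership labels
#'
#' Convenience wrapper used by the command line: labels every (gene, pathway)
#' pair by membership in `pathways` and evaluates the given score column
#' pooled across all pairs.
#'
#' @param scoreTable data.frame with `gene_id`, `set_id` and the score column
#' @param pathways a [PathwaySet-class] providing the membership labels
#' @param column score column name (e.g. `"p_value"` or `"final_rank"`)
#' @param orientation passed to [rocAuc()]
#' @return list with `points` and `auc` as in [rocAuc()]
#' @export
evaluateScores <- function(scoreTable, pathways, column = "p_value",
                           orientation = "smaller") {
    if (!column %in% names(scoreTable))
        stop("column '", column, "' not found in the score table")
    lab <- mapply(function(g, s) g %in% pathways@sets[[s]],
                  scoreTable$gene_id, scoreTable$set_id)
    rocAuc(as.integer(lab), scoreTable[[column]], orientation)
}
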