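test_that("depth filter removes exactly the sub-threshold samples in order", {
    x <- toyExpr(nGenes = 5, nSamples = 4)
    counts <- c(s01 = 2e6, s02 = 5e5, s03 = 1e6, s04 = 3e6)
    kept <- filterSamplesByDepth(x, counts, minTotal = 1e6)
    expect_identical(colnames(kept), c("s01", "s03", "s04"))
    expect_identical(stage(kept), "raw")

    # all above threshold: identity
    all_ok <- filterSamplesByDepth(x, counts, minTotal = 1e5)
    expect_identical(exprValues(all_ok), exprValues(x))
    # missing totals and empty survivor set are contract errors
    expect_error(filterSamplesByDepth(x, counts[-2], 1e6), "s02")
    expect_error(filterSamplesByDepth(x, counts, 1e9), "below the depth cutoff")
})

test_that("quantile normalization forces identical column distributions", {
    m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
    qn <- exprValues(quantileNormalize(CoexMatrix(m)))
    expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
    expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

    # tie policy: tied entries share the mean reference over their rank span
    m2 <- matrix(c(1, 1, 2, 3, 4, 5), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
    qn2 <- exprValues(quantileNormalize(CoexMatrix(m2)))
    expect_equal(unname(qn2[, "a"]), c(2.25, 2.25, 3.5))
    expect_equal(unname(qn2[, "b"]), c(2, 2.5, 3.5))

    # identical columns are unchanged
    m3 <- matrix(c(5, 1, 9, 5, 1, 9), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
    expect_equal(exprValues(quantileNormalize(CoexMatrix(m3))), m3)
    expect_error(quantileNormalize(CoexMatrix(m[, 1, drop = FALSE])),
                 "two samples")
})

test_that("quantile-normalized columns are permutations of one another", {
    x <- toyExpr(nGenes = 25, nSamples = 7, seed = 11)
    qn <- exprValues(quantileNormalize(x))
    ref <- unname(sort(qn[, 1]))
    for (j in 2:ncol(qn)) expect_equal(unname(sort(qn[, j])), ref)
    expect_identical(stage(quantileNormalize(x)), "normalized")
})

test_that("log transform applies log2(x + pseudo-count)", {
    m <- matrix(c(0, 4, 60, 0, 4, 60), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
    x <- CoexMatrix(m, stage = "normalized")
    lg <- logTransform(x)
    expect_equal(unname(exprValues(lg)[, 1]), c(2, 3, 6))
    expect_identical(stage(lg), "logged")
    expect_warning(logTransform(CoexMatrix(m, stage = "raw")), "raw")
    expect_error(logTransform(x, pseudoCount = 0), "positive")
})

test_that("correlation matrix matches a two-pass Pearson computation", {
    # hand-computed example
    m <- matrix(c(1, 1, 2, 2, 3, 4), 2, 3,
                dimnames = list(c("g1", "g2"), c("a", "b", "c")))
    corr <- correlationMatrix(CoexMatrix(m, stage = "logged"))
    expect_equal(corr["g1", "g2"], 0.981980506, tolerance = 1e-8)

    # anti-correlated profiles
    m2 <- rbind(g1 = c(1, 2, 3), g2 = c(6, 4, 2))
    colnames(m2) <- c("a", "b", "c")
    expect_equal(correlationMatrix(CoexMatrix(m2, stage = "logged"))["g1", "g2"], -1)

    # brute-force two-pass oracle on random matrices
    set.seed(5)
    for (rep in 1:3) {
        vals <- matrix(rnorm(20 * 10), 20, 10,
                       dimnames = list(sprintf("g%02d", 1:20),
                                       sprintf("s%02d", 1:10)))
        got <- correlationMatrix(CoexMatrix(abs(vals), stage = "logged"))
        brute <- matrix(1, 20, 20)
        for (i in 1:20) for (j in 1:20) {
            a <- abs(vals)[i, ]; b <- abs(vals)[j, ]
            brute[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
                sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
        }
        expect_equal(unname(got), brute, tolerance = 1e-10)
        expect_equal(got, t(got))
        expect_equal(unname(diag(got)), rep(1, 20))
    }
    # zero-variance genes are a named error, not silent NaN
    m3 <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))
    colnames(m3) <- c("a", "b", "c")
    expect_error(correlationMatrix(CoexMatrix(m3, stage = "logged")), "g1")
    expect_error(correlationMatrix(CoexMatrix(m2[, 1:2], stage = "logged")),
                 "three samples")
})

test_that("ranked gene lists order by decreasing r with lexicographic ties", {
    corr <- toyCorr(c(0.9, 0.1, 0.5))
    rl <- rankedGeneList(corr, "g1")
    expect_identical(rankedGenes(rl), c("g2", "g4", "g3"))
    expect_identical(targetGene(rl), "g1")
    expect_equal(rankedCorrelations(rl), c(0.9, 0.5, 0.1))

    tie <- toyCorr(c(0.5, 0.5, 0.1))
    expect_identical(rankedGenes(rankedGeneList(tie, "g1"))[1:2],
                     c("g2", "g3"))
    expect_error(rankedGeneList(corr, "nope"), "not present")
})

test_that("ranked list is a bijection onto the other genes, non-increasing", {
    set.seed(9)
    x <- toyExpr(nGenes = 15, nSamples = 8, seed = 21)
    corr <- correlationMatrix(logTransform(quantileNormalize(x)))
    for (g in rownames(corr)) {
        rl <- rankedGeneList(corr, g)
        expect_identical(sort(rankedGenes(rl)),
                         sort(setdiff(rownames(corr), g)))
        expect_false(is.unsorted(-rankedCorrelations(rl)))
        expect_identical(length(rankedGenes(rl)), nrow(corr) - 1L)
    }
})

test_that("UPGMA dendrogram reproduces hand-computed average linkage", {
    # three samples: cophenetic distances must follow UPGMA on d = 1 - cor
    set.seed(2)
    vals <- matrix(rnorm(60), 20, 3,
                   dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
    vals <- abs(vals) + 1
    d <- 1 - cor(vals)
    tree <- upgmaDendrogram(CoexMatrix(vals, stage = "raw"))
    expect_setequal(tree$tip.label, c("a", "b", "c"))
    coph <- ape::cophenetic.phylo(tree)
    pair <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
    first <- rownames(d)[pair]
    other <- setdiff(colnames(d), first)
    expect_equal(coph[first[1], first[2]], min(d[upper.tri(d)]),
                 tolerance = 1e-12)
    expect_equal(coph[first[1], other],
                 mean(d[first, other]), tolerance = 1e-12)

    # identical samples merge at height zero
    dup <- cbind(a = vals[, 1], b = vals[, 1], c = vals[, 2])
    coph2 <- ape::cophenetic.phylo(
        upgmaDendrogram(CoexMatrix(dup, stage = "raw")))
    expect_equal(coph2["a", "b"], 0, tolerance = 1e-12)
})

test_that("expression TSV round-trips through read/write", {
    x <- toyExpr(nGenes = 6, nSamples = 4, seed = 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTSV(x, path, comments = "demo header")
    back <- readExpressionTSV(path)
    expect_equal(exprValues(back), exprValues(x), tolerance = 1e-9)
    expect_identical(stage(back), "raw")
})
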