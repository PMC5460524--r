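test_that("enrichment score follows the running-sum definition on toys", {
    corr <- toyCorr(c(0.9, 0.7, 0.5, 0.1))  # ranked: g2 g3 g4 g5, n = 4
    rl <- rankedGeneList(corr, "g1")

    top <- enrichmentScore(rl, c("g2", "g3"))
    expect_equal(top$ES, 1)
    expect_identical(top$sign, 1)

    bottom <- enrichmentScore(rl, c("g4", "g5"))
    expect_equal(bottom$ES, -1)
    expect_identical(bottom$sign, -1)

    alt <- enrichmentScore(rl, c("g2", "g4"))  # ranks {1, 3}
    expect_equal(alt$ES, 0.5)
    expect_identical(alt$k_star, 1L)
    expect_identical(alt$sign, 1)

    # target gene among the members is ignored; m = 0 or n are undefined
    withT <- enrichmentScore(rl, c("g1", "g2", "g4"))
    expect_identical(withT$m, 2L)
    expect_error(enrichmentScore(rl, "absent"), "m = 0")
    expect_error(enrichmentScore(rl, paste0("g", 2:5)), "m = 4")
})

test_that("the rescaled running sum always returns to zero", {
    set.seed(31)
    x <- toyExpr(nGenes = 30, nSamples = 10, seed = 31)
    corr <- correlationMatrix(logTransform(quantileNormalize(x)))
    genes <- rownames(corr)
    for (rep in 1:20) {
        t <- sample(genes, 1)
        members <- sample(setdiff(genes, t), sample(2:20, 1))
        es <- enrichmentScore(rankedGeneList(corr, t), members)
        expect_true(abs(es$ES) <= 1)
        expect_identical(es$m, length(members))
    }
})

test_that("exact p-values on n=4, m=2 match exhaustive enumeration", {
    expect_equal(exactPositivePvalue(4, 2, 1), 1 / 6)
    expect_equal(exactPositivePvalue(4, 2, 0.5), 2 / 3)
    expect_equal(exactPositivePvalue(4, 2, 1e-9), 1)  # T -> 0: always true
    expect_equal(exactPositivePvalue(10, 3, 0), 1)
    expect_error(exactPositivePvalue(10, 0, 0.5), "m must")
    expect_error(exactPositivePvalue(10, 10, 0.5), "m must")
    expect_error(exactPositivePvalue(10, 3, 1.5), "exceed 1")
})

test_that("the DP p-value is non-increasing in the observed score", {
    for (n in c(10, 25)) {
        for (m in c(2, 5, n %/% 2)) {
            es <- seq(0.05, 1, by = 0.05)
            ps <- vapply(es, function(e) exactPositivePvalue(n, m, e),
                         numeric(1))
            expect_false(is.unsorted(rev(ps)))
            expect_true(all(ps > 0 & ps <= 1))
        }
    }
})

test_that("DP agrees exactly with enumeration on moderate sizes", {
    # spot checks beyond the exhaustive acceptance sweep
    for (case in list(c(9, 4), c(11, 5), c(12, 3))) {
        n <- case[1]; m <- case[2]
        maxima <- enumMaxPrefix(n, m)
        for (T in sort(unique(maxima[maxima > 0]))) {
            expect_equal(exactPositivePvalue(n, m, T / (m * (n - m))),
                         mean(maxima >= T),
                         tolerance = 1e-15,
                         label = sprintf("n=%d m=%d T=%d", n, m, T))
        }
    }
})

test_that("gseaAllPathways applies the negative-score convention", {
    corr <- toyCorr(seq(0.9, 0.1, length.out = 6))
    rl <- rankedGeneList(corr, "g1")
    ranks <- rankedGenes(rl)  # n = 6
    ps <- PathwaySet(list(
        top = ranks[1:2],        # ES = 1 -> p = 1/C(6,2)
        bottom = ranks[5:6],     # ES = -1 -> p = 1
        mid = ranks[c(1, 4)]
    ))
    res <- gseaAllPathways(rl, ps)
    expect_identical(nrow(res), 3L)
    expect_equal(res$p_value[res$set_id == "top"], 1 / choose(6, 2))
    expect_equal(res$ES[res$set_id == "bottom"], -1)
    expect_equal(res$p_value[res$set_id == "bottom"], 1)
    expect_true(all(res$p_value[res$ES <= 0] == 1))
})

test_that("the corpus GSEA driver matches the per-list function", {
    x <- toyExpr(nGenes = 15, nSamples = 8, seed = 8)
    corr <- correlationMatrix(logTransform(quantileNormalize(x)))
    genes <- rownames(corr)
    ps <- filterPathways(PathwaySet(list(A = genes[1:5], B = genes[6:11])),
                         genes, minSize = 2, maxSize = 50)
    corpus <- gseaCorpus(corr, ps)
    expect_identical(nrow(corpus), 15L * 2L)
    for (t in genes[c(1, 7, 15)]) {
        single <- gseaAllPathways(rankedGeneList(corr, t), ps)
        sub <- corpus[corpus$gene_id == t, names(single)]
        rownames(sub) <- NULL
        expect_equal(sub, single)
    }
})
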