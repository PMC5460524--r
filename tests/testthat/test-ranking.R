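test_that("internal correlation averages all unordered member pairs", {
    corr <- diag(4)
    dimnames(corr) <- rep(list(paste0("g", 1:4)), 2)
    corr["g1", "g2"] <- corr["g2", "g1"] <- 0.6
    corr["g1", "g3"] <- corr["g3", "g1"] <- 0.2
    corr["g2", "g3"] <- corr["g3", "g2"] <- 0.1
    expect_equal(internalCorrelation(corr, c("g1", "g2", "g3")), 0.3)
    expect_equal(internalCorrelation(corr, c("g1", "g2")), 0.6)
    expect_error(internalCorrelation(corr, "g1"), ">= 2")

    perfect <- matrix(1, 3, 3, dimnames = rep(list(paste0("g", 1:3)), 2))
    expect_equal(internalCorrelation(perfect, paste0("g", 1:3)), 1)
})

test_that("inflation diagnostic correlates significance with cohesion", {
    corr <- diag(6)
    ids <- paste0("g", 1:6)
    dimnames(corr) <- list(ids, ids)
    corr[1:2, 1:2] <- 0.8; corr[3:4, 3:4] <- 0.1; diag(corr) <- 1
    corr <- (corr + t(corr)) / 2
    ps <- PathwaySet(list(hi = c("g1", "g2"), lo = c("g3", "g4")))
    tab <- expand.grid(gene_id = ids, set_id = c("hi", "lo"),
                       stringsAsFactors = FALSE)
    tab$p_value <- ifelse(tab$set_id == "hi", 0.01, 0.1)
    out <- inflationDiagnostic(list(demo = tab), ps, corr)
    # two points: (0.8, 2) and (0.1, 1) -> r = 1
    expect_equal(unname(out$r["demo"]), 1)
    expect_equal(sort(out$perPathway$mean_neglog10_p_demo), c(1, 2))

    # all p = 1 -> zero variance -> undefined marker, never silent NaN
    tab$p_value <- 1
    out2 <- inflationDiagnostic(list(demo = tab), ps, corr)
    expect_true(is.na(out2$r["demo"]))
    expect_equal(out2$perPathway$mean_neglog10_p_demo, c(0, 0))
})

test_that("combined ranking sorts by ORA p, then p-score, then id", {
    oraP <- c(A = 0.01, B = 1, C = 1)
    psc <- c(A = 0.9, B = 0.1, C = 0.2)
    rt <- combinedPathwayRanking(oraP, psc)
    expect_identical(rt$set_id, c("A", "B", "C"))
    expect_identical(rt$final_rank, 1:3)

    # all-equal scores fall back to lexicographic ids
    same <- combinedPathwayRanking(c(B = 1, A = 1, C = 1),
                                   c(B = .5, A = .5, C = .5))
    expect_identical(same$set_id, c("A", "B", "C"))

    # permutation invariance of the input order
    perm <- combinedPathwayRanking(oraP[c(3, 1, 2)], psc[c(2, 3, 1)])
    expect_identical(perm, rt)
    expect_error(combinedPathwayRanking(oraP, psc[1:2]), "same pathways")
})

test_that("trapezoidal AUC matches hand-derived cases and handles ties", {
    roc <- rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1),
                  orientation = "larger")
    expect_equal(roc$auc, 3 / 4)
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(utils::tail(roc$points$tpr, 1), 1)

    # perfect separation, both orientations
    expect_equal(rocAuc(c(1, 1, 0, 0), c(1, 2, 3, 4), "smaller")$auc, 1)
    expect_equal(rocAuc(c(1, 1, 0, 0), c(4, 3, 2, 1), "larger")$auc, 1)
    # constant scores are uninformative
    expect_equal(rocAuc(c(1, 0, 1, 0), rep(2, 4), "smaller")$auc, 0.5)
    expect_error(rocAuc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise formulation", {
    set.seed(123)
    for (rep in 1:200) {
        n <- sample(4:30, 1)
        labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes present
        scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
        orient <- sample(c("smaller", "larger"), 1)
        expect_equal(rocAuc(labels, scores, orient)$auc,
                     mannWhitneyAuc(labels, scores, orient),
                     tolerance = 1e-12)
    }
})

test_that("AUC agrees with an independent ROC implementation", {
    set.seed(55)
    labels <- rbinom(60, 1, 0.3)
    labels[1:2] <- c(0, 1)
    scores <- runif(60)
    got <- rocAuc(labels, scores, orientation = "larger")$auc
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
})
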