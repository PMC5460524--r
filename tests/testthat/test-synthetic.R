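test_that("simulation is deterministic and leaves the global RNG alone", {
    cfg <- list(nGenes = 50, nSamples = 12, pathwaySizes = c(8, 8),
                pathwayRho = c(0.7, 0.2))
    a <- simulateDataset(cfg$nGenes, cfg$nSamples, cfg$pathwaySizes,
                         cfg$pathwayRho, seed = 5)
    b <- simulateDataset(cfg$nGenes, cfg$nSamples, cfg$pathwaySizes,
                         cfg$pathwayRho, seed = 5)
    expect_identical(exprValues(syntheticExpression(a)),
                     exprValues(syntheticExpression(b)))
    expect_identical(pathwayMembers(syntheticTruth(a)),
                     pathwayMembers(syntheticTruth(b)))
    c <- simulateDataset(cfg$nGenes, cfg$nSamples, cfg$pathwaySizes,
                         cfg$pathwayRho, seed = 6)
    expect_false(identical(exprValues(syntheticExpression(a)),
                           exprValues(syntheticExpression(c))))

    set.seed(1); before <- rnorm(3)
    set.seed(1); invisible(simulateDataset(10, 5, seed = 99)); after <- rnorm(3)
    expect_identical(before, after)
})

test_that("planted blocks are disjoint, sized and non-negative as configured", {
    ds <- simulateDataset(100, 15, pathwaySizes = c(10, 20),
                          pathwayRho = c(0.5, 0.3), seed = 2)
    truth <- syntheticTruth(ds)
    expect_identical(unname(pathwaySizes(truth)), c(10L, 20L))
    expect_identical(anyDuplicated(unlist(pathwayMembers(truth))), 0L)
    vals <- exprValues(syntheticExpression(ds))
    expect_true(all(vals >= 0))
    expect_identical(dim(vals), c(100L, 15L))
    expect_identical(stage(syntheticExpression(ds)), "raw")

    expect_error(simulateDataset(10, 5, pathwaySizes = 11, pathwayRho = 0.5,
                                 seed = 1), "exceed")
    expect_error(simulateDataset(10, 5, pathwaySizes = 5, pathwayRho = 1,
                                 seed = 1), "\\[0, 1\\)")
    expect_error(simulateDataset(10, 5, pathwaySizes = 5, pathwayRho = 0.1,
                                 backgroundRho = 0.3, seed = 1),
                 "positive semi-definite")
    expect_error(simulateDataset(10, 5), "seed")
})

test_that("empirical within-block correlation tracks the generative rho", {
    # Monte-Carlo check of the generator itself, on its raw output
    ds <- simulateDataset(80, 500, pathwaySizes = c(25, 25),
                          pathwayRho = c(0.7, 0.3), seed = 17)
    corr <- stats::cor(t(exprValues(syntheticExpression(ds))))
    truth <- pathwayMembers(syntheticTruth(ds))
    expect_equal(internalCorrelation(corr, truth$planted01), 0.7,
                 tolerance = 0.05)
    expect_equal(internalCorrelation(corr, truth$planted02), 0.3,
                 tolerance = 0.05)
    # near-unity cohesion survives sampling noise
    hi <- simulateDataset(40, 200, pathwaySizes = 10, pathwayRho = 0.999,
                          seed = 3)
    chi <- stats::cor(t(exprValues(syntheticExpression(hi))))
    expect_gt(internalCorrelation(chi,
                                  pathwayMembers(syntheticTruth(hi))[[1]]),
              0.95)
})

test_that("truth labels enumerate the full gene x pathway grid", {
    ds <- simulateDataset(30, 8, pathwaySizes = c(5, 5),
                          pathwayRho = c(0.5, 0.5), seed = 4)
    lab <- plantedTruthLabels(ds)
    expect_identical(nrow(lab), 30L * 2L)
    expect_identical(sum(lab$label), 10L)
    members <- pathwayMembers(syntheticTruth(ds))$planted01
    expect_true(all(lab$label[lab$set_id == "planted01" &
                              lab$gene_id %in% members] == 1L))
    expect_true(all(lab$label[lab$set_id == "planted01" &
                              !(lab$gene_id %in% members)] == 0L))
})
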