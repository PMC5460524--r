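# independent brute-force oracles and small fixture builders

# distribution of the rescaled max prefix (hit step +(n-m), miss step -m)
# over all C(n, m) placements of the m hits, by exhaustive enumeration
enumMaxPrefix <- function(n, m) {
    placements <- utils::combn(n, m)
    apply(placements, 2L, function(pos) {
        step <- rep(-m, n)
        step[pos] <- n - m
        max(cumsum(step))
    })
}

# one-sided Fisher p by enumerating every selection of size nSel from a
# background of nBg genes whose first K genes form the pathway
enumFisherGreater <- function(k, K, nSel, nBg) {
    sel <- utils::combn(nBg, nSel)
    overlap <- apply(sel, 2L, function(s) sum(s <= K))
    mean(overlap >= k)
}

# Mann-Whitney formulation of the AUC: P(score+ beats score-) + 0.5 P(tie),
# after orienting so that larger means positive
mannWhitneyAuc <- function(labels, scores, orientation = "smaller") {
    s <- if (orientation == "smaller") -scores else scores
    sp <- s[labels == 1]
    sn <- s[labels == 0]
    cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
    mean(cmp)
}

# numerical-integration oracle for the Gaussian-mixture survival function
integrateKdeSurvival <- function(centers, h, at) {
    dens <- function(x)
        vapply(x, function(xi) mean(stats::dnorm(xi, centers, h)), numeric(1))
    stats::integrate(dens, at, Inf, rel.tol = 1e-11)$value
}

# small correlation matrix with a prescribed first row (target "g1")
toyCorr <- function(r1) {
    k <- length(r1) + 1L
    ids <- paste0("g", seq_len(k))
    corr <- diag(k)
    dimnames(corr) <- list(ids, ids)
    corr[1L, -1L] <- r1
    corr[-1L, 1L] <- r1
    corr
}

# tiny CoexMatrix with reproducible random positive values
toyExpr <- function(nGenes = 10, nSamples = 6, seed = 1, stage = "raw") {
    set.seed(seed)
    m <- matrix(stats::runif(nGenes * nSamples, 1, 100), nGenes, nSamples,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    CoexMatrix(m, stage = stage)
}
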