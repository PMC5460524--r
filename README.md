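# coexPath

Pathway prediction from gene co-expression. Given a gene × sample expression
matrix and a collection of gene sets (pathways), **coexPath** ranks, for every
gene, the pathways most likely related to it — using the gene's co-expression
neighbourhood rather than a differential-expression contrast. It is aimed at
researchers building "guilt-by-association" function-prediction resources
from expression compendia (e.g. bulk RNA-seq collections of a plant or other
non-model organism annotated with KEGG-style pathways).

## The method

1. **Preprocessing.** Samples with low sequencing depth (total estimated
   counts below 10⁶) are dropped; the TPM matrix is quantile-normalized and
   transformed by log2(x + 4). Sample structure can be sanity-checked with a
   UPGMA dendrogram (average linkage on 1 − Pearson correlation).
2. **Co-expression.** The gene–gene Pearson correlation matrix is computed,
   and for each target gene *t* all other genes are ordered by decreasing
   correlation, giving a ranked list L_t = {g₁, …, g_n}, r₁ ≥ … ≥ r_n.
3. **ORA.** For each threshold N ∈ {100, 500, 1000, 1500, 2000, 2500, 3000},
   the top-N genes of L_t are tested for over-representation of each pathway
   by the one-sided Fisher's exact test (hypergeometric upper tail), with the
   n ranked genes as background. Pathways with fewer than 15 or more than 500
   measurable genes are excluded.
4. **Unweighted GSEA with exact p-values.** The running sum over L_t steps by
   +1/m at the m pathway members and −1/(n−m) elsewhere; the enrichment score
   ES is its signed maximum deviation. For ES > 0 the gene-permutation
   p-value Pr(ES⁺_null ≥ ES⁺) is computed **exactly** by a lattice-path
   dynamic programme over big integers (no sampling); for ES ≤ 0 the p-value
   is set to 1, since only enrichment at the top of the list is of interest.
5. **Percentile (p-)score.** Pathways with strong *internal correlation*
   (high mean pairwise correlation among their members) get inflated ORA and
   GSEA significance even for unrelated genes. To correct this, each
   pathway's observed ES values across *all* target genes are modelled by a
   Gaussian kernel density (Silverman bandwidth), and a gene's p-score is the
   closed-form survival probability Pr(ES ≥ ES_e) under that model — a
   per-pathway calibration that is comparable across pathways.
6. **Ranking and evaluation.** The default pathway ranking for a gene orders
   by ORA top-500 p-value, then p-score, then pathway id. Gene–pathway pairs
   are labelled condition positive/negative by annotated membership, and
   predictions are evaluated by ROC curves and trapezoidal AUC (pooled
   p-values, or pooled per-gene pathway ranks).

A seeded generator of synthetic corpora with planted co-expressed pathways
(block-exchangeable Gaussian blocks of controlled internal correlation, plus
the matching truth GMT) makes every stage testable without downloads.

## Worked example

```r
library(coexPath)

ds <- simulateDataset(nGenes = 500, nSamples = 60,
                      pathwaySizes = c(25, 25), pathwayRho = c(0.7, 0.2),
                      seed = 11)
res <- analyzeCoexpression(syntheticExpression(ds), syntheticTruth(ds),
                           thresholds = c(100L, 250L), rankThreshold = 250L,
                           targets = "g001", gseaPvalues = TRUE)
res$rankTables[["g001"]]
#>      set_id        ora_p    p_score final_rank
#> 1 planted01 3.507420e-08 0.02716681          1
#> 2 planted02 9.940206e-01 0.77600788          2

res$gsea[res$gsea$gene_id == "g001", ]
#>  gene_id    set_id  m         ES k_star      p_value
#>     g001 planted01 24  1.0000000     24 1.915869e-41
#>     g001 planted02 25 -0.2706329    268 1.000000e+00
```

Gene `g001` belongs to the planted 25-gene block with internal correlation
0.7. Its 24 fellow members occupy the top 24 positions of its ranked list
(ES = 1, exact permutation p = 1.9 × 10⁻⁴¹; ORA top-250 p = 3.5 × 10⁻⁸), and
its p-score 0.027 says that ES sits in the top 2.7% of the pathway's observed
score distribution — so the signal is specific, not an internal-correlation
artifact. The decoy block is correctly rejected (ORA p ≈ 0.99, p-score 0.78).
The same analysis over all 500 genes gives a pooled ORA-250 AUC of 0.955, and
the inflation diagnostic shows the cohesive block inflating non-member GSEA
p-values (mean −log10 p 1.72 vs 0.69 for the loose block) while p-scores stay
calibrated.

A command-line interface wrapping the same functions is installed at
`exec/coexpath` (subcommands `simulate`, `normalize`, `correlate`, `ora`,
`gsea`, `pscore`, `rank`, `evaluate`, `run`); `runPipeline()` /
`coexpath run --config config.yaml` executes every stage and writes all TSV,
GMT and Newick artifacts with versioned, seeded headers.

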