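# splitGSEA

Rank-based gene set enrichment analysis for binary phenotypes, with
**split-averaged test statistics** that increase statistical power, and a
fully self-contained synthetic benchmark.

## The problem and the method

Running-sum gene set enrichment analysis scores a gene set by (1) ranking
all genes by a per-gene association with the phenotype — here the
Mann–Whitney statistic rescaled to `r = 2U/(n_A n_B) − 1 ∈ [−1, 1]` — and
(2) walking the ranked list with a running sum that rises by `|r_i|^p / N_R`
at set members and falls by `1/(N_genes − N_H)` elsewhere (`p = 1` by
default).  The enrichment score **ES** is the signed extremum of that walk,
and its significance comes from a null distribution built by permuting the
phenotype labels.

A peculiarity of this construction is that the permutation null of ES is
almost independent of the number of samples `N`, while the observed
(sampling) distribution narrows as `N` grows.  That opens a route to more
power: split the cohort into two stratified halves `S1`, `S2`, score each
half, and use

    ES_avg = 0.5 (ES1 + ES2)

as the test statistic — its null is markedly narrower (an average of two
roughly independent half-cohort scores), while its observed value keeps
the same location when a real association is present.  `ES_avg` depends on
the arbitrary choice of split, so the package also provides

    <ES_avg> = Σ_splits ES_avg / M

averaged over `M` random splits (default 25), which pins the statistic and
its p-value down to any desired precision.  The known failure mode —
gene sets with exactly balanced up- and down-regulated members, where each
half scores either sign with equal probability — is documented and
exercised by the benchmark.

For whom: anyone running GSEA-style analyses on expression (bulk or
single-cell pseudobulk) or other omics matrices with a two-class
phenotype, who wants more power out of the same cohort, plus a simulation
harness to verify type-I error and power claims without external data.

## Worked example

```r
library(splitGSEA)
set.seed(7)
pe  <- simulateDataset()            # 600 genes, 25 + 25 samples
gs  <- syntheticGeneSets()          # the 21 benchmark sets a-u
res <- runEnrichment(pe, GeneSetCollection(geneSets(gs)[c("a", "b", "h", "k")]),
                     StatisticSpec("ESavgMulti", nSplits = 25),
                     nPerm = 2000)
print(res, digits = 3)
#>   gene_set statistic_kind n_splits size observed p_value  p_label n_perm
#> 1        a     ESavgMulti       25   20   0.1433   0.545   0.5451   2000
#> 2        b     ESavgMulti       25   20   0.7153   0.000 < 0.0005   2000
#> 3        h     ESavgMulti       25   20   0.0381   0.833   0.8332   2000
#> 4        k     ESavgMulti       25   20   0.6899   0.000 < 0.0005   2000
```

Reading the output: `observed` is `<ES_avg>` over 25 random stratified
splits (positive = coherently higher expression in the first phenotype
class).  The control set `a` (no built-in association) is far from
significant; the strongly associated sets `b` and `k` exceed every one of
the 2000 same-sign permutation draws, so their p-values are reported as
the bound `< 0.0005`; the balanced up/down set `h` averages to nearly
zero — the documented pathological case where split averaging loses the
(sign-ambiguous) signal.

Real data go through the same API: `readDataset("expr.gct", "pheno.cls")`
and `readGeneSets("hallmarks.gmt")`, then `runEnrichment()`.  A
command-line wrapper with `enrich`, `simulate`, `null`, `power` and
`benchmark` subcommands lives at `inst/scripts/splitgsea.R`.

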