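# Stratified splitting and the split-averaged statistics.

test_that("stratifiedSplit stratifies, covers the cohort and is deterministic", {
    ph4 <- factor(c("A", "A", "B", "B"))
    set.seed(1)
    sp <- stratifiedSplit(ph4)
    expect_setequal(c(sp$S1, sp$S2), 1:4)
    expect_equal(sum(ph4[sp$S1] == "A"), 1L)
    expect_equal(sum(ph4[sp$S1] == "B"), 1L)

    # two odd classes: halves still equal (147 + 147 = 294 -> 147 / 147)
    ph294 <- factor(rep(c("good", "poor"), c(147, 147)))
    set.seed(2)
    sp294 <- stratifiedSplit(ph294)
    expect_equal(length(sp294$S1), 147L)
    expect_equal(length(sp294$S2), 147L)
    expect_lte(abs(sum(ph294[sp294$S1] == "good") -
                   sum(ph294[sp294$S2] == "good")), 1L)

    # unbalanced odd classes: per-class imbalance at most 1
    ph9 <- factor(rep(c("A", "B"), c(5, 4)))
    set.seed(3)
    sp9 <- stratifiedSplit(ph9)
    expect_setequal(c(sp9$S1, sp9$S2), 1:9)
    expect_lte(abs(sum(ph9[sp9$S1] == "A") - sum(ph9[sp9$S2] == "A")), 1L)

    # same RNG state -> identical partition
    set.seed(99); a <- stratifiedSplit(ph294)
    set.seed(99); b <- stratifiedSplit(ph294)
    expect_identical(a, b)

    expect_error(stratifiedSplit(factor(c("A", "B", "B"))), ">= 2 samples")
})

test_that("esAvg averages two independently computed half scores", {
    set.seed(5)
    pe <- simulateDataset(nPerClass = 10)
    gs <- syntheticGeneSets()
    sp <- stratifiedSplit(phenotype(pe))
    got <- esAvg(pe, gs[["b"]], sp)
    # independent recomputation through the plain R core path
    half <- function(ix) {
        d <- PhenotypeExperiment(exprsMatrix(pe)[, ix],
                                 factor(phenotype(pe)[ix],
                                        levels = c("A", "B")))
        esScore(enrichmentScore(rankGenes(d), gs[["b"]], quiet = TRUE))
    }
    expect_equal(got, 0.5 * (half(sp$S1) + half(sp$S2)),
                 tolerance = 1e-12)
    expect_lte(abs(got), 1)
    # trivial identities on the averaging itself
    expect_equal(0.5 * (0.4 + (-0.4)), 0)
    # split referring to unknown samples errors
    expect_error(esAvg(pe, gs[["b"]], list(S1 = 1:10, S2 = 1:10)),
                 "disjoint")
})

test_that("esAvgMulti with M = 1 equals esAvg for the same RNG state", {
    set.seed(17)
    pe <- simulateDataset(nPerClass = 8)
    gs <- syntheticGeneSets()
    set.seed(101)
    v1 <- esAvgMulti(pe, gs[["k"]], M = 1)
    set.seed(101)
    v2 <- esAvg(pe, gs[["k"]])
    expect_identical(v1, v2)
})

test_that("split statistics stay in [-1, 1] and average to a stable location", {
    set.seed(23)
    pe <- simulateDataset(nPerClass = 10)
    gs <- syntheticGeneSets()
    vals <- replicate(20, esAvgMulti(pe, gs[["e"]], M = 2))
    expect_true(all(abs(vals) <= 1))
    # label-symmetric data: statistic near zero in distribution
    m <- exprsMatrix(pe)
    mm <- cbind(m[, 1:10], m[, 1:10])
    colnames(mm) <- paste0("s", seq_len(20))
    sym <- PhenotypeExperiment(mm,
                               factor(rep(c("A", "B"), each = 10),
                                      levels = c("A", "B")))
    vs <- replicate(30, esAvgMulti(sym, gs[["b"]], M = 2))
    expect_lt(abs(mean(vs)), 0.25)
})

test_that("label swap negates the split statistics when halves are tie-free", {
    # rank correlations take few discrete values on small halves, so draw
    # until both half rankings happen to be free of tied r values
    set.seed(29)
    repeat {
        m <- matrix(rnorm(5 * 12), 5, 12,
                    dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
        pe <- PhenotypeExperiment(m, factor(rep(c("A", "B"), each = 6),
                                            levels = c("A", "B")))
        sp <- stratifiedSplit(phenotype(pe))
        set <- rownames(pe)[1:3]
        # antisymmetry needs tie-free rankings and a unique extremum
        # magnitude of the running sum in each half
        clean <- function(ix) {
            d <- PhenotypeExperiment(exprsMatrix(pe)[, ix],
                                     factor(phenotype(pe)[ix],
                                            levels = c("A", "B")))
            rk <- rankGenes(d)
            if (anyDuplicated(rk@r)) return(FALSE)
            prof <- enrichmentScore(rk, set, quiet = TRUE)@values
            abs(max(prof) + min(prof)) > 1e-9
        }
        if (clean(sp$S1) && clean(sp$S2)) break
    }
    sw <- PhenotypeExperiment(exprsMatrix(pe),
                              factor(phenotype(pe), levels = c("B", "A")))
    expect_equal(esAvg(sw, set, sp), -esAvg(pe, set, sp),
                 tolerance = 1e-12)
})

test_that("computeStatistic dispatches on the spec kind", {
    set.seed(37)
    pe <- simulateDataset(nPerClass = 6)
    gs <- syntheticGeneSets()
    esVal <- computeStatistic(pe, gs[["b"]], StatisticSpec("ES"))
    expect_equal(esVal,
                 esScore(enrichmentScore(rankGenes(pe), gs[["b"]],
                                         quiet = TRUE)))
    set.seed(7)
    a <- computeStatistic(pe, gs[["b"]], StatisticSpec("ESavg"))
    set.seed(7)
    b <- esAvg(pe, gs[["b"]])
    expect_identical(a, b)
    set.seed(7)
    d <- computeStatistic(pe, gs[["b"]],
                          StatisticSpec("ESavgMulti", nSplits = 3))
    set.seed(7)
    e <- esAvgMulti(pe, gs[["b"]], M = 3)
    expect_identical(d, e)
})
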