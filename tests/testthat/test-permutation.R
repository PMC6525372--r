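# Phenotype-permutation nulls and empirical p-values.

test_that("pValue follows the sign-matched tail convention", {
    res <- pValue(0.3, c(-0.5, -0.2, 0.1, 0.3, 0.9))
    expect_equal(res$p, 2 / 3)
    expect_equal(res$denominator, 3L)
    expect_false(res$bound)

    # observed exceeding every null value -> reported as a bound
    res2 <- pValue(0.95, c(0.1, 0.2, 0.3, -0.4))
    expect_true(res2$bound)
    expect_equal(res2$p, 0)
    expect_match(res2$label, "^< ")

    # two-sided option
    res3 <- pValue(0.3, c(-0.5, -0.2, 0.1, 0.3, 0.9),
                   alternative = "two-sided")
    expect_equal(res3$p, 3 / 5)

    # zeros count toward both signs
    res4 <- pValue(-0.1, c(0, 0.5, -0.2))
    expect_equal(res4$denominator, 2L)
    expect_equal(res4$p, 1 / 2)

    # empty same-sign tail warns and reports a bound
    expect_warning(res5 <- pValue(0.4, c(-0.1, -0.2)), "< 1/n_perm")
    expect_true(res5$bound)
})

test_that("nullDistribution has the right shape and stays in [-1, 1]", {
    set.seed(43)
    pe <- simulateDataset(nPerClass = 8)
    gs <- syntheticGeneSets()
    nd <- nullDistribution(pe, gs[["b"]], StatisticSpec("ES"), nPerm = 300)
    expect_s4_class(nd, "NullDistribution")
    expect_length(nullValues(nd), 300)
    expect_true(all(abs(nullValues(nd)) <= 1))
    expect_true(validObject(nd))
})

test_that("null mean of ES on a control set matches its sampling mean", {
    set.seed(47)
    gs <- syntheticGeneSets()
    pe <- simulateDataset()
    nd <- nullDistribution(pe, gs[["a"]], StatisticSpec("ES"),
                           nPerm = 2000)
    sampled <- replicate(150, {
        d <- simulateDataset()
        esScore(enrichmentScore(rankGenes(d), gs[["a"]], quiet = TRUE))
    })
    tol <- 3 * sqrt(sd(sampled)^2 / length(sampled) +
                    sd(nullValues(nd))^2 / 2000)
    expect_lt(abs(mean(nullValues(nd)) - mean(sampled)), tol + 0.02)
})

test_that("nullWidthSummary reports widths and degenerate cases", {
    expect_error(nullWidthSummary(rnorm(50)), "at least 100")
    s <- nullWidthSummary(rep(0.1, 200))
    expect_equal(s$sd, 0)
    expect_equal(s$iqr, 0)
    set.seed(53)
    s2 <- nullWidthSummary(runif(5000, -0.5, 0.5))
    expect_gt(s2$sd, 0.2)
    expect_true(is.numeric(s2$nModes))
})

test_that("multi-split averaging removes the multi-peak null structure", {
    set.seed(59)
    pe <- simulateDataset(nPerClass = 25)
    gs <- syntheticGeneSets()
    nd1 <- nullDistribution(pe, gs[["b"]], StatisticSpec("ESavg"),
                            nPerm = 2000)
    nd25 <- nullDistribution(pe, gs[["b"]],
                             StatisticSpec("ESavgMulti", nSplits = 25),
                             nPerm = 500)
    m1 <- nullWidthSummary(nd1)$nModes
    m25 <- nullWidthSummary(nd25)$nModes
    expect_gte(m1, 2)      # single-split null is multi-modal
    expect_lte(m25, m1)    # averaging smooths the structure away
})

test_that("runEnrichment returns a complete result table", {
    set.seed(61)
    pe <- simulateDataset(nPerClass = 8)
    gs <- syntheticGeneSets()
    res <- runEnrichment(pe, GeneSetCollection(geneSets(gs)[c("a", "b")]),
                         StatisticSpec("ES"), nPerm = 200)
    expect_equal(nrow(res), 2L)
    expect_named(res, c("gene_set", "statistic_kind", "n_splits", "size",
                        "observed", "p_value", "p_label", "n_perm"))
    expect_true(all(res$size == 20))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    # strong set b should look far more significant than control a
    expect_lt(res$p_value[res$gene_set == "b"],
              res$p_value[res$gene_set == "a"] + 1e-9)
})

test_that("ES p-values are uniform when the dataset carries no association at all", {
    # the synthetic benchmark embeds truly associated genes, which shifts a
    # control set's competitive ES slightly against the permutation null;
    # with labels reassigned at random that shift vanishes and the p-value
    # machinery must deliver uniform p-values
    set.seed(6022)
    gs <- syntheticGeneSets()
    pv <- numeric(200)
    pos <- logical(200)
    for (i in seq_len(200)) {
        pe <- simulateDataset()
        relab <- PhenotypeExperiment(
            exprsMatrix(pe),
            factor(sample(rep(c("A", "B"), each = 25)), c("A", "B")))
        obs <- computeStatistic(relab, gs[["a"]], StatisticSpec("ES"))
        nul <- nullDistribution(relab, gs[["a"]], StatisticSpec("ES"),
                                nPerm = 150L)
        pv[i] <- pValue(obs, nul)$p
        pos[i] <- obs > 0
    }
    ks <- suppressWarnings(stats::ks.test(pv, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_gt(mean(pos), 0.3)   # signs split roughly evenly
    expect_lt(mean(pos), 0.7)
})
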