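# Rank correlation and running-sum enrichment score.

test_that("scaledMannWhitney matches pair counting and handles edges", {
    expect_equal(scaledMannWhitney(c(3, 4), c(1, 2)), 1.0)
    expect_equal(scaledMannWhitney(c(1, 4), c(2, 3)), 0.0)
    # brute-force derived: only pair (4 > 3), U = 1, 2*1/9 - 1
    expect_equal(scaledMannWhitney(c(1, 2, 4), c(3, 5, 6)), -7 / 9,
                 tolerance = 1e-12)
    expect_equal(oracleMW(c(1, 2, 4), c(3, 5, 6)), -7 / 9)
    expect_error(scaledMannWhitney(numeric(0), 1:3), "degenerate")
    expect_error(scaledMannWhitney(1:3, numeric(0)), "degenerate")
    # mid-rank tie convention
    set.seed(4)
    for (i in 1:50) {
        A <- sample(1:5, sample(2:6, 1), replace = TRUE)
        B <- sample(1:5, sample(2:6, 1), replace = TRUE)
        expect_equal(scaledMannWhitney(A, B), oracleMW(A, B),
                     tolerance = 1e-12)
    }
})

test_that("rankGenes orders by descending correlation with stable ties", {
    m <- matrix(c(2, 3, 0, 1), 1, 4,
                dimnames = list("g1", paste0("s", 1:4)))
    pe <- PhenotypeExperiment(m, factor(c("A", "A", "B", "B"),
                                        c("A", "B")))
    rk <- rankGenes(pe)
    expect_equal(unname(rk@r), 1.0)
    expect_equal(rk@ordering, 1L)

    set.seed(7)
    pe2 <- randomTinyDataset()
    rk2 <- rankGenes(pe2)
    # agrees with gene-by-gene scaledMannWhitney
    ph <- phenotype(pe2)
    x <- exprsMatrix(pe2)
    rManual <- apply(x, 1, function(v)
        scaledMannWhitney(v[ph == "A"], v[ph == "B"]))
    expect_equal(rk2@r, rManual, tolerance = 1e-12)
    expect_equal(rk2@ordering, order(-rk2@r, seq_along(rk2@r)))
})

test_that("swapping phenotype labels negates r and reverses a tie-free ranking", {
    set.seed(11)
    repeat {   # draw until the ranking is tie-free
        pe <- randomTinyDataset()
        rk <- rankGenes(pe)
        if (!anyDuplicated(rk@r)) break
    }
    swapped <- PhenotypeExperiment(
        exprsMatrix(pe), factor(phenotype(pe), levels = c("B", "A")))
    rkSw <- rankGenes(swapped)
    expect_equal(rkSw@r, -rk@r, tolerance = 1e-12)
    expect_equal(rkSw@ordering, rev(rk@ordering))
})

test_that("block-(ii) genes correlate positively with phenotype on average", {
    set.seed(21)
    bl <- syntheticBlocks()
    iiIdx <- which(bl$block == "ii")
    means <- replicate(100, {
        pe <- simulateDataset(nPerClass = 25)
        mean(rankGenes(pe)@r[iiIdx])
    })
    expect_gt(mean(means), 0)
    expect_gt(mean(means), 3 * sd(means) / sqrt(length(means)))
})

test_that("enrichmentScore reproduces hand-computed running sums", {
    r <- c(g1 = 0.8, g2 = 0.5, g3 = -0.5, g4 = -0.8)
    rk <- new("CorrelationRanking", r = r, ordering = 1:4)
    p1 <- enrichmentScore(rk, c("g1", "g2"))
    expect_equal(esScore(p1), 1.0, tolerance = 1e-9)
    expect_equal(p1@values, c(0.8 / 1.3, 1.0, 0.5, 0.0), tolerance = 1e-9)
    expect_equal(p1@NR, 1.3)

    p2 <- enrichmentScore(rk, c("g2", "g4"))
    expect_equal(esScore(p2), -0.8 / 1.3, tolerance = 1e-9)
    expect_equal(p2@values, c(-0.5, -0.5 + 0.5 / 1.3, -0.8 / 1.3, 0),
                 tolerance = 1e-9)
})

test_that("enrichmentScore validates its inputs", {
    r <- c(g1 = 0.5, g2 = -0.5, g3 = 0)
    rk <- new("CorrelationRanking", r = r, ordering = c(1L, 3L, 2L))
    expect_error(enrichmentScore(rk, c("x", "y")), "no members")
    expect_error(enrichmentScore(rk, c("g1", "g2", "g3")), "every gene")
    expect_error(enrichmentScore(rk, "g3", setName = "zeroset"),
                 "N_R = 0.*zeroset|zeroset.*N_R = 0")
    expect_message(enrichmentScore(rk, c("g1", "nope")), "dropped")
})

test_that("running sum ends at zero and |ES| <= 1 on random instances", {
    set.seed(31)
    for (i in 1:100) {
        pe <- randomTinyDataset(ties = i %% 3 == 0)
        rk <- rankGenes(pe)
        setIdx <- randomSubsetIdx(nrow(pe))
        NR <- sum(abs(rk@r[setIdx]))
        if (NR == 0) next
        prof <- enrichmentScore(rk, rownames(pe)[setIdx], quiet = TRUE)
        expect_lt(abs(tail(prof@values, 1)), 1e-9)
        expect_lte(abs(esScore(prof)), 1 + 1e-12)
    }
})

test_that("compiled kernels agree with the R implementations", {
    set.seed(41)
    for (i in 1:40) {
        pe <- randomTinyDataset(ties = i %% 2 == 0)
        kp <- splitGSEA:::.kernelPrep(pe)
        rk <- rankGenes(pe)
        rKernel <- splitGSEA:::.rankCorrKernel(kp$ord, kp$xs, kp$grpA,
                                               rep(1L, ncol(pe)))
        expect_equal(rKernel, unname(rk@r), tolerance = 1e-12)
        setIdx <- randomSubsetIdx(nrow(pe))
        if (sum(abs(rk@r[setIdx])) == 0) next
        esR <- esScore(enrichmentScore(rk, rownames(pe)[setIdx],
                                       quiet = TRUE))
        esK <- splitGSEA:::.esKernel(unname(rk@r),
                                     list(as.integer(setIdx - 1L)), 1)
        expect_equal(drop(esK), esR, tolerance = 1e-12)
    }
})
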