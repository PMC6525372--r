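# Brute-force reference implementations, deliberately independent of the
# package's vectorized R and compiled C++ paths.

# pair-counting Mann-Whitney correlation (ties count 1/2)
oracleMW <- function(A, B) {
    U <- 0
    for (a in A) for (b in B) U <- U + (a > b) + 0.5 * (a == b)
    2 * U / (length(A) * length(B)) - 1
}

# explicit-loop running-sum enrichment score
oracleES <- function(r, setIdx, p = 1) {
    n <- length(r)
    ord <- order(-r, seq_along(r))
    NR <- sum(abs(r[setIdx])^p)
    miss <- 1 / (n - length(setIdx))
    cs <- 0; best <- 0; besta <- -1
    profile <- numeric(n)
    for (k in seq_len(n)) {
        g <- ord[k]
        cs <- if (g %in% setIdx) cs + abs(r[g])^p / NR else cs - miss
        profile[k] <- cs
        if (abs(cs) > besta) {
            besta <- abs(cs)
            best <- cs
        }
    }
    list(es = best, profile = profile)
}

# small random dataset: <= 20 genes, <= 12 samples, optional ties
randomTinyDataset <- function(maxGenes = 20, maxSamples = 12,
                              ties = FALSE) {
    nG <- sample(3:maxGenes, 1)
    nA <- sample(2:(maxSamples %/% 2), 1)
    nB <- sample(2:(maxSamples %/% 2), 1)
    vals <- if (ties) sample(1:4, nG * (nA + nB), replace = TRUE) else
        rnorm(nG * (nA + nB))
    m <- matrix(vals, nG, nA + nB,
                dimnames = list(sprintf("g%02d", seq_len(nG)),
                                sprintf("s%02d", seq_len(nA + nB))))
    PhenotypeExperiment(m, factor(rep(c("A", "B"), c(nA, nB)),
                                  levels = c("A", "B")))
}

randomSubsetIdx <- function(nG) {
    k <- sample(seq_len(nG - 1), 1)
    sort(sample(seq_len(nG), k))
}
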