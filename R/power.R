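# Power and type-I-error estimation: proportion of realizations detecting
# an association at significance level alpha.

#' Stratified random subset of a cohort
#'
#' Draws N samples preserving the cohort's class proportions as closely as
#' possible (largest-remainder rounding of the per-class quotas).  With
#' \code{N} equal to the cohort size the identity subset is returned.
#'
#' @param dataset a \linkS4class{PhenotypeExperiment}.
#' @param N subset size; each class must retain at least 2 samples.
#' @return a \linkS4class{PhenotypeExperiment} with N samples.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset(nPerClass = 10)
#' ncol(drawSubset(pe, 10))
#' @export
drawSubset <- function(dataset, N) {
    stopifnot(is(dataset, "PhenotypeExperiment"))
    total <- ncol(dataset)
    if (N > total) stop("subset size exceeds cohort size")
    if (N == total) return(dataset)
    ph <- phenotype(dataset)
    counts <- table(ph)
    quota <- N * as.numeric(counts) / total
    base <- floor(quota)
    rem <- N - sum(base)
    if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    if (any(base < 2))
        stop("infeasible subset size: a phenotype class would retain ",
             "fewer than 2 samples")
    chosen <- unlist(lapply(seq_along(counts), function(ci) {
        ix <- which(ph == names(counts)[ci])
        sample(ix, base[ci])
    }), use.names = FALSE)
    dataset[, sort(chosen)]
}

# shared engine: observed statistics, nulls and p-values for several gene
# sets and statistic specs on one prepared dataset
.evalOnce <- function(kp, setsIdx, specs, nPerm, alternative) {
    S <- length(setsIdx)
    out <- lapply(specs, function(sp) {
        obs <- drop(.statDraws(kp, setsIdx, sp, 1L, shuffle = FALSE))
        nul <- .statDraws(kp, setsIdx, sp, nPerm, shuffle = TRUE)
        p <- vapply(seq_len(S), function(s)
            pValue(obs[s], nul[, s], alternative = alternative)$p,
            numeric(1))
        list(observed = as.numeric(obs), p = p)
    })
    out
}

.powerTable <- function(pArr, obsArr, setNames, specs, alpha,
                        nRealizations, nPerm) {
    rows <- list()
    for (k in seq_along(specs)) {
        pm <- matrix(pArr[, , k], nrow = dim(pArr)[1])
        prop <- unname(colMeans(pm < alpha))
        rows[[k]] <- data.frame(
            gene_set = setNames,
            statistic_kind = specs[[k]]@kind,
            n_splits = if (specs[[k]]@kind == "ES") 0L else
                if (specs[[k]]@kind == "ESavg") 1L else specs[[k]]@nSplits,
            proportion = as.numeric(prop),
            se = sqrt(prop * (1 - prop) / nRealizations),
            n_realizations = nRealizations,
            alpha = alpha, n_perm = nPerm,
            row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Statistical power on the synthetic benchmark
#'
#' For each realization a fresh synthetic dataset is simulated, the
#' observed statistic and a fresh phenotype-permutation null are computed
#' for every requested gene set and statistic, and the power is the
#' proportion of realizations with \eqn{p < \alpha}.  A binomial standard
#' error accompanies every proportion.
#'
#' @param geneSetNames which of the benchmark sets a-u to evaluate.
#' @param specs list of \linkS4class{StatisticSpec}s evaluated on the same
#'   realizations.
#' @param nRealizations dataset realizations (default 100).
#' @param nPerm permutations per null (default 10000; 1000 is a practical
#'   fast setting).
#' @param alpha significance level (default 0.05).
#' @param nPerClass samples per class in each realization (default 25).
#' @param alternative p-value tail convention.
#' @param returnDetails if TRUE, attach the per-realization p-values and
#'   observed statistics as \code{attr(x, "details")} (arrays of dimension
#'   realizations x sets x specs).
#' @return \code{data.frame} with one row per gene set and statistic:
#'   \code{proportion} of realizations with \eqn{p < \alpha} and its
#'   binomial \code{se}.
#' @examples
#' set.seed(1)
#' estimatePowerSynthetic("b", list(StatisticSpec("ES")),
#'                        nRealizations = 5, nPerm = 50)
#' @export
estimatePowerSynthetic <- function(geneSetNames = c("a", "b"),
                                   specs = list(StatisticSpec("ES")),
                                   nRealizations = 100L, nPerm = 10000L,
                                   alpha = 0.05, nPerClass = 25L,
                                   alternative = c("sign-matched",
                                                   "two-sided"),
                                   returnDetails = FALSE) {
    alternative <- match.arg(alternative)
    if (is(specs, "StatisticSpec")) specs <- list(specs)
    coll <- syntheticGeneSets()
    stopifnot(all(geneSetNames %in% names(coll)))
    sets <- geneSets(coll)[geneSetNames]
    geneIds <- syntheticBlocks()$gene
    idx <- .setsToIdx(sets, geneIds)
    S <- length(sets); K <- length(specs)
    pArr <- array(NA_real_, c(nRealizations, S, K),
                  dimnames = list(NULL, geneSetNames,
                                  vapply(specs, slot, character(1),
                                         "kind")))
    obsArr <- pArr
    for (rz in seq_len(nRealizations)) {
        pe <- simulateDataset(nPerClass)
        kp <- .kernelPrep(pe)
        ev <- .evalOnce(kp, idx, specs, nPerm, alternative)
        for (k in seq_len(K)) {
            pArr[rz, , k] <- ev[[k]]$p
            obsArr[rz, , k] <- ev[[k]]$observed
        }
    }
    res <- .powerTable(pArr, obsArr, geneSetNames, specs, alpha,
                       nRealizations, nPerm)
    if (returnDetails)
        attr(res, "details") <- list(p = pArr, observed = obsArr)
    res
}

#' Statistical power by subsampling a fixed cohort
#'
#' Realizations are stratified random subsets of size N drawn from a fixed
#' cohort (so realizations are correlated for N close to the cohort size).
#' By default a fresh permutation null is generated per realization; with
#' \code{sharedNull = TRUE} one null is precomputed on a single random
#' subset of size N and reused across realizations (the cheaper workflow
#' appropriate for a fixed cohort).
#'
#' @param cohort a \linkS4class{PhenotypeExperiment}.
#' @param geneSet character vector of member gene identifiers.
#' @param spec a \linkS4class{StatisticSpec}.
#' @param N subset size per realization.
#' @param nRealizations number of subsets drawn.
#' @param nPerm permutations per null.
#' @param alpha significance level.
#' @param sharedNull reuse one precomputed null across realizations.
#' @param alternative p-value tail convention.
#' @param returnDetails attach per-realization p-values/observed values.
#' @return one-row-per-run \code{data.frame} as in
#'   \code{\link{estimatePowerSynthetic}}, plus column \code{N}.
#' @export
estimatePowerSubsampling <- function(cohort, geneSet,
                                     spec = StatisticSpec("ES"), N,
                                     nRealizations = 100L, nPerm = 10000L,
                                     alpha = 0.05, sharedNull = FALSE,
                                     alternative = c("sign-matched",
                                                     "two-sided"),
                                     returnDetails = FALSE) {
    alternative <- match.arg(alternative)
    stopifnot(is(cohort, "PhenotypeExperiment"), is(spec, "StatisticSpec"))
    sharedVals <- NULL
    if (sharedNull) {
        sub0 <- drawSubset(cohort, N)
        sharedVals <- nullValues(nullDistribution(sub0, geneSet, spec,
                                                  nPerm = nPerm))
    }
    p <- obs <- numeric(nRealizations)
    for (rz in seq_len(nRealizations)) {
        sub <- drawSubset(cohort, N)
        kp <- .kernelPrep(sub)
        idx <- .setsToIdx(list(set = geneSet), rownames(sub))
        obs[rz] <- drop(.statDraws(kp, idx, spec, 1L, shuffle = FALSE))
        nul <- if (sharedNull) sharedVals else
            drop(.statDraws(kp, idx, spec, nPerm, shuffle = TRUE))
        p[rz] <- pValue(obs[rz], nul, alternative = alternative)$p
    }
    prop <- mean(p < alpha)
    res <- data.frame(
        gene_set = "set", statistic_kind = spec@kind,
        n_splits = if (spec@kind == "ES") 0L else
            if (spec@kind == "ESavg") 1L else spec@nSplits,
        N = N, proportion = prop,
        se = sqrt(prop * (1 - prop) / nRealizations),
        n_realizations = nRealizations, alpha = alpha, n_perm = nPerm,
        row.names = NULL, stringsAsFactors = FALSE)
    if (returnDetails)
        attr(res, "details") <- list(p = p, observed = obs)
    res
}
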