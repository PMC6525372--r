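# Split-averaged statistics: ES_avg over one stratified half-split and
# <ES_avg> averaged over M random splits.

#' Stratified random half-split of a cohort
#'
#' Partitions the samples into two disjoint halves S1 and S2 covering the
#' cohort, dividing each phenotype class as evenly as possible (per-class
#' counts in the two halves differ by at most 1).  When both class counts
#' are odd, the two extra samples are placed on opposite sides -- one random
#' draw decides which side gets which -- so a 25+25 cohort always splits
#' 25/25.  Randomness comes from R's RNG: identical RNG state gives an
#' identical partition.
#'
#' @param phenotype two-level factor of per-sample class labels.
#' @param sampleIds optional identifiers; defaults to indices.
#' @return list with elements \code{S1} and \code{S2} (sample ids/indices).
#' @examples
#' set.seed(1)
#' stratifiedSplit(factor(c("A", "A", "B", "B")))
#' @export
stratifiedSplit <- function(phenotype, sampleIds = seq_along(phenotype)) {
    phenotype <- as.factor(phenotype)
    if (anyNA(phenotype)) stop("phenotype labels contain missing values")
    counts <- table(phenotype)
    if (any(counts < 2L))
        stop("each phenotype class needs >= 2 samples to be split")
    byClass <- split(seq_along(phenotype), phenotype)
    take <- vapply(byClass, function(ix) length(ix) %/% 2L, integer(1))
    odd <- which(vapply(byClass, length, integer(1)) %% 2L == 1L)
    if (length(odd)) {
        # alternate sides for odd classes, first side by one random draw
        odd <- if (length(odd) > 1L) sample(odd) else odd
        side1 <- runif(1) < 0.5
        for (k in seq_along(odd)) {
            if (side1) take[odd[k]] <- take[odd[k]] + 1L
            side1 <- !side1
        }
    }
    s1 <- unlist(lapply(seq_along(byClass), function(ci) {
        ix <- byClass[[ci]]
        sample(ix)[seq_len(take[ci])]
    }), use.names = FALSE)
    s1 <- sort(s1)
    s2 <- setdiff(seq_along(phenotype), s1)
    list(S1 = sampleIds[s1], S2 = sampleIds[s2])
}

#' Split-averaged enrichment score for an explicit split
#'
#' \eqn{ES_{avg} = 0.5 (ES_1 + ES_2)} where \eqn{ES_1}, \eqn{ES_2} are the
#' enrichment scores computed on the two halves of the cohort (each half is
#' ranked and scored independently with \code{\link{rankGenes}} and
#' \code{\link{enrichmentScore}}).
#'
#' @param dataset a \linkS4class{PhenotypeExperiment}.
#' @param geneSet character vector of member gene identifiers.
#' @param split list with \code{S1}, \code{S2} (sample identifiers or
#'   indices), e.g. from \code{\link{stratifiedSplit}}; by default a fresh
#'   stratified split is drawn.
#' @param weightExponent running-sum weight exponent p.
#' @return scalar ES_avg in \eqn{[-1, 1]}.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset(nPerClass = 6)
#' sp <- stratifiedSplit(phenotype(pe))
#' esAvg(pe, syntheticGeneSets()[["b"]], sp)
#' @export
esAvg <- function(dataset, geneSet, split = NULL, weightExponent = 1) {
    stopifnot(is(dataset, "PhenotypeExperiment"))
    kp <- .kernelPrep(dataset)
    sets <- .setsToIdx(list(set = geneSet), rownames(dataset))
    if (is.null(split))
        split <- stratifiedSplit(phenotype(dataset),
                                 sampleIds = colnames(dataset))
    .esAvgOneSplit(dataset, kp, sets, split, weightExponent)
}

# score both halves of an explicit split with the rank/ES kernels
.esAvgOneSplit <- function(dataset, kp, setsIdx, split, weightExponent) {
    stopifnot(is.list(split), all(c("S1", "S2") %in% names(split)))
    toIdx <- function(ids) {
        if (is.character(ids)) ids <- match(ids, colnames(dataset))
        if (anyNA(ids) || any(ids < 1L | ids > ncol(dataset)))
            stop("split refers to unknown samples")
        as.integer(ids)
    }
    i1 <- toIdx(split$S1); i2 <- toIdx(split$S2)
    if (length(intersect(i1, i2)) || length(union(i1, i2)) != ncol(dataset))
        stop("split halves must be disjoint and cover the cohort")
    es1 <- .esOnSubset(kp, setsIdx, i1, weightExponent)
    es2 <- .esOnSubset(kp, setsIdx, i2, weightExponent)
    0.5 * (es1 + es2)
}

.esOnSubset <- function(kp, setsIdx, sampleIdx, weightExponent) {
    sub <- integer(ncol(kp$ord))
    sub[sampleIdx] <- 1L
    r <- .rankCorrKernel(kp$ord, kp$xs, kp$grpA, sub)
    drop(.esKernel(r, setsIdx, weightExponent))
}

#' Multi-split averaged enrichment score
#'
#' \eqn{\langle ES_{avg} \rangle}: the mean of \code{\link{esAvg}} over M
#' independent stratified half-splits drawn from R's RNG.  With M = 1 this
#' is ES_avg for a single random split.  Averaging over more splits narrows
#' the distribution of the statistic over split choices (law of large
#' numbers) without moving its location.
#'
#' @inheritParams esAvg
#' @param M number of random splits (>= 1).
#' @return scalar \eqn{\langle ES_{avg}\rangle} in \eqn{[-1, 1]}.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset(nPerClass = 10)
#' esAvgMulti(pe, syntheticGeneSets()[["b"]], M = 5)
#' @export
esAvgMulti <- function(dataset, geneSet, M = 25L, weightExponent = 1) {
    stopifnot(M >= 1L)
    kp <- .kernelPrep(dataset)
    sets <- .setsToIdx(list(set = geneSet), rownames(dataset))
    ph <- phenotype(dataset)
    vals <- vapply(seq_len(M), function(m)
        .esAvgOneSplit(dataset, kp, sets, stratifiedSplit(ph),
                       weightExponent),
        numeric(1))
    mean(vals)
}

#' Evaluate an enrichment statistic described by a StatisticSpec
#'
#' Dispatches on the statistic kind: whole-cohort ES, single-split ES_avg
#' (one fresh random stratified split), or \eqn{\langle ES_{avg}\rangle}
#' over M fresh splits.
#'
#' @param dataset a \linkS4class{PhenotypeExperiment}.
#' @param geneSet character vector of member identifiers.
#' @param spec a \linkS4class{StatisticSpec}.
#' @return scalar statistic value.
#' @export
computeStatistic <- function(dataset, geneSet, spec = StatisticSpec("ES")) {
    stopifnot(is(spec, "StatisticSpec"))
    validObject(spec)
    if (spec@kind == "ES")
        return(esScore(enrichmentScore(rankGenes(dataset), geneSet,
                                       weightExponent = spec@weightExponent,
                                       quiet = TRUE)))
    M <- if (spec@kind == "ESavg") 1L else spec@nSplits
    esAvgMulti(dataset, geneSet, M = M,
               weightExponent = spec@weightExponent)
}

#' Distribution of the split-averaged statistic over random split draws
#'
#' Evaluates \eqn{\langle ES_{avg}\rangle} with M splits repeatedly, each
#' draw using fresh independent stratified splits while the phenotype
#' labels stay fixed.  The spread of the returned values quantifies how
#' much the statistic depends on the particular splits chosen; it narrows
#' as \eqn{1/\sqrt{M}}-ish while the mean stays put, which is what makes
#' the multi-split statistic well defined in the large-M limit.
#'
#' @inheritParams esAvg
#' @param M number of random splits per draw.
#' @param nDraws number of independent draws.
#' @return numeric vector of \code{nDraws} statistic values.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset(nPerClass = 10)
#' sd(splitDistribution(pe, syntheticGeneSets()[["b"]], M = 2,
#'                      nDraws = 50))
#' @export
splitDistribution <- function(dataset, geneSet, M = 25L, nDraws = 1000L,
                              weightExponent = 1) {
    stopifnot(M >= 1L, nDraws >= 1L)
    kp <- .kernelPrep(dataset)
    sets <- .setsToIdx(list(set = geneSet), rownames(dataset))
    spec <- StatisticSpec("ESavgMulti", nSplits = M,
                          weightExponent = weightExponent)
    as.numeric(.statDraws(kp, sets, spec, nDraws, shuffle = FALSE))
}

# ---- internal kernel plumbing -------------------------------------------

# Precompute per-dataset inputs for the C++ kernels: per-gene sample
# ordering (ascending expression), the correspondingly sorted values (for
# mid-rank tie handling), and 0/1 labels for the positive class.
.kernelPrep <- function(dataset) {
    stopifnot(is(dataset, "PhenotypeExperiment"))
    x <- exprsMatrix(dataset)
    G <- nrow(x)
    ord <- t(apply(x, 1L, order))
    storage.mode(ord) <- "integer"
    xs <- matrix(x[cbind(rep(seq_len(G), times = ncol(x)), as.vector(ord))],
                 nrow = G)
    ph <- phenotype(dataset)
    list(ord = ord, xs = xs,
         grpA = as.integer(ph == levels(ph)[1]))
}

# Map a named list of member-id vectors to 0-based index vectors into the
# dataset's gene list; absent members are dropped (standard GSEA behaviour)
# with a message reporting the count per set.
.setsToIdx <- function(sets, geneIds, quiet = TRUE) {
    out <- lapply(names(sets), function(nm) {
        idx <- match(sets[[nm]], geneIds)
        miss <- sum(is.na(idx))
        if (miss > 0L && !quiet)
            message(miss, " member(s) of ", nm, " not in the dataset")
        idx <- idx[!is.na(idx)]
        if (length(idx) == 0L)
            stop("gene set ", nm, " has no members in the dataset")
        if (length(idx) >= length(geneIds))
            stop("gene set ", nm, " covers every gene in the dataset")
        as.integer(idx - 1L)
    })
    names(out) <- names(sets)
    out
}

# Draws (rows) x sets (columns) of the statistic described by spec.
# shuffle = TRUE permutes labels per draw (null); FALSE keeps them
# (split-sampling distribution; constant rows for kind ES).
.statDraws <- function(kp, setsIdx, spec, nDraws, shuffle) {
    M <- switch(spec@kind, ES = 0L, ESavg = 1L, ESavgMulti = spec@nSplits)
    .statKernel(kp$ord, kp$xs, kp$grpA, setsIdx, spec@weightExponent,
                as.integer(nDraws), M, shuffle)
}
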