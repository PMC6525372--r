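#' Scaled Mann-Whitney rank correlation between two groups
#'
#' The Mann-Whitney U statistic rescaled to \eqn{[-1, 1]}:
#' \deqn{r = 2U/(n_A n_B) - 1,}
#' where \eqn{U} counts pairs \eqn{(a, b)} with \eqn{a > b}, ties counting
#' 1/2 (mid-rank convention).  \eqn{r = +1} iff every value in \code{valuesA}
#' exceeds every value in \code{valuesB}, \eqn{-1} in the opposite case, and
#' 0 when the two groups are stochastically indistinguishable under rank
#' comparison.
#'
#' @param valuesA,valuesB non-empty numeric vectors (e.g. expression of one
#'   gene in the two phenotype classes; A is the positive direction).
#' @return a scalar correlation in \eqn{[-1, 1]}.
#' @examples
#' scaledMannWhitney(c(3, 4), c(1, 2))   # complete separation: +1
#' scaledMannWhitney(c(1, 4), c(2, 3))   # balanced interleaving: 0
#' @export
scaledMannWhitney <- function(valuesA, valuesB) {
    nA <- length(valuesA); nB <- length(valuesB)
    if (nA == 0L || nB == 0L)
        stop("degenerate phenotype: both groups must be non-empty")
    if (anyNA(valuesA) || anyNA(valuesB))
        stop("missing values are not allowed")
    rk <- rank(c(valuesA, valuesB))            # mid-ranks for ties
    U <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2
    2 * U / (nA * nB) - 1
}

#' Rank genes by phenotype correlation
#'
#' Computes the scaled Mann-Whitney correlation between each gene's
#' expression and the binary phenotype (positive r = higher expression in the
#' first phenotype class) and orders genes by descending correlation.  Ties
#' in r are broken by ascending gene index (stable), so reruns are
#' deterministic.
#'
#' @param dataset a \linkS4class{PhenotypeExperiment}.
#' @return a \linkS4class{CorrelationRanking}.
#' @examples
#' pe <- simulateDataset(nPerClass = 5)
#' rk <- rankGenes(pe)
#' head(rk@r)
#' @export
rankGenes <- function(dataset) {
    stopifnot(is(dataset, "PhenotypeExperiment"))
    validObject(dataset)
    x <- exprsMatrix(dataset)
    ph <- phenotype(dataset)
    inA <- ph == levels(ph)[1]
    nA <- sum(inA); nB <- sum(!inA)
    # mid-ranks within each gene across samples, then a rank-sum per class:
    # identical to calling scaledMannWhitney() gene by gene
    rk <- t(apply(x, 1L, rank))
    U <- rowSums(rk[, inA, drop = FALSE]) - nA * (nA + 1) / 2
    r <- 2 * U / (nA * nB) - 1
    names(r) <- rownames(x)
    new("CorrelationRanking", r = r,
        ordering = order(-r, seq_along(r)))
}

#' Weighted running-sum enrichment score
#'
#' Walks the phenotype-ranked gene list: the running sum increases by
#' \eqn{|r_i|^p / N_R} at members of the gene set (with
#' \eqn{N_R = \sum_{i \in set} |r_i|^p}) and decreases by
#' \eqn{1/(N_{genes} - N_H)} at non-members.  The enrichment score is the
#' running-sum value of largest absolute magnitude, keeping its sign; the
#' final value is 0 by construction (hits and misses each sum to one).  The
#' default weight exponent is \eqn{p = 1}.
#'
#' @param ranking a \linkS4class{CorrelationRanking} from
#'   \code{\link{rankGenes}}.
#' @param geneSet character vector of gene identifiers.  Members absent from
#'   the ranking are dropped (their count is reported via a message); the
#'   intersection must be a non-empty proper subset of the ranked genes.
#' @param weightExponent running-sum weight exponent p (default 1).
#' @param setName label used in error messages.
#' @param quiet suppress the dropped-member message.
#' @return a \linkS4class{RunningSumProfile}; extract the score with
#'   \code{\link{esScore}}.
#' @examples
#' r <- c(g1 = 0.8, g2 = 0.5, g3 = -0.5, g4 = -0.8)
#' rk <- new("CorrelationRanking", r = r, ordering = 1:4)
#' esScore(enrichmentScore(rk, c("g1", "g2")))   # 1
#' @export
enrichmentScore <- function(ranking, geneSet, weightExponent = 1,
                            setName = "gene set", quiet = FALSE) {
    stopifnot(is(ranking, "CorrelationRanking"))
    r <- ranking@r
    n <- length(r)
    idx <- match(geneSet, names(r))
    nMissing <- sum(is.na(idx))
    if (nMissing > 0L && !quiet)
        message(nMissing, " member(s) of ", setName,
                " absent from the dataset were dropped")
    idx <- idx[!is.na(idx)]
    nH <- length(idx)
    if (nH == 0L)
        stop(setName, " has no members in the dataset")
    if (nH >= n)
        stop(setName, " covers every gene in the dataset")
    NR <- sum(abs(r[idx])^weightExponent)
    if (NR == 0)
        stop("all in-set correlations are zero for ", setName,
             " (N_R = 0); enrichment score undefined")
    ord <- ranking@ordering
    inSet <- logical(n)
    inSet[idx] <- TRUE
    inSetOrd <- inSet[ord]
    steps <- ifelse(inSetOrd, abs(r[ord])^weightExponent / NR,
                    -1 / (n - nH))
    cs <- cumsum(steps)
    es <- cs[which.max(abs(cs))]
    new("RunningSumProfile", values = cs, es = es, NR = NR,
        NH = as.integer(nH), weightExponent = as.numeric(weightExponent))
}
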