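# Phenotype-permutation null distributions and empirical p-values.

#' Permutation null distribution of an enrichment statistic
#'
#' For each of \code{nPerm} permutations the phenotype labels are shuffled
#' over all samples (class sizes preserved) and the statistic is evaluated
#' exactly as for observed data: for split statistics the shuffled cohort is
#' then split into fresh random stratified halves (M of them for
#' \eqn{\langle ES_{avg}\rangle}), so every permutation draw consumes its
#' own splits.
#'
#' @param dataset a \linkS4class{PhenotypeExperiment}.
#' @param geneSet character vector of member gene identifiers.
#' @param spec a \linkS4class{StatisticSpec}.
#' @param nPerm number of permutations (default 10000).
#' @return a \linkS4class{NullDistribution}.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset(nPerClass = 8)
#' nd <- nullDistribution(pe, syntheticGeneSets()[["b"]],
#'                        StatisticSpec("ES"), nPerm = 200)
#' sd(nullValues(nd))
#' @export
nullDistribution <- function(dataset, geneSet, spec = StatisticSpec("ES"),
                             nPerm = 10000L) {
    stopifnot(nPerm >= 1L, is(spec, "StatisticSpec"))
    validObject(spec)
    kp <- .kernelPrep(dataset)
    sets <- .setsToIdx(list(set = geneSet), rownames(dataset))
    vals <- drop(.statDraws(kp, sets, spec, nPerm, shuffle = TRUE))
    new("NullDistribution", values = as.numeric(vals), spec = spec,
        nPerm = as.integer(nPerm))
}

#' Empirical permutation p-value
#'
#' Default tail convention (\code{"sign-matched"}): the null is restricted
#' to draws with the same sign as the observed statistic (zeros count toward
#' both signs) and \eqn{p} is the fraction of those draws at least as
#' extreme in magnitude.  \code{"two-sided"} instead uses
#' \eqn{\#(|null| \ge |observed|)/n_{perm}}.  When no null draw is at least
#' as extreme the p-value is reported as the bound \code{"< 1/n_perm"}
#' (numeric value 0 with \code{bound = TRUE}).
#'
#' @param observed scalar observed statistic.
#' @param null a \linkS4class{NullDistribution} or numeric vector of null
#'   draws.
#' @param alternative tail convention.
#' @return list with \code{p} (numeric exceedance proportion), \code{bound}
#'   (TRUE when the exceedance count is 0, i.e. p < 1/n_perm),
#'   \code{label} (printable p-value, e.g. \code{"< 0.0001"}),
#'   \code{exceedances} and \code{denominator}.
#' @examples
#' pValue(0.3, c(-0.5, -0.2, 0.1, 0.3, 0.9))$p   # 2/3
#' @export
pValue <- function(observed, null,
                   alternative = c("sign-matched", "two-sided")) {
    alternative <- match.arg(alternative)
    vals <- if (is(null, "NullDistribution")) nullValues(null) else
        as.numeric(null)
    if (length(vals) == 0L) stop("empty null distribution")
    nPerm <- length(vals)
    if (alternative == "two-sided") {
        den <- nPerm
        k <- sum(abs(vals) >= abs(observed))
    } else {
        same <- if (observed >= 0) vals >= 0 else vals <= 0
        den <- sum(same)
        k <- sum(abs(vals[same]) >= abs(observed))
    }
    if (den == 0L) {
        warning("no null draws share the sign of the observed statistic; ",
                "p reported as < 1/n_perm")
        return(list(p = 0, bound = TRUE,
                    label = sprintf("< %g", 1 / nPerm),
                    exceedances = 0L, denominator = 0L))
    }
    p <- k / den
    list(p = p, bound = k == 0L,
         label = if (k == 0L) sprintf("< %g", 1 / nPerm) else
             format(p, digits = 4),
         exceedances = as.integer(k), denominator = as.integer(den))
}

#' Width summary of a null distribution
#'
#' Descriptive statistics for comparing null widths across cohort sizes and
#' statistics: standard deviation, interquartile range, and a fixed-break
#' histogram (plus a crude mode count from a kernel density, useful for
#' seeing the trimodal single-split null relax to unimodal as M grows).
#'
#' @param null a \linkS4class{NullDistribution} with at least 100 draws.
#' @param breaks histogram breaks over \eqn{[-1, 1]}.
#' @return list with \code{sd}, \code{iqr}, \code{hist} and \code{nModes}.
#' @export
nullWidthSummary <- function(null, breaks = seq(-1, 1, by = 0.05)) {
    vals <- if (is(null, "NullDistribution")) nullValues(null) else
        as.numeric(null)
    if (length(vals) < 100L)
        stop("null width summary needs at least 100 permutation draws")
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
    dens <- density(vals, bw = 0.05)
    y <- dens$y
    modes <- sum(diff(sign(diff(y))) == -2)
    list(sd = sd(vals), iqr = IQR(vals), hist = h, nModes = modes)
}

#' Gene set enrichment over a collection
#'
#' Runs the chosen statistic and its phenotype-permutation null for every
#' gene set in a collection and returns a result table.  All sets share the
#' same permutations (per-gene expression ranks are computed once and only
#' re-aggregated per permutation), which is mathematically identical to
#' independent runs per set.
#'
#' @param dataset a \linkS4class{PhenotypeExperiment}.
#' @param collection a \linkS4class{GeneSetCollection} or named list of
#'   member vectors.
#' @param spec a \linkS4class{StatisticSpec}.
#' @param nPerm permutations for the null (default 10000).
#' @param alternative p-value tail convention, see \code{\link{pValue}}.
#' @param minSize,maxSize sets whose intersection with the dataset falls
#'   outside this range are skipped with a message.
#' @return \code{data.frame} with columns \code{gene_set},
#'   \code{statistic_kind}, \code{n_splits}, \code{size}, \code{observed},
#'   \code{p_value}, \code{p_label}, \code{n_perm}.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset(nPerClass = 8)
#' gs <- syntheticGeneSets()
#' runEnrichment(pe, GeneSetCollection(geneSets(gs)[c("a", "b")]),
#'               StatisticSpec("ES"), nPerm = 100)
#' @export
runEnrichment <- function(dataset, collection, spec = StatisticSpec("ES"),
                          nPerm = 10000L,
                          alternative = c("sign-matched", "two-sided"),
                          minSize = 1L, maxSize = Inf) {
    alternative <- match.arg(alternative)
    sets <- if (is(collection, "GeneSetCollection")) geneSets(collection)
            else collection
    geneIds <- rownames(dataset)
    keep <- vapply(sets, function(m) {
        k <- sum(m %in% geneIds)
        k >= max(1L, minSize) && k <= maxSize && k < length(geneIds)
    }, logical(1))
    if (!all(keep))
        message("skipping ", sum(!keep),
                " set(s) outside the allowed size range")
    sets <- sets[keep]
    if (length(sets) == 0L) stop("no usable gene sets")
    kp <- .kernelPrep(dataset)
    idx <- .setsToIdx(sets, geneIds, quiet = FALSE)
    observed <- drop(.statDraws(kp, idx, spec, 1L, shuffle = FALSE))
    nulls <- .statDraws(kp, idx, spec, nPerm, shuffle = TRUE)
    pv <- lapply(seq_along(sets), function(s)
        pValue(observed[s], nulls[, s], alternative = alternative))
    data.frame(
        gene_set = names(sets),
        statistic_kind = spec@kind,
        n_splits = if (spec@kind == "ES") 0L else
            if (spec@kind == "ESavg") 1L else spec@nSplits,
        size = lengths(idx),
        observed = as.numeric(observed),
        p_value = vapply(pv, `[[`, numeric(1), "p"),
        p_label = vapply(pv, `[[`, character(1), "label"),
        n_perm = as.integer(nPerm),
        row.names = NULL, stringsAsFactors = FALSE)
}
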