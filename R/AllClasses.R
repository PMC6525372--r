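#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors DataFrame
#' @importFrom graphics hist
#' @importFrom stats rnorm sd quantile IQR density setNames runif
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom Rcpp sourceCpp
#' @useDynLib splitGSEA, .registration = TRUE
NULL

#' PhenotypeExperiment: expression matrix with a binary phenotype
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding a genes-by-samples expression matrix (assay \code{"exprs"}) and a
#' two-level factor \code{phenotype} in the column data.  The \emph{first}
#' factor level is the positive direction: a gene with higher expression in
#' that class receives a positive rank correlation.
#'
#' Validity requires unique gene and sample identifiers, a complete (no
#' missing values) numeric matrix, and exactly two phenotype classes with at
#' least two samples each.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @aliases PhenotypeExperiment-class
#' @exportClass PhenotypeExperiment
setClass("PhenotypeExperiment",
         contains = "SummarizedExperiment")

.validPhenotypeExperiment <- function(object) {
    msg <- NULL
    m <- SummarizedExperiment::assay(object)
    if (!is.numeric(m))
        msg <- c(msg, "expression assay must be numeric")
    if (anyNA(m))
        msg <- c(msg, "expression matrix contains missing values")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    ph <- object$phenotype
    if (is.null(ph)) {
        msg <- c(msg, "colData must contain a 'phenotype' column")
    } else {
        if (!is.factor(ph))
            msg <- c(msg, "'phenotype' must be a factor")
        else {
            if (nlevels(ph) != 2L)
                msg <- c(msg, sprintf(
                    "phenotype must have exactly 2 classes (found %d)",
                    nlevels(ph)))
            else if (any(table(ph) < 2L))
                msg <- c(msg, "each phenotype class needs >= 2 samples")
            if (anyNA(ph))
                msg <- c(msg, "phenotype labels contain missing values")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("PhenotypeExperiment", .validPhenotypeExperiment)

#' Construct a PhenotypeExperiment
#'
#' @param exprs numeric matrix, genes in rows and samples in columns.  Row
#'   and column names are used as gene and sample identifiers; if absent they
#'   are generated.
#' @param phenotype factor, character or anything coercible to a factor of
#'   length \code{ncol(exprs)} with exactly two levels.  If a character
#'   vector is given, the level order follows first appearance (the first
#'   class observed is the positive direction); pass a factor to control the
#'   order explicitly.
#' @return a \linkS4class{PhenotypeExperiment}.
#' @examples
#' m <- matrix(rnorm(40), nrow = 8,
#'             dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' pe <- PhenotypeExperiment(m, c("A", "A", "A", "B", "B"))
#' phenotype(pe)
#' @export
PhenotypeExperiment <- function(exprs, phenotype) {
    exprs <- as.matrix(exprs)
    if (is.null(rownames(exprs)))
        rownames(exprs) <- sprintf("g%d", seq_len(nrow(exprs)))
    if (is.null(colnames(exprs)))
        colnames(exprs) <- sprintf("s%d", seq_len(ncol(exprs)))
    if (!is.factor(phenotype))
        phenotype <- factor(as.character(phenotype),
                            levels = unique(as.character(phenotype)))
    if (length(phenotype) != ncol(exprs))
        stop("phenotype length (", length(phenotype),
             ") does not match number of samples (", ncol(exprs), ")")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = S4Vectors::DataFrame(phenotype = phenotype,
                                       row.names = colnames(exprs)))
    new("PhenotypeExperiment", se)
}

#' GeneSetCollection: named gene sets
#'
#' A named list of character vectors of gene identifiers, with unique set
#' names and non-empty, de-duplicated member lists.
#'
#' @slot sets named list of character vectors.
#' @slot controls character vector of set names flagged as negative controls
#'   (no phenotype association by construction); may be empty.
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", controls = "character"),
         prototype(sets = list(), controls = character(0)))

setValidity("GeneSetCollection", function(object) {
    msg <- NULL
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || any(names(s) == "") ||
            anyDuplicated(names(s)))
            msg <- c(msg, "gene set names must be present and unique")
        if (!all(vapply(s, is.character, logical(1))))
            msg <- c(msg, "gene set members must be character vectors")
        if (any(lengths(s) == 0L))
            msg <- c(msg, "empty gene sets are not allowed")
        if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
            msg <- c(msg, "gene sets must not contain duplicate members")
    }
    if (!all(object@controls %in% names(s)))
        msg <- c(msg, "control flags refer to unknown set names")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param controls optional character vector naming sets that are negative
#'   controls.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, controls = character(0)) {
    new("GeneSetCollection", sets = sets, controls = controls)
}

#' CorrelationRanking: per-gene phenotype correlations and their ordering
#'
#' @slot r named numeric vector of per-gene scaled Mann-Whitney correlations
#'   in [-1, 1], in input gene order.
#' @slot ordering integer permutation of gene indices sorted by descending
#'   correlation (ties broken by ascending gene index).
#' @aliases CorrelationRanking-class
#' @exportClass CorrelationRanking
setClass("CorrelationRanking",
         representation(r = "numeric", ordering = "integer"))

setValidity("CorrelationRanking", function(object) {
    msg <- NULL
    n <- length(object@r)
    if (length(object@ordering) != n ||
        !identical(sort(object@ordering), seq_len(n)))
        msg <- c(msg, "ordering must be a permutation of gene indices")
    if (any(object@r < -1 - 1e-12 | object@r > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

#' RunningSumProfile: the GSEA running sum and its signed extremum
#'
#' The running sum over the phenotype-ranked gene list increments by
#' \eqn{|r_i|^p / N_R} at gene set members and decrements by
#' \eqn{1/(N_{genes} - N_H)} elsewhere; the enrichment score is the value of
#' largest absolute magnitude (signed).  The final value is 0 by
#' construction.
#'
#' @slot values numeric running-sum values after each ranked gene.
#' @slot es the enrichment score (signed extremum).
#' @slot NR hit normalisation, sum of |r|^p over in-set genes.
#' @slot NH number of set members present in the dataset.
#' @slot weightExponent the weight exponent p (default 1).
#' @aliases RunningSumProfile-class
#' @exportClass RunningSumProfile
setClass("RunningSumProfile",
         representation(values = "numeric", es = "numeric", NR = "numeric",
                        NH = "integer", weightExponent = "numeric"))

#' StatisticSpec: which enrichment statistic to compute
#'
#' @slot kind one of \code{"ES"} (whole-cohort enrichment score),
#'   \code{"ESavg"} (average over one stratified half-split) or
#'   \code{"ESavgMulti"} (further averaged over \code{nSplits} random
#'   half-splits).
#' @slot nSplits number of random splits M (used by \code{"ESavgMulti"};
#'   M = 1 reduces exactly to \code{"ESavg"}).
#' @slot weightExponent running-sum weight exponent p.
#' @aliases StatisticSpec-class
#' @exportClass StatisticSpec
setClass("StatisticSpec",
         representation(kind = "character", nSplits = "integer",
                        weightExponent = "numeric"),
         prototype(kind = "ES", nSplits = 1L, weightExponent = 1))

setValidity("StatisticSpec", function(object) {
    msg <- NULL
    if (!object@kind %in% c("ES", "ESavg", "ESavgMulti"))
        msg <- c(msg, "kind must be ES, ESavg or ESavgMulti")
    if (object@nSplits < 1L)
        msg <- c(msg, "nSplits must be >= 1")
    if (object@weightExponent < 0)
        msg <- c(msg, "weightExponent must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a StatisticSpec
#'
#' @param kind \code{"ES"}, \code{"ESavg"} or \code{"ESavgMulti"}.
#' @param nSplits number of random half-splits M (only for
#'   \code{"ESavgMulti"}).
#' @param weightExponent running-sum weight exponent p; the default 1 weights
#'   hits by |r|.
#' @return a \linkS4class{StatisticSpec}.
#' @examples
#' StatisticSpec("ESavgMulti", nSplits = 25)
#' @export
StatisticSpec <- function(kind = c("ES", "ESavg", "ESavgMulti"),
                          nSplits = 1L, weightExponent = 1) {
    kind <- match.arg(kind)
    new("StatisticSpec", kind = kind, nSplits = as.integer(nSplits),
        weightExponent = as.numeric(weightExponent))
}

#' NullDistribution: permutation draws of an enrichment statistic
#'
#' @slot values numeric vector of the statistic under phenotype permutation.
#' @slot spec the \linkS4class{StatisticSpec} that produced the draws.
#' @slot nPerm number of permutations.
#' @aliases NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution",
         representation(values = "numeric", spec = "StatisticSpec",
                        nPerm = "integer"))

setValidity("NullDistribution", function(object) {
    msg <- NULL
    if (length(object@values) != object@nPerm)
        msg <- c(msg, "length(values) must equal nPerm")
    if (any(abs(object@values) > 1 + 1e-9))
        msg <- c(msg, "null values must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})
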