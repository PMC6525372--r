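#' Accessors
#'
#' Small accessor generics for the package's classes.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("controlSets", function(x) standardGeneric("controlSets"))

#' @rdname accessors
#' @export
setGeneric("esScore", function(x) standardGeneric("esScore"))

#' @rdname accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @describeIn accessors two-level phenotype factor (first level = positive
#'   direction).
#' @export
setMethod("phenotype", "PhenotypeExperiment", function(x) x$phenotype)

#' @describeIn accessors the genes-by-samples expression matrix.
#' @export
setMethod("exprsMatrix", "PhenotypeExperiment",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @describeIn accessors named list of member vectors.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn accessors names of the negative-control sets.
#' @export
setMethod("controlSets", "GeneSetCollection", function(x) x@controls)

#' @describeIn accessors the enrichment score of a running-sum profile.
#' @export
setMethod("esScore", "RunningSumProfile", function(x) x@es)

#' @describeIn accessors the permutation draws of a null distribution.
#' @export
setMethod("nullValues", "NullDistribution", function(x) x@values)

#' @export
#' @rdname accessors
#' @param i set name or index.
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @export
#' @rdname accessors
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
#' @rdname accessors
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "PhenotypeExperiment", function(object) {
    tab <- table(phenotype(object))
    cat("PhenotypeExperiment:", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("phenotype classes: ",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = " vs "),
        "; positive direction = ", levels(phenotype(object))[1], "\n",
        sep = "")
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection of", length(object@sets), "sets")
    if (length(object@controls))
        cat(" (controls:", paste(object@controls, collapse = ", "),
            paste0(")"))
    cat("\n")
    if (length(object@sets)) {
        sz <- lengths(object@sets)
        cat("  sizes:", min(sz), "-", max(sz), "members\n")
        cat("  names:", paste(head(names(object@sets), 6), collapse = ", "),
            if (length(object@sets) > 6) "..." else "", "\n")
    }
})

setMethod("show", "StatisticSpec", function(object) {
    cat("StatisticSpec:", object@kind)
    if (object@kind == "ESavgMulti")
        cat(" (M =", object@nSplits, "splits)")
    cat(", weight exponent p =", object@weightExponent, "\n")
})

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution:", object@nPerm, "phenotype permutations of",
        object@spec@kind, "\n")
    cat("  sd =", signif(sd(object@values), 4),
        " IQR =", signif(IQR(object@values), 4), "\n")
})

setMethod("show", "RunningSumProfile", function(object) {
    cat("RunningSumProfile over", length(object@values), "genes: ES =",
        signif(object@es, 6), sprintf("(NH=%d, NR=%.4g, p=%g)\n",
                                      object@NH, object@NR,
                                      object@weightExponent))
})

setMethod("show", "CorrelationRanking", function(object) {
    cat("CorrelationRanking of", length(object@r), "genes; r range [",
        signif(min(object@r), 3), ",", signif(max(object@r), 3), "]\n")
})
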