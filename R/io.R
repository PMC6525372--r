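# Readers and writers for the standard GSEA file formats: GCT (expression),
# CLS (categorical phenotype) and GMT (gene set collections), plus plain
# TSV dialects.  Gene-id matching is case sensitive throughout.

#' Read an expression matrix (GCT or TSV)
#'
#' GCT is the \code{#1.2} dialect: a version line, a dimensions line, then a
#' table with \code{Name} and \code{Description} columns followed by one
#' column per sample.  The TSV dialect is a plain table with gene
#' identifiers in the first column and sample identifiers in the header.
#' Parse problems (dimension mismatches, duplicate gene ids, non-numeric
#' cells) raise errors naming the offending line.
#'
#' @param path file path.
#' @param format \code{"GCT"}, \code{"TSV"} or \code{"auto"} (by
#'   extension).
#' @return numeric matrix, genes x samples.
#' @export
readExpression <- function(path, format = c("auto", "GCT", "TSV")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "GCT"
                  else "TSV"
    if (format == "GCT") .readGCT(path) else .readExprTSV(path)
}

.parseNumericRows <- function(rows, ids, path, lineOffset) {
    vals <- suppressWarnings(
        lapply(rows, function(x) as.numeric(x)))
    bad <- which(vapply(vals, anyNA, logical(1)))
    if (length(bad))
        stop("non-numeric expression value in ", path, " at line ",
             lineOffset + bad[1])
    m <- do.call(rbind, vals)
    rownames(m) <- ids
    m
}

.readGCT <- function(path) {
    ln <- readLines(path)
    if (length(ln) < 3L || !startsWith(trimws(ln[1]), "#1.2"))
        stop(path, ": not a GCT 1.2 file (missing '#1.2' version line)")
    dims <- suppressWarnings(as.integer(strsplit(trimws(ln[2]), "\t")[[1]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
        stop(path, ": malformed dimensions at line 2")
    header <- strsplit(ln[3], "\t", fixed = TRUE)[[1]]
    if (length(header) < 3L || header[1] != "Name")
        stop(path, ": malformed header at line 3 (expected Name, ",
             "Description, samples...)")
    sampleIds <- header[-(1:2)]
    if (dims[2] != length(sampleIds))
        stop(path, ": dimensions line declares ", dims[2],
             " samples but header has ", length(sampleIds))
    body <- ln[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != dims[1])
        stop(path, ": dimensions line declares ", dims[1],
             " genes but file has ", length(body), " data rows")
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(header)))
        stop(path, ": wrong field count at line ",
             3 + which(nf != length(header))[1])
    ids <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop(path, ": duplicate gene id '", ids[duplicated(ids)][1], "'")
    m <- .parseNumericRows(lapply(parts, function(x) x[-(1:2)]), ids,
                           path, 3L)
    colnames(m) <- sampleIds
    m
}

.readExprTSV <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character")
    ids <- tab[[1]]
    if (anyDuplicated(ids))
        stop(path, ": duplicate gene id '", ids[duplicated(ids)][1], "'")
    m <- .parseNumericRows(asplit(as.matrix(tab[-1]), 1), ids, path, 1L)
    colnames(m) <- colnames(tab)[-1]
    m
}

#' Read a binary phenotype (CLS or two-column TSV)
#'
#' CLS is the categorical dialect: \code{"<N> 2 1"}, a \code{"# class1
#' class2"} line (file order fixes the class order; the first class is the
#' positive direction), and a line of per-sample labels given either as
#' class names or as 0/1 indices into the declared order.  The TSV dialect
#' has columns \code{sample} and \code{label}; class order follows first
#' appearance.
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"CLS"} or \code{"TSV"}.
#' @return factor of per-sample labels (two levels, first = positive
#'   direction); for TSV input, named by sample id.
#' @export
readPhenotype <- function(path, format = c("auto", "CLS", "TSV")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.cls$", path, ignore.case = TRUE)) "CLS"
                  else "TSV"
    if (format == "CLS") .readCLS(path) else .readPhenoTSV(path)
}

.readCLS <- function(path) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) < 3L) stop(path, ": truncated CLS file")
    hdr <- suppressWarnings(as.integer(strsplit(trimws(ln[1]), "[ \t]+")[[1]]))
    if (length(hdr) < 2L || anyNA(hdr[1:2]))
        stop(path, ": malformed CLS header line")
    nSamples <- hdr[1]; nClasses <- hdr[2]
    if (nClasses != 2L)
        stop(path, ": expected exactly 2 phenotype classes, found ",
             nClasses)
    cl <- strsplit(trimws(ln[2]), "[ \t]+")[[1]]
    if (cl[1] != "#") stop(path, ": malformed CLS class-name line")
    classes <- cl[-1]
    if (length(classes) != 2L)
        stop(path, ": class-name line must declare 2 classes")
    lab <- strsplit(trimws(ln[3]), "[ \t]+")[[1]]
    if (length(lab) != nSamples)
        stop(path, ": header declares ", nSamples, " samples but label ",
             "line has ", length(lab))
    if (all(lab %in% c("0", "1"))) {
        lab <- classes[as.integer(lab) + 1L]
    } else if (!all(lab %in% classes)) {
        stop(path, ": label '", setdiff(lab, classes)[1],
             "' not among declared classes")
    }
    if (length(unique(lab)) < 2L)
        stop(path, ": only one phenotype class present in labels")
    factor(lab, levels = classes)
}

.readPhenoTSV <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character")
    if (ncol(tab) < 2L)
        stop(path, ": phenotype TSV needs columns sample and label")
    lab <- tab[[2]]
    classes <- unique(lab)
    if (length(classes) != 2L)
        stop(path, ": expected exactly 2 phenotype classes, found ",
             length(classes))
    setNames(factor(lab, levels = classes), tab[[1]])
}

#' Read a GMT gene set collection
#'
#' Tab-separated: set name, description, then member identifiers.
#' Duplicate members within a set are de-duplicated with a warning;
#' duplicate set names or member-less sets are errors.
#'
#' @param path file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop(path, ": set with no members at line ", short[1])
    nms <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(nms))
        stop(path, ": duplicate gene set name '",
             nms[duplicated(nms)][1], "'")
    sets <- lapply(parts, function(x) {
        mem <- x[-(1:2)]
        mem <- mem[nzchar(mem)]
        if (anyDuplicated(mem)) {
            warning("duplicate members de-duplicated in set '", x[1], "'")
            mem <- unique(mem)
        }
        mem
    })
    names(sets) <- nms
    GeneSetCollection(sets)
}

#' Assemble a PhenotypeExperiment from expression + phenotype files
#'
#' For CLS input, labels are matched to samples by file order; for
#' phenotype TSV input they are matched by sample identifier.
#'
#' @param exprPath expression file (GCT or TSV).
#' @param phenoPath phenotype file (CLS or TSV).
#' @return a \linkS4class{PhenotypeExperiment}.
#' @export
readDataset <- function(exprPath, phenoPath) {
    m <- readExpression(exprPath)
    ph <- readPhenotype(phenoPath)
    if (!is.null(names(ph)) && all(colnames(m) %in% names(ph)))
        ph <- ph[colnames(m)]
    if (length(ph) != ncol(m))
        stop("phenotype has ", length(ph), " labels but expression has ",
             ncol(m), " samples")
    PhenotypeExperiment(m, ph)
}

#' Write GCT / CLS / GMT files
#'
#' @param dataset a \linkS4class{PhenotypeExperiment} (for
#'   \code{writeGCT}/\code{writeCLS}).
#' @param collection a \linkS4class{GeneSetCollection} (for
#'   \code{writeGMT}).
#' @param path output file path.
#' @return the path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeGCT <- function(dataset, path) {
    m <- exprsMatrix(dataset)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(m)),
                     collapse = "\t"), con)
    body <- cbind(rownames(m), "na",
                  format(m, trim = TRUE, digits = 12))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' @rdname writers
#' @export
writeCLS <- function(dataset, path) {
    ph <- phenotype(dataset)
    writeLines(c(paste(length(ph), nlevels(ph), 1),
                 paste("#", paste(levels(ph), collapse = " ")),
                 paste(as.character(ph), collapse = " ")), path)
    invisible(path)
}

#' @rdname writers
#' @export
writeGMT <- function(collection, path) {
    sets <- geneSets(collection)
    writeLines(vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"),
        character(1)), path)
    invisible(path)
}
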