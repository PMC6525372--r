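# Synthetic benchmark: 600-gene block-structured multivariate-normal
# datasets and the 21 benchmark gene sets a-u.

.BLOCK_IDS <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x")

#' Block structure of the synthetic benchmark
#'
#' The 600 genes are organised in ten blocks drawn from a multivariate
#' normal with unit variances.  \code{dmu} is the difference in mean between
#' phenotype classes A and B for each gene in the block (placed
#' symmetrically at \eqn{\pm\Delta\mu/2}; only the difference matters for
#' rank statistics); \code{rho} the within-block correlation.  Block viii
#' has two 10-gene subgroups with opposite \eqn{\Delta\mu} signs,
#' correlation +0.6 within each subgroup and -0.6 between them.  Blocks are
#' mutually independent.
#'
#' @return \code{data.frame} with one row per gene: \code{gene} (identifier
#'   \code{gene001}..\code{gene600}), \code{index}, \code{block},
#'   \code{dmu}, \code{rho}.
#' @examples
#' table(syntheticBlocks()$block)
#' @export
syntheticBlocks <- function() {
    spec <- list(
        i    = list(size = 420L, dmu = 0,    rho = 0),
        ii   = list(size = 20L,  dmu = 0.5,  rho = 0),
        iii  = list(size = 20L,  dmu = 0.25, rho = 0),
        iv   = list(size = 20L,  dmu = 0.1,  rho = 0),
        v    = list(size = 20L,  dmu = 0.5,  rho = 0.6),
        vi   = list(size = 20L,  dmu = 0.25, rho = 0.6),
        vii  = list(size = 20L,  dmu = 0.1,  rho = 0.6),
        viii = list(size = 20L,  dmu = c(rep(0.5, 10), rep(-0.5, 10)),
                    rho = 0.6),
        ix   = list(size = 20L,  dmu = c(rep(0.5, 10), rep(-0.5, 10)),
                    rho = 0),
        x    = list(size = 20L,  dmu = 0,    rho = 0.6))
    blk <- rep(names(spec), vapply(spec, `[[`, integer(1), "size"))
    dmu <- unlist(lapply(spec, function(b) rep_len(b$dmu, b$size)),
                  use.names = FALSE)
    rho <- rep(vapply(spec, `[[`, numeric(1), "rho"),
               vapply(spec, `[[`, integer(1), "size"))
    data.frame(gene = sprintf("gene%03d", seq_along(blk)),
               index = seq_along(blk),
               block = factor(blk, levels = .BLOCK_IDS),
               dmu = dmu, rho = rho,
               stringsAsFactors = FALSE)
}

# covariance matrix of one block (unit diagonal)
.blockCovariance <- function(blockId, size, rho) {
    if (blockId == "viii") {
        v <- c(rep(1, 10), rep(-1, 10))
        sig <- (1 - rho) * diag(size) + rho * tcrossprod(v)
    } else {
        sig <- (1 - rho) * diag(size) + rho * matrix(1, size, size)
    }
    sig
}

#' Full gene-gene covariance of the synthetic benchmark
#'
#' Block-diagonal 600 x 600 covariance (symmetric, unit diagonal, positive
#' definite) implied by \code{\link{syntheticBlocks}}.  Off-block
#' covariances are 0 (blocks are independent).
#'
#' @return 600 x 600 numeric matrix.
#' @export
syntheticCovariance <- function() {
    bl <- syntheticBlocks()
    n <- nrow(bl)
    sig <- matrix(0, n, n, dimnames = list(bl$gene, bl$gene))
    for (b in levels(bl$block)) {
        ix <- which(bl$block == b)
        sig[ix, ix] <- .blockCovariance(b, length(ix), bl$rho[ix[1]])
    }
    sig
}

#' Simulate a synthetic benchmark dataset
#'
#' Draws expression for 600 genes and \code{2 * nPerClass} samples from the
#' block multivariate normal with unit variances; class A genes get mean
#' \eqn{+\Delta\mu/2} and class B \eqn{-\Delta\mu/2}.  Class A is the first
#' phenotype level (positive direction).  Deterministic given the RNG state.
#'
#' @param nPerClass samples per phenotype class (default 25, i.e. a
#'   50-sample cohort).
#' @return a \linkS4class{PhenotypeExperiment}.
#' @examples
#' set.seed(1)
#' pe <- simulateDataset()
#' pe
#' @export
simulateDataset <- function(nPerClass = 25L) {
    if (nPerClass < 2L) stop("nPerClass must be >= 2")
    bl <- syntheticBlocks()
    n <- 2L * as.integer(nPerClass)
    x <- matrix(NA_real_, nrow(bl), n)
    for (b in levels(bl$block)) {
        ix <- which(bl$block == b)
        rho <- bl$rho[ix[1]]
        z <- matrix(rnorm(length(ix) * n), length(ix), n)
        if (rho != 0) {
            L <- chol(.blockCovariance(b, length(ix), rho))
            z <- crossprod(L, z)
        }
        x[ix, ] <- z
    }
    shift <- bl$dmu / 2
    x[, seq_len(nPerClass)] <- x[, seq_len(nPerClass)] + shift
    x[, nPerClass + seq_len(nPerClass)] <-
        x[, nPerClass + seq_len(nPerClass)] - shift
    dimnames(x) <- list(bl$gene,
                        c(sprintf("A%02d", seq_len(nPerClass)),
                          sprintf("B%02d", seq_len(nPerClass))))
    PhenotypeExperiment(x, factor(rep(c("A", "B"), each = nPerClass),
                                  levels = c("A", "B")))
}

#' The 21 benchmark gene sets a-u
#'
#' Twenty-one 20-member gene sets spanning no association (controls a and
#' j), a ladder of effect sizes (\eqn{\Delta\mu} 0.5/0.25/0.1) with and
#' without within-set correlation, balanced up/down mixtures (h, i),
#' moderately unbalanced mixtures (l, p, q, r), and dilutions with null
#' genes (s, t, u).  Partial draws from a block take its lowest-index genes
#' (within the stated subgroup where one is named); under exchangeability
#' within a block the choice is statistically irrelevant.  Where the listed
#' composition leaves per-block counts open the split is, in listed block
#' order: m = 7/7/6 from ii/iii/iv, n = 7/7/6 from v/vi/vii, o =
#' 4/4/3/3/3/3 from ii-vii, u = 8 null genes plus the first gene of each of
#' blocks ii-x and the second gene of ii, iii, iv.
#'
#' @return a \linkS4class{GeneSetCollection} with controls \code{a} and
#'   \code{j} flagged.
#' @examples
#' syntheticGeneSets()
#' @export
syntheticGeneSets <- function() {
    bl <- syntheticBlocks()
    first <- function(block, k, offset = 0L) {
        ix <- which(bl$block == block)
        ix[offset + seq_len(k)]
    }
    # subgroup offsets: in blocks viii and ix genes 1-10 are dmu=+0.5 and
    # 11-20 are dmu=-0.5
    idx <- list(
        a = first("i", 20),
        b = first("ii", 20),
        c = first("iii", 20),
        d = first("iv", 20),
        e = first("v", 20),
        f = first("vi", 20),
        g = first("vii", 20),
        h = first("viii", 20),
        i = first("ix", 20),
        j = first("x", 20),
        k = c(first("ii", 10), first("v", 10)),
        l = c(first("ii", 10), first("viii", 5), first("viii", 5, 10L)),
        m = c(first("ii", 7), first("iii", 7), first("iv", 6)),
        n = c(first("v", 7), first("vi", 7), first("vii", 6)),
        o = c(first("ii", 4), first("iii", 4), first("iv", 3),
              first("v", 3), first("vi", 3), first("vii", 3)),
        p = c(first("ix", 10), first("viii", 5, 10L), first("viii", 5)),
        q = c(first("ii", 10), first("viii", 5), first("viii", 5, 10L)),
        r = c(first("ii", 3), first("ix", 10), first("ix", 7, 10L)),
        s = c(first("i", 10), first("ii", 10)),
        t = c(first("i", 10), first("v", 10)),
        u = c(first("i", 8),
              vapply(c("ii", "iii", "iv", "v", "vi", "vii",
                       "viii", "ix", "x"),
                     function(b) first(b, 1L), integer(1)),
              vapply(c("ii", "iii", "iv"),
                     function(b) first(b, 1L, 1L), integer(1))))
    GeneSetCollection(lapply(idx, function(ix) bl$gene[ix]),
                      controls = c("a", "j"))
}
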