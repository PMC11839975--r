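## Expression preprocessing: fraction-of-transcripts normalization, replicate
## collapse, zero handling + median/log2 standardization, stage correlation.

#' Fraction-of-transcripts normalization
#'
#' Converts raw counts to per-sample relative transcript abundances: with
#' \code{useLengths = TRUE} (the default when lengths are available),
#' \eqn{\tau_i = (c_i/l_i) / \sum_j (c_j/l_j)} per sample (TPM semantics on a
#' 0-1 scale); with \code{useLengths = FALSE}, plain count fractions
#' \eqn{c_i/\sum_j c_j}. Every sample column of the result sums to one.
#'
#' @param counts a \linkS4class{StageCounts} object
#' @param useLengths logical; divide by gene length before normalizing.
#'   Requires \code{rowData(counts)$length}.
#' @return gene x sample numeric matrix of fractions (columns sum to 1)
#' @examples
#' m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' sc <- StageCounts(m, stage = "A", replicate = 1)
#' normalizeFractions(sc, useLengths = FALSE)  # 0.25, 0.75
#' @export
normalizeFractions <- function(counts, useLengths = FALSE) {
    stopifnot(is(counts, "StageCounts"))
    cts <- SummarizedExperiment::assay(counts, "counts")
    if (useLengths) {
        len <- SummarizedExperiment::rowData(counts)$length
        if (is.null(len))
            stop("useLengths = TRUE but no gene lengths in rowData(counts)$length")
        cts <- cts / len
    }
    tot <- colSums(cts)
    zero <- tot == 0
    if (any(zero))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(cts)[zero], collapse = ", "))
    sweep(cts, 2, tot, "/")
}

#' Collapse replicates to stage-level expression
#'
#' Takes the replicate median per gene within each developmental stage, then
#' renormalizes each stage column to sum to one (medians of per-sample
#' fractions do not themselves sum to one; the renormalization is harmless
#' because all downstream indices are invariant to per-stage positive
#' rescaling).
#'
#' @param fractions gene x sample matrix from \code{\link{normalizeFractions}}
#' @param design data.frame-like with row names = sample ids and columns
#'   \code{stage} (factor, levels in developmental order) and \code{replicate};
#'   typically \code{colData()} of the \linkS4class{StageCounts} object.
#' @param renormalize logical; rescale stage columns to sum to 1 (default TRUE)
#' @return a \linkS4class{StageExpression}
#' @export
collapseReplicates <- function(fractions, design, renormalize = TRUE) {
    design <- as.data.frame(design)
    missing <- setdiff(rownames(design), colnames(fractions))
    if (length(missing))
        stop("design references sample(s) absent from the matrix: ",
             paste(missing, collapse = ", "))
    stage <- design$stage
    if (!is.factor(stage)) stage <- factor(stage, levels = unique(stage))
    stages <- levels(stage)
    out <- vapply(stages, function(s) {
        smp <- rownames(design)[stage == s]
        if (!length(smp)) stop("stage without replicates: ", s)
        sub <- fractions[, smp, drop = FALSE]
        apply(sub, 1, stats::median)
    }, numeric(nrow(fractions)))
    out <- matrix(out, nrow = nrow(fractions),
                  dimnames = list(rownames(fractions), stages))
    if (renormalize) {
        tot <- colSums(out)
        if (any(tot == 0)) stop("stage with all-zero medians: ",
                                paste(stages[tot == 0], collapse = ", "))
        out <- sweep(out, 2, tot, "/")
    }
    new("StageExpression", values = out, stageOrder = stages)
}

## Fill zeros in a single profile by the interior/boundary rules.
## Interior zero <- mean of the two adjacent values; boundary zero <- the
## single neighboring value. Two adjacent zeros are resolved iteratively
## left to right (each fill uses current values).
fillZeros <- function(v) {
    interpolated <- FALSE; edge <- FALSE
    n <- length(v)
    for (i in seq_len(n)) {
        if (v[i] != 0) next
        if (i == 1L) {
            v[1L] <- v[2L]; edge <- TRUE
        } else if (i == n) {
            v[n] <- v[n - 1L]; edge <- TRUE
        } else {
            v[i] <- mean(c(v[i - 1L], v[i + 1L])); interpolated <- TRUE
        }
    }
    list(values = v, interpolated = interpolated, edge = edge)
}

#' Standardize expression profiles (median-centred log2)
#'
#' Applies the zero-handling and standardization rules used for enrichment
#' and profile visualization: genes with more than two zero-expression
#' stages are discarded; a remaining interior zero is interpolated with the
#' mean of its two adjacent stages; a zero at the first or last stage takes
#' the value of its only neighbor; finally each gene is log2-transformed and
#' centred on its own median, so 0 means "at this gene's median level". The
#' median is taken on the log2 scale (for an odd number of stages this is
#' identical to dividing by the median before the transform; for an even
#' number it uses the geometric mean of the two central stages, which keeps
#' the median of every standardized profile exactly 0).
#'
#' @param stageExpr a \linkS4class{StageExpression}
#' @return a \linkS4class{StandardizedExpression} with an audit of how many
#'   genes were discarded / interpolated / edge-filled / retained
#' @export
standardizeExpression <- function(stageExpr) {
    stopifnot(is(stageExpr, "StageExpression"))
    v <- stageExpr@values
    if (ncol(v) < 3L) stop("need at least 3 stages")
    nzero <- rowSums(v == 0)
    keep <- nzero <= 2L
    discarded <- sum(!keep)
    v <- v[keep, , drop = FALSE]
    interpolated <- 0L; edge_filled <- 0L
    out <- v
    todo <- which(rowSums(v == 0) > 0L)
    for (i in todo) {
        f <- fillZeros(v[i, ])
        out[i, ] <- f$values
        if (f$interpolated) interpolated <- interpolated + 1L
        if (f$edge) edge_filled <- edge_filled + 1L
    }
    if (any(out == 0)) {
        bad <- rownames(out)[rowSums(out == 0) > 0]
        stop("degenerate profile (zero remains after filling) for gene(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
    lg <- log2(out)
    std <- lg - apply(lg, 1, stats::median)
    new("StandardizedExpression", values = std,
        audit = list(discarded = discarded, interpolated = interpolated,
                     edge_filled = edge_filled, retained = nrow(std)))
}

#' All-against-all stage correlation
#'
#' Pearson correlation between developmental stages over standardized
#' expression profiles (a transcriptome-similarity heatmap input).
#'
#' @param std a \linkS4class{StandardizedExpression}
#' @return symmetric stage x stage correlation matrix; a stage with zero
#'   variance yields \code{NA} entries and a warning naming the stage.
#' @export
stageCorrelation <- function(std) {
    stopifnot(is(std, "StandardizedExpression"))
    v <- std@values
    if (nrow(v) < 2L) stop("need at least 2 retained genes")
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
        warning("stage(s) with zero variance, correlations undefined: ",
                paste(colnames(v)[sds == 0], collapse = ", "))
    suppressWarnings(stats::cor(v, method = "pearson"))
}
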