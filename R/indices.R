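## Expression-weighted transcriptome indices: TAI and its divergence and
## codon-bias twins, cumulative-phylostrata variants, min-max normalization
## and per-phylostratum relative expression.

#' Expression-weighted transcriptome index
#'
#' The common form of TAI, TdNI, TdSI and TCBI: for each developmental stage
#' \eqn{s}, \eqn{x_s = \sum_i w_i e_{is} / \sum_i e_{is}} over genes that
#' carry both expression and a weight. Genes missing the weight are excluded
#' (and not counted in \code{nGenesUsed}). The profile is invariant to
#' rescaling any stage column by a positive constant and bounded by the range
#' of the weights used.
#'
#' @param expr a \linkS4class{StageExpression}
#' @param weights named numeric vector (gene -> weight); \code{NA} = missing
#' @param weightName label stored on the result
#' @return an \linkS4class{IndexProfile}
#' @examples
#' e <- new("StageExpression",
#'          values = matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "S1")),
#'          stageOrder = "S1")
#' profileValues(weightedTranscriptomeIndex(e, c(a = 1, b = 5)))  # 4
#' @export
weightedTranscriptomeIndex <- function(expr, weights, weightName = "weight") {
    stopifnot(is(expr, "StageExpression"))
    if (is.null(names(weights))) stop("'weights' must be named by gene")
    common <- intersect(rownames(expr@values), names(weights))
    common <- common[!is.na(weights[common])]
    if (!length(common))
        stop("no gene has both expression and a '", weightName, "' value")
    e <- expr@values[common, , drop = FALSE]
    w <- as.numeric(weights[common])
    denom <- colSums(e)
    if (any(denom == 0))
        stop("zero total expression over included genes at stage(s): ",
             paste(colnames(e)[denom == 0], collapse = ", "))
    x <- as.numeric(crossprod(e, w)) / denom
    names(x) <- colnames(e)
    new("IndexProfile", values = x, nGenesUsed = length(common),
        weightName = weightName)
}

#' Transcriptome age index (TAI) and its twins
#'
#' \code{tai} weights expression by the gene's phylostratum (low = old
#' transcriptome), \code{tdni}/\code{tdsi} by nonsynonymous/synonymous
#' divergence, and \code{tcbi} by the effective number of codons (low =
#' strong codon bias). Each index uses the intersection of expressed genes
#' and genes carrying that attribute; the number used is recorded on the
#' profile.
#'
#' @param expr a \linkS4class{StageExpression}
#' @param evol a \linkS4class{GeneEvolStats}
#' @return an \linkS4class{IndexProfile}
#' @export
tai <- function(expr, evol) indexFromStats(expr, evol, "ps")

#' @rdname tai
#' @export
tdni <- function(expr, evol) indexFromStats(expr, evol, "dN")

#' @rdname tai
#' @export
tdsi <- function(expr, evol) indexFromStats(expr, evol, "dS")

#' @rdname tai
#' @export
tcbi <- function(expr, evol) indexFromStats(expr, evol, "enc")

indexFromStats <- function(expr, evol, which) {
    stopifnot(is(evol, "GeneEvolStats"))
    st <- evol@stats
    if (!which %in% colnames(st))
        stop("GeneEvolStats carries no '", which, "' attribute")
    w <- stats::setNames(as.numeric(st[[which]]), rownames(st))
    weightedTranscriptomeIndex(expr, w, weightName = which)
}

#' Cumulative-phylostrata TAI
#'
#' TAI restricted to genes with phylostratum \code{<= k}: sequentially
#' including genes from successive phylostrata shows at which evolutionary
#' depth the profile shape settles. \code{k = P} reproduces \code{\link{tai}}
#' exactly.
#'
#' @param expr a \linkS4class{StageExpression}
#' @param evol a \linkS4class{GeneEvolStats} with a \code{ps} column
#' @param k include genes with \code{ps <= k}
#' @return an \linkS4class{IndexProfile}
#' @export
cumulativeTai <- function(expr, evol, k) {
    stopifnot(is(evol, "GeneEvolStats"), length(k) == 1L, k >= 1)
    st <- evol@stats
    if (!"ps" %in% colnames(st)) stop("GeneEvolStats carries no 'ps' attribute")
    ps <- stats::setNames(as.numeric(st$ps), rownames(st))
    ps <- ps[!is.na(ps) & ps <= k]
    if (!length(ps)) stop("no genes with ps <= ", k)
    weightedTranscriptomeIndex(expr, ps, weightName = "ps")
}

#' Min-max normalize an index profile to [0, 1]
#'
#' \eqn{(x_s - \min x) / (\max x - \min x)}; used to overlay profiles from
#' different datasets on a common 0-1 axis. The stage with the lowest index
#' maps to 0 and the highest to 1.
#'
#' @param profile an \linkS4class{IndexProfile}
#' @return an \linkS4class{IndexProfile} on [0, 1]
#' @export
minMaxNormalizeProfile <- function(profile) {
    stopifnot(is(profile, "IndexProfile"))
    x <- profile@values
    rng <- range(x)
    if (rng[1] == rng[2])
        stop("constant profile: min-max normalization is undefined")
    new("IndexProfile", values = (x - rng[1]) / (rng[2] - rng[1]),
        nGenesUsed = profile@nGenesUsed,
        weightName = paste0("norm_", profile@weightName))
}

#' Per-phylostratum relative expression
#'
#' For each phylostratum, the mean normalized expression of its genes per
#' stage, min-max scaled across stages: \eqn{RE(ps)_s = (\bar f_s - \bar
#' f_{min}) / (\bar f_{max} - \bar f_{min})}, so every stratum row spans
#' [0, 1] with 1 at the stage where the stratum is most expressed.
#'
#' @param expr a \linkS4class{StageExpression}
#' @param evol a \linkS4class{GeneEvolStats} with a \code{ps} column
#' @return matrix (phylostratum x stage) of RE values in [0, 1]
#' @export
relativeExpression <- function(expr, evol) {
    stopifnot(is(evol, "GeneEvolStats"))
    st <- evol@stats
    if (!"ps" %in% colnames(st)) stop("GeneEvolStats carries no 'ps' attribute")
    ps <- stats::setNames(as.numeric(st$ps), rownames(st))
    ps <- ps[!is.na(ps)]
    common <- intersect(rownames(expr@values), names(ps))
    if (!length(common)) stop("no genes shared between expression and ps map")
    e <- expr@values[common, , drop = FALSE]
    strata <- sort(unique(ps[common]))
    out <- t(vapply(strata, function(p) {
        f <- colMeans(e[ps[common] == p, , drop = FALSE])
        rng <- range(f)
        if (rng[1] == rng[2])
            stop("constant mean-expression row for phylostratum ", p,
                 ": relative expression undefined")
        (f - rng[1]) / (rng[2] - rng[1])
    }, numeric(ncol(e))))
    rownames(out) <- paste0("ps", strata)
    out
}

#' Read a per-gene divergence table
#'
#' Loads a TSV with columns \code{gene}, \code{dN}, \code{dS} (one row per
#' focal gene, typically from an ortholog-based divergence pipeline) into
#' named vectors ready for \code{\link{GeneEvolStats}}.
#'
#' @param path file path
#' @return list with named numeric vectors \code{dN} and \code{dS}
#' @export
readDivergenceTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "dN", "dS")
    if (!all(need %in% colnames(tab)))
        stop("divergence table needs columns: ", paste(need, collapse = ", "))
    dup <- duplicated(tab$gene)
    if (any(dup))
        stop("duplicate gene rows: ",
             paste(utils::head(unique(tab$gene[dup]), 5), collapse = ", "))
    badN <- which(!is.finite(tab$dN) | tab$dN < 0)
    badS <- which(!is.finite(tab$dS) | tab$dS < 0)
    bad <- sort(unique(c(badN, badS)))
    if (length(bad))
        stop("malformed dN/dS values at line(s) ",
             paste(utils::head(bad + 1L, 10), collapse = ", "))
    list(dN = stats::setNames(tab$dN, tab$gene),
         dS = stats::setNames(tab$dS, tab$gene))
}
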