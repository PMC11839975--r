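## Stage-wise functional enrichment: upregulated-gene selection, two-sided
## (minimum-likelihood) hypergeometric test, log odds, BH correction.

#' Gene-to-term annotation set
#'
#' Gene-level functional annotations restricted to a declared term subset
#' (e.g. a GO slim). The background universe N defaults to the genes
#' carrying at least one (restricted) annotation, configurable to a full
#' gene list.
#'
#' @slot geneToTerms named list, gene -> character vector of terms
#' @slot universe character, background gene ids (size N of the tests)
#' @slot termUniverse character, terms eligible for testing
#' @export
setClass("AnnotationSet",
    representation(geneToTerms = "list", universe = "character",
                   termUniverse = "character"))

setValidity("AnnotationSet", function(object) {
    if (is.null(names(object@geneToTerms)) && length(object@geneToTerms))
        return("geneToTerms must be named by gene")
    if (!all(names(object@geneToTerms) %in% object@universe))
        return("every annotated gene must be in the universe")
    TRUE
})

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet:", length(object@geneToTerms), "annotated genes,",
        length(object@termUniverse), "terms, background N =",
        length(object@universe), "\n")
})

#' Construct an AnnotationSet
#'
#' @param annotations data.frame with columns \code{gene}, \code{term}
#' @param termSubset optional character vector; annotations outside it are
#'   dropped before testing (subset restriction, e.g. a GO Plant slim)
#' @param universe optional background gene ids; defaults to the genes left
#'   with at least one annotation after restriction
#' @return an \linkS4class{AnnotationSet}
#' @export
AnnotationSet <- function(annotations, termSubset = NULL, universe = NULL) {
    annotations <- as.data.frame(annotations)
    if (!all(c("gene", "term") %in% colnames(annotations)))
        stop("annotations need columns 'gene' and 'term'")
    annotations$gene <- as.character(annotations$gene)
    annotations$term <- as.character(annotations$term)
    if (!is.null(termSubset))
        annotations <- annotations[annotations$term %in% termSubset, ,
                                   drop = FALSE]
    g2t <- lapply(split(annotations$term, annotations$gene), unique)
    if (is.null(universe)) universe <- names(g2t)
    universe <- unique(as.character(universe))
    if (!all(names(g2t) %in% universe))
        stop("annotated gene(s) missing from the supplied universe")
    new("AnnotationSet", geneToTerms = g2t, universe = universe,
        termUniverse = sort(unique(annotations$term)))
}

#' Select stage-upregulated genes
#'
#' A gene is upregulated in a stage when its standardized expression there is
#' at least \code{threshold} (default 0.5 on the log2 scale) above its own
#' profile median - i.e. its standardized value, which is 0 at the median, is
#' \code{>= threshold} (inclusive).
#'
#' @param std a \linkS4class{StandardizedExpression}
#' @param stage stage label
#' @param threshold log2 threshold, default 0.5
#' @return character vector of gene ids
#' @export
selectUpregulated <- function(std, stage, threshold = 0.5) {
    stopifnot(is(std, "StandardizedExpression"))
    v <- std@values
    if (!stage %in% colnames(v)) stop("unknown stage: ", stage)
    rownames(v)[v[, stage] >= threshold]
}

#' Two-sided hypergeometric test (minimum-likelihood method)
#'
#' Exact two-sided p value for a 2x2 sampling scheme: drawing \code{n} genes
#' from a background of \code{N} of which \code{K} carry the annotation and
#' observing \code{k} carriers. The two-sided p sums the probabilities of all
#' outcomes at most as likely as the observed one,
#' \eqn{p = \sum_{j: P(j) \le P(k)} P(j)} (with a 1e-7 relative tolerance on
#' the comparison, as is standard for exact tests); the alternative
#' convention of doubling the smaller tail is available via
#' \code{method = "doubling"}.
#'
#' @param k observed annotated genes in the draw
#' @param K annotated genes in the background
#' @param n draw size
#' @param N background size
#' @param method "minlik" (default) or "doubling"
#' @return p value in (0, 1]
#' @export
hypergeomTwoSided <- function(k, K, n, N, method = c("minlik", "doubling")) {
    method <- match.arg(method)
    if (K > N || n > N || k > min(n, K) || k < max(0, n - (N - K)) || k < 0)
        stop("inconsistent counts: need max(0, n-(N-K)) <= k <= min(n, K) <= N")
    support <- max(0L, n - (N - K)):min(n, K)
    d <- stats::dhyper(support, K, N - K, n)
    dk <- d[match(k, support)]
    if (method == "minlik") {
        p <- sum(d[d <= dk * (1 + 1e-7)])
    } else {
        lower <- sum(d[support <= k])
        upper <- sum(d[support >= k])
        p <- 2 * min(lower, upper)
    }
    min(p, 1)
}

#' Log odds of annotation frequency
#'
#' \eqn{\log_2[(k/n)/(K/N)]}: how much more (positive) or less (negative)
#' frequent an annotation is among a stage's upregulated genes than in the
#' background. When \eqn{k = 0} (log of zero) a Haldane-Anscombe continuity
#' correction adds 0.5 to the annotated cells, so the frequencies become
#' \eqn{(k+0.5)/(n+1)} and \eqn{(K+0.5)/(N+1)}.
#'
#' @inheritParams hypergeomTwoSided
#' @return log2 frequency ratio
#' @export
logOdds <- function(k, K, n, N) {
    if (n == 0 || K == 0)
        stop("log odds undefined for n = 0 or K = 0")
    if (k == 0)
        return(log2(((k + 0.5) / (n + 1)) / ((K + 0.5) / (N + 1))))
    log2((k / n) / (K / N))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (a validated wrapper around
#' \code{\link[stats]{p.adjust}}): input order preserved, adjusted values
#' monotone after sorting and capped at 1, never smaller than the raw p.
#'
#' @param p numeric vector of p values in [0, 1]
#' @return adjusted p values in input order
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Stage-wise enrichment scan
#'
#' For every stage: select upregulated genes (restricted to the annotation
#' universe), count per-term overlaps, test each term with the two-sided
#' hypergeometric test, attach log odds, and BH-adjust within the stage
#' (\code{adjustAcross = "stage"}; \code{"global"} adjusts across the whole
#' scan instead). A stage with no upregulated genes yields rows with n = 0
#' and no test.
#'
#' @param std a \linkS4class{StandardizedExpression}
#' @param annotations an \linkS4class{AnnotationSet}
#' @param stages stage labels to scan (default: all)
#' @param threshold upregulation threshold on the log2 scale (default 0.5)
#' @param adjustAcross BH family: "stage" (default) or "global"
#' @param alpha significance level for the \code{significant} flag
#' @return data.frame with columns stage, term, k, n, K, N, log_odds, p,
#'   p_adj, significant
#' @export
enrichmentScan <- function(std, annotations, stages = NULL, threshold = 0.5,
                           adjustAcross = c("stage", "global"),
                           alpha = 0.05) {
    stopifnot(is(std, "StandardizedExpression"),
              is(annotations, "AnnotationSet"))
    adjustAcross <- match.arg(adjustAcross)
    if (!length(annotations@termUniverse)) stop("no terms to test")
    if (is.null(stages)) stages <- colnames(std@values)
    universe <- annotations@universe
    N <- length(universe)
    terms <- annotations@termUniverse
    # per-term background counts
    allAnn <- unlist(annotations@geneToTerms, use.names = FALSE)
    Ktab <- table(factor(allAnn, levels = terms))
    rows <- vector("list", length(stages))
    for (si in seq_along(stages)) {
        s <- stages[si]
        up <- intersect(selectUpregulated(std, s, threshold), universe)
        n <- length(up)
        upAnn <- unlist(annotations@geneToTerms[up], use.names = FALSE)
        ktab <- table(factor(upAnn, levels = terms))
        df <- data.frame(stage = s, term = terms,
                         k = as.integer(ktab), n = n,
                         K = as.integer(Ktab), N = N,
                         stringsAsFactors = FALSE)
        if (n > 0) {
            df$log_odds <- mapply(logOdds, df$k, df$K, df$n, df$N)
            df$p <- mapply(hypergeomTwoSided, df$k, df$K, df$n, df$N)
        } else {
            df$log_odds <- NA_real_
            df$p <- NA_real_
        }
        rows[[si]] <- df
    }
    out <- do.call(rbind, rows)
    out$p_adj <- NA_real_
    if (adjustAcross == "stage") {
        for (s in stages) {
            idx <- out$stage == s & !is.na(out$p)
            if (any(idx)) out$p_adj[idx] <- bhAdjust(out$p[idx])
        }
    } else {
        idx <- !is.na(out$p)
        if (any(idx)) out$p_adj[idx] <- bhAdjust(out$p[idx])
    }
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
    rownames(out) <- NULL
    out
}
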