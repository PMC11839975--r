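## Reciprocal-best-hit orthology from two directed hit tables.

#' Reciprocal best hits
#'
#' Orthology by the RBH criterion: the pair (a, b) is retained iff b is a's
#' best hit in the A->B table and a is b's best hit in the B->A table, after
#' filtering both tables at \code{eThreshold}. The best hit is the record
#' with the highest bitscore, ties broken by lowest e-value, then by
#' lexicographically smallest subject id, so the result is deterministic.
#'
#' @param hitsAB,hitsBA data.frames with columns \code{query},
#'   \code{subject}, \code{e_value}, \code{bitscore}
#' @param eThreshold keep hits with \code{e_value <= eThreshold}
#' @return data.frame with columns \code{a}, \code{b}, one row per ortholog
#'   pair, sorted by \code{a}; zero rows if none
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, eThreshold = 1e-5) {
    bestAB <- bestHitPerQuery(hitsAB, eThreshold)
    bestBA <- bestHitPerQuery(hitsBA, eThreshold)
    if (!nrow(bestAB) || !nrow(bestBA))
        return(data.frame(a = character(0), b = character(0)))
    back <- stats::setNames(bestBA$subject, bestBA$query)
    keep <- !is.na(back[bestAB$subject]) & back[bestAB$subject] == bestAB$query
    out <- data.frame(a = bestAB$query[keep], b = bestAB$subject[keep])
    out[order(out$a), , drop = FALSE]
}

bestHitPerQuery <- function(hits, eThreshold) {
    hits <- as.data.frame(hits)
    need <- c("query", "subject", "e_value", "bitscore")
    if (!all(need %in% colnames(hits)))
        stop("hit table needs columns: ", paste(need, collapse = ", "))
    hits <- hits[hits$e_value <= eThreshold, , drop = FALSE]
    if (!nrow(hits))
        return(data.frame(query = character(0), subject = character(0)))
    ord <- order(hits$query, -hits$bitscore, hits$e_value,
                 as.character(hits$subject))
    hits <- hits[ord, , drop = FALSE]
    hits[!duplicated(hits$query), c("query", "subject"), drop = FALSE]
}
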