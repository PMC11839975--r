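## Phylostratigraphy: gene-age assignment from homology hit tables via the
## oldest-hit rule, e-value robustness sweeps, and lineage-map construction
## from a consensus phylogeny.

#' Assign genes to phylostrata (oldest-hit rule)
#'
#' A gene's phylostratum is the oldest internode (smallest index) among the
#' taxa it hits at \code{e <= eCutoff} (inclusive threshold). Genes with no
#' qualifying hit are reported as unassigned and excluded from downstream
#' indices.
#'
#' @param hits data.frame with columns \code{query}, \code{taxon},
#'   \code{e_value} (duplicate (query, taxon) pairs allowed; the best hit
#'   counts)
#' @param lineage a \linkS4class{LineageMap}
#' @param eCutoff positive e-value cutoff (hits kept when \code{e <= eCutoff})
#' @return a \linkS4class{PhylostratumMap}
#' @examples
#' lin <- LineageMap(c(t1 = 1, t2 = 2, t3 = 3))
#' hits <- data.frame(query = "g", taxon = c("t1", "t3"), e_value = 1e-9)
#' psAssignments(assignPhylostrata(hits, lin, 1e-3))  # g -> 1
#' @export
assignPhylostrata <- function(hits, lineage, eCutoff = 1e-3) {
    stopifnot(is(lineage, "LineageMap"), eCutoff > 0)
    hits <- validateHitTable(hits)
    unknown <- setdiff(unique(hits$taxon), names(lineage@taxonToPs))
    if (length(unknown))
        stop("hit table references taxa absent from the lineage map: ",
             paste(utils::head(unknown, 10), collapse = ", "))
    allGenes <- unique(hits$query)
    keep <- hits$e_value <= eCutoff
    sub <- hits[keep, , drop = FALSE]
    if (nrow(sub)) {
        psHit <- lineage@taxonToPs[sub$taxon]
        agg <- tapply(psHit, sub$query, min)
        ps <- stats::setNames(as.integer(agg), names(agg))
        ps <- ps[sort(names(ps))]
    } else {
        ps <- stats::setNames(integer(0), character(0))
    }
    unassigned <- sort(setdiff(allGenes, names(ps)))
    new("PhylostratumMap", ps = ps, unassigned = unassigned,
        eCutoff = eCutoff)
}

validateHitTable <- function(hits) {
    hits <- as.data.frame(hits)
    need <- c("query", "taxon", "e_value")
    if (!all(need %in% colnames(hits)))
        stop("hit table needs columns: ", paste(need, collapse = ", "))
    if (any(hits$e_value < 0)) stop("e_value must be non-negative")
    hits$query <- as.character(hits$query)
    hits$taxon <- as.character(hits$taxon)
    hits
}

#' e-value robustness sweep
#'
#' Recomputes the phylostratigraphic map at each cutoff and reports
#' monotonicity: as cutoffs get stricter the qualifying hit set of a gene
#' shrinks, so its phylostratum index can only increase (gene looks younger)
#' or the gene drops out; an age decrease under a stricter cutoff is a
#' violation.
#'
#' @param hits,lineage as in \code{\link{assignPhylostrata}}
#' @param cutoffs numeric vector of cutoffs (any order; sorted internally
#'   from permissive to strict)
#' @return list with \code{maps} (one \linkS4class{PhylostratumMap} per
#'   cutoff, named by cutoff) and \code{violations} (data.frame gene /
#'   cutoff_from / cutoff_to / ps_from / ps_to; zero rows when monotone)
#' @export
evalueSweep <- function(hits, lineage,
                        cutoffs = c(10, 1, 1e-1, 1e-2, 1e-3, 1e-5, 1e-10,
                                    1e-15, 1e-20, 1e-30, 1e-40)) {
    if (!length(cutoffs)) stop("cutoffs must be non-empty")
    cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
    maps <- lapply(cutoffs, function(ct) assignPhylostrata(hits, lineage, ct))
    names(maps) <- format(cutoffs, scientific = TRUE, trim = TRUE)
    viol <- list()
    for (i in seq_along(maps)[-1]) {
        a <- maps[[i - 1]]@ps; b <- maps[[i]]@ps
        common <- intersect(names(a), names(b))
        bad <- common[b[common] < a[common]]
        if (length(bad))
            viol[[length(viol) + 1L]] <- data.frame(
                gene = bad,
                cutoff_from = cutoffs[i - 1], cutoff_to = cutoffs[i],
                ps_from = unname(a[bad]), ps_to = unname(b[bad]))
    }
    violations <- if (length(viol)) do.call(rbind, viol) else
        data.frame(gene = character(0), cutoff_from = numeric(0),
                   cutoff_to = numeric(0), ps_from = integer(0),
                   ps_to = integer(0))
    list(maps = maps, violations = violations)
}

#' Build a lineage map from a consensus phylogeny
#'
#' Indexes the internodes on the root-to-focal path of a rooted tree from
#' oldest (1, the root) to youngest, and assigns every terminal taxon the
#' index of the internode where its lineage diverges from the focal lineage.
#' The focal species itself gets the youngest stratum P = (number of
#' internodes on the path) + 1.
#'
#' @param tree an \code{\link[ape]{ape}} \code{phylo} object or a Newick
#'   string/file path
#' @param focal tip label of the focal species
#' @return a \linkS4class{LineageMap}
#' @examples
#' lm <- buildLineageFromNewick("(((A,B),C),D);", focal = "A")
#' taxonToPs(lm)  # D=1, C=2, B=3, A=4
#' @export
buildLineageFromNewick <- function(tree, focal) {
    if (is.character(tree)) {
        tree <- if (file.exists(tree)) ape::read.tree(tree) else
            ape::read.tree(text = tree)
    }
    if (is.null(tree)) stop("could not parse Newick input")
    if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or Newick")
    if (!focal %in% tree$tip.label)
        stop("focal taxon '", focal, "' not found in the tree")
    ntip <- length(tree$tip.label)
    focalTip <- match(focal, tree$tip.label)
    root <- ntip + 1L
    path <- ape::nodepath(tree, from = root, to = focalTip)
    internodes <- path[-length(path)]          # internal nodes, root first
    P <- length(internodes) + 1L
    psOfNode <- stats::setNames(seq_along(internodes), internodes)
    out <- integer(ntip)
    for (tip in seq_len(ntip)) {
        if (tip == focalTip) { out[tip] <- P; next }
        mrca <- ape::getMRCA(tree, c(tip, focalTip))
        if (!as.character(mrca) %in% names(psOfNode))
            stop("taxon '", tree$tip.label[tip],
                 "' does not attach to the root-focal path")
        out[tip] <- psOfNode[[as.character(mrca)]]
    }
    names(out) <- tree$tip.label
    LineageMap(out, nStrata = P)
}

#' Read a BLAST tabular hit file
#'
#' Parses 12-column outfmt-6 output (or a 3-column query/taxon/e-value
#' extract) into the hit-table data.frame used by
#' \code{\link{assignPhylostrata}}. The subject taxon is extracted from the
#' subject id with \code{taxonPattern}, a regular expression whose first
#' capture group is the taxon tag.
#'
#' @param path file path
#' @param taxonPattern regex with one capture group applied to the subject
#'   id; default takes everything before the first \code{|}
#' @return data.frame with columns query, taxon, e_value (and bitscore when
#'   present)
#' @export
readBlastTab <- function(path, taxonPattern = "^([^|]+)\\|") {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) >= 12L) {
        out <- data.frame(query = as.character(tab[[1]]),
                          subject = as.character(tab[[2]]),
                          e_value = as.numeric(tab[[11]]),
                          bitscore = as.numeric(tab[[12]]))
    } else if (ncol(tab) == 3L) {
        out <- data.frame(query = as.character(tab[[1]]),
                          subject = as.character(tab[[2]]),
                          e_value = as.numeric(tab[[3]]))
    } else stop("expected 12-column outfmt-6 or 3-column query/taxon/e-value")
    m <- regmatches(out$subject, regexec(taxonPattern, out$subject))
    taxon <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                    character(1))
    out$taxon <- ifelse(is.na(taxon), out$subject, taxon)
    out
}
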