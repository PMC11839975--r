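#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Gene-by-sample counts for an ordered developmental series
#'
#' Extends \linkS4class{SummarizedExperiment}: a \code{"counts"} assay of
#' non-negative integers plus a sample design in \code{colData} with columns
#' \code{stage} (a factor whose levels give the developmental order) and
#' \code{replicate}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("StageCounts", contains = "SummarizedExperiment")

setValidity("StageCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cts)))
            msg <- c(msg, "counts must be finite")
        else if (any(cts < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("stage", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must have 'stage' and 'replicate' columns")
    else if (!is.factor(cd$stage))
        msg <- c(msg, "colData$stage must be a factor (levels = stage order)")
    if (length(msg)) msg else TRUE
})

#' Construct a StageCounts object
#'
#' @param counts gene x sample matrix of non-negative counts; rownames are
#'   gene ids, colnames sample ids.
#' @param stage character/factor of stage labels, one per sample. If not a
#'   factor, \code{stageOrder} (or order of first appearance) fixes the
#'   developmental order.
#' @param replicate replicate identifiers, one per sample.
#' @param stageOrder optional character vector giving the ordered stage labels.
#' @param geneLengths optional named numeric of gene lengths (bp), stored in
#'   \code{rowData()$length}.
#' @return a \linkS4class{StageCounts} object
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sc <- StageCounts(m, stage = c("A", "A", "B", "B"), replicate = c(1, 2, 1, 2))
#' @export
StageCounts <- function(counts, stage, replicate, stageOrder = NULL,
                        geneLengths = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    if (length(stage) != ncol(counts))
        stop("'stage' must have one entry per sample")
    if (length(replicate) != ncol(counts))
        stop("'replicate' must have one entry per sample")
    if (!is.factor(stage)) {
        lv <- if (is.null(stageOrder)) unique(as.character(stage)) else stageOrder
        stage <- factor(as.character(stage), levels = lv)
    }
    if (anyNA(stage)) stop("stage labels outside the declared stage order")
    cd <- S4Vectors::DataFrame(stage = stage,
                               replicate = as.character(replicate),
                               row.names = colnames(counts))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(geneLengths)) {
        if (is.null(names(geneLengths))) {
            if (length(geneLengths) != nrow(counts))
                stop("unnamed 'geneLengths' must match nrow(counts)")
            rd$length <- as.numeric(geneLengths)
        } else {
            rd$length <- as.numeric(geneLengths[rownames(counts)])
        }
        if (anyNA(rd$length) || any(rd$length <= 0))
            stop("gene lengths must be positive and cover all genes")
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("StageCounts", se)
}

#' Stage-level normalized expression
#'
#' Gene x stage matrix of non-negative normalized expression values (the
#' e_i of the weighted transcriptome indices): per-sample fraction-of-
#' transcripts values collapsed to the replicate median per stage and
#' renormalized so each stage column sums to one.
#'
#' @slot values gene x stage numeric matrix, non-negative
#' @slot stageOrder character, ordered developmental stage labels (= colnames)
#' @export
setClass("StageExpression",
    representation(values = "matrix", stageOrder = "character"))

setValidity("StageExpression", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (any(!is.finite(v))) return("values must be finite")
    if (any(v < 0)) return("values must be non-negative")
    if (!identical(colnames(v), object@stageOrder))
        return("colnames(values) must equal stageOrder")
    TRUE
})

#' Standardized log2 expression profiles
#'
#' Gene x stage matrix on the log2 scale where 0 is each gene's own median,
#' after the zero-handling rules: genes with more than two zero stages are
#' discarded; an interior zero is replaced by the mean of the two adjacent
#' stages; a boundary zero takes the single neighboring value. The
#' \code{audit} slot counts genes touched by each rule.
#'
#' @slot values gene x stage numeric matrix (log2, median-centred)
#' @slot audit list with integer counts \code{discarded}, \code{interpolated},
#'   \code{edge_filled}, \code{retained}
#' @export
setClass("StandardizedExpression",
    representation(values = "matrix", audit = "list"))

setValidity("StandardizedExpression", function(object) {
    need <- c("discarded", "interpolated", "edge_filled", "retained")
    if (!all(need %in% names(object@audit)))
        return(paste("audit must contain:", paste(need, collapse = ", ")))
    if (nrow(object@values) != object@audit$retained)
        return("audit$retained must equal nrow(values)")
    TRUE
})

#' Per-gene evolutionary attributes
#'
#' Holds the per-gene weights of the transcriptome indices: phylostratum
#' (\code{ps}, integer, 1 = oldest), nonsynonymous (\code{dN}) and synonymous
#' (\code{dS}) divergence, and effective number of codons (\code{enc}).
#' Any attribute may be \code{NA} for a gene; each index uses the genes
#' carrying its weight.
#'
#' @slot stats \link[S4Vectors]{DataFrame} with row names = gene ids and any
#'   of the columns \code{ps}, \code{dN}, \code{dS}, \code{enc}
#' @export
setClass("GeneEvolStats", representation(stats = "DataFrame"))

setValidity("GeneEvolStats", function(object) {
    st <- object@stats
    if (is.null(rownames(st))) return("stats must have gene ids as row names")
    ok <- intersect(colnames(st), c("ps", "dN", "dS", "enc"))
    if (!length(ok)) return("stats must carry at least one of ps/dN/dS/enc")
    if ("enc" %in% colnames(st)) {
        e <- st$enc[!is.na(st$enc)]
        if (length(e) && (any(e < 20 - 1e-9) || any(e > 61 + 1e-9)))
            return("enc values must lie in [20, 61]")
    }
    if ("ps" %in% colnames(st)) {
        p <- st$ps[!is.na(st$ps)]
        if (length(p) && any(p < 1 | p != round(p)))
            return("ps values must be positive integers")
    }
    TRUE
})

#' Construct a GeneEvolStats object
#'
#' @param genes character vector of gene ids
#' @param ps,dN,dS,enc optional numeric vectors aligned with \code{genes}
#'   (or named by gene); \code{NA} marks a missing attribute.
#' @return a \linkS4class{GeneEvolStats}
#' @export
GeneEvolStats <- function(genes, ps = NULL, dN = NULL, dS = NULL, enc = NULL) {
    genes <- as.character(genes)
    align <- function(x) {
        if (is.null(x)) return(NULL)
        if (!is.null(names(x))) x <- x[genes]
        if (length(x) != length(genes))
            stop("attribute vectors must align with 'genes'")
        unname(as.numeric(x))
    }
    df <- S4Vectors::DataFrame(row.names = genes)
    if (!is.null(ps))  df$ps  <- align(ps)
    if (!is.null(dN))  df$dN  <- align(dN)
    if (!is.null(dS))  df$dS  <- align(dS)
    if (!is.null(enc)) df$enc <- align(enc)
    new("GeneEvolStats", stats = df)
}

#' A per-stage transcriptome index profile
#'
#' One value per developmental stage of an expression-weighted mean of a
#' gene-level evolutionary attribute (TAI, TdNI, TdSI or TCBI).
#'
#' @slot values named numeric, one value per stage in developmental order
#' @slot nGenesUsed integer, number of genes entering the weighted mean
#' @slot weightName character, which attribute was used
#' @export
setClass("IndexProfile",
    representation(values = "numeric", nGenesUsed = "integer",
                   weightName = "character"))

setValidity("IndexProfile", function(object) {
    if (any(!is.finite(object@values))) return("profile values must be finite")
    if (is.null(names(object@values))) return("profile values must be named by stage")
    TRUE
})

#' Taxon-to-phylostratum lineage map
#'
#' Maps subject taxa to the internodes (phylostrata) of the root-to-focal
#' path of a consensus phylogeny; 1 = oldest internode, \code{nStrata} =
#' the focal species' own stratum.
#'
#' @slot taxonToPs named integer vector, values in 1..nStrata
#' @slot nStrata integer, total number of phylostrata P (>= 2)
#' @export
setClass("LineageMap",
    representation(taxonToPs = "integer", nStrata = "integer"))

setValidity("LineageMap", function(object) {
    if (object@nStrata < 2L) return("nStrata must be >= 2")
    if (is.null(names(object@taxonToPs))) return("taxonToPs must be named")
    if (any(object@taxonToPs < 1L | object@taxonToPs > object@nStrata))
        return("taxonToPs values must lie in 1..nStrata")
    TRUE
})

#' @rdname LineageMap-class
#' @param taxonToPs named integer-like vector (taxon -> phylostratum)
#' @param nStrata total number of phylostrata; defaults to \code{max(taxonToPs)}
#' @export
LineageMap <- function(taxonToPs, nStrata = max(taxonToPs)) {
    v <- as.integer(round(taxonToPs))
    names(v) <- names(taxonToPs)
    new("LineageMap", taxonToPs = v, nStrata = as.integer(nStrata))
}

#' Gene-to-phylostratum assignment
#'
#' @slot ps named integer vector (gene -> phylostratum)
#' @slot unassigned character, genes with no qualifying hit (discarded from
#'   downstream indices)
#' @slot eCutoff numeric, the e-value cutoff used
#' @export
setClass("PhylostratumMap",
    representation(ps = "integer", unassigned = "character",
                   eCutoff = "numeric"))

setValidity("PhylostratumMap", function(object) {
    if (length(object@ps) && is.null(names(object@ps)))
        return("ps must be named by gene")
    if (length(intersect(names(object@ps), object@unassigned)))
        return("assigned and unassigned gene sets must be disjoint")
    TRUE
})

#' Flat-line permutation test result
#'
#' @slot observedVariance variance across stages of the observed index profile
#' @slot pValue empirical permutation p value, (1 + #{null >= obs})/(1 + n)
#' @slot pGamma p value from a gamma distribution fitted to the null
#'   variances (NA unless requested)
#' @slot nullBand data.frame with columns stage, mean, sd of the permuted
#'   profiles (one row per stage)
#' @slot nPermutations integer
#' @slot seed integer seed used
#' @slot profile the observed \linkS4class{IndexProfile}
#' @export
setClass("FlatLineResult",
    representation(observedVariance = "numeric", pValue = "numeric",
                   pGamma = "numeric", nullBand = "data.frame",
                   nPermutations = "integer", seed = "integer",
                   profile = "IndexProfile"))

setValidity("FlatLineResult", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    if (object@nPermutations < 100L)
        return("at least 100 permutations are required")
    if (nrow(object@nullBand) != length(object@profile@values))
        return("nullBand needs one row per stage")
    TRUE
})

#' Effect size (Hedges' g) with pooled t test
#'
#' @slot g Hedges' g with small-sample correction
#' @slot t pooled-variance t statistic
#' @slot df degrees of freedom (n1 + n2 - 2)
#' @slot p two-sided p value
#' @slot ci95 numeric length-2, 95 percent CI of the mean difference
#' @export
setClass("EffectSizeResult",
    representation(g = "numeric", t = "numeric", df = "integer",
                   p = "numeric", ci95 = "numeric"))

setValidity("EffectSizeResult", function(object) {
    if (length(object@ci95) != 2L || object@ci95[1] > object@ci95[2])
        return("ci95 must be (low, high) with low <= high")
    TRUE
})

#' Synthetic gene catalog with ground truth
#'
#' Ground-truth twin of \linkS4class{GeneEvolStats} produced by the simulator:
#' true phylostratum, CDS length, divergence rates, target codon bias and
#' sparse GO labels per gene.
#'
#' @slot genes \link[S4Vectors]{DataFrame} with columns \code{true_ps},
#'   \code{cds_length}, \code{dN}, \code{dS}, \code{target_enc} and a
#'   \code{go_terms} \link[IRanges]{CharacterList}; row names are gene ids
#' @slot nStrata integer, number of phylostrata simulated
#' @export
setClass("GeneCatalog",
    representation(genes = "DataFrame", nStrata = "integer"))

setValidity("GeneCatalog", function(object) {
    g <- object@genes
    need <- c("true_ps", "cds_length", "dN", "dS", "target_enc", "go_terms")
    if (!all(need %in% colnames(g)))
        return(paste("genes must have columns:", paste(need, collapse = ", ")))
    if (any(g$cds_length %% 3L != 0L))
        return("cds_length must be divisible by 3")
    if (any(!is.finite(g$dN)) || any(!is.finite(g$dS)))
        return("dN and dS must be finite")
    if (any(g$true_ps < 1L | g$true_ps > object@nStrata))
        return("true_ps outside 1..nStrata")
    if (any(g$target_enc < 20 | g$target_enc > 61))
        return("target_enc must lie in [20, 61]")
    TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "StageExpression", function(object) {
    cat("StageExpression:", nrow(object@values), "genes x",
        ncol(object@values), "stages\n")
    cat("  stages:", paste(object@stageOrder, collapse = " "), "\n")
})

setMethod("show", "StandardizedExpression", function(object) {
    a <- object@audit
    cat("StandardizedExpression:", nrow(object@values), "genes x",
        ncol(object@values), "stages (log2, median-centred)\n")
    cat(sprintf("  audit: %d discarded, %d interpolated, %d edge-filled, %d retained\n",
                a$discarded, a$interpolated, a$edge_filled, a$retained))
})

setMethod("show", "GeneEvolStats", function(object) {
    st <- object@stats
    have <- vapply(c("ps", "dN", "dS", "enc"), function(cn)
        if (cn %in% colnames(st)) sum(!is.na(st[[cn]])) else 0L, integer(1))
    cat("GeneEvolStats:", nrow(st), "genes\n")
    cat(sprintf("  ps: %d  dN: %d  dS: %d  enc: %d genes with values\n",
                have["ps"], have["dN"], have["dS"], have["enc"]))
})

setMethod("show", "IndexProfile", function(object) {
    cat(sprintf("IndexProfile (%s, n = %d genes)\n", object@weightName,
                object@nGenesUsed))
    print(round(object@values, 4))
})

setMethod("show", "PhylostratumMap", function(object) {
    cat("PhylostratumMap:", length(object@ps), "genes assigned,",
        length(object@unassigned), "unassigned (e <=",
        format(object@eCutoff), ")\n")
})

setMethod("show", "LineageMap", function(object) {
    cat("LineageMap:", length(object@taxonToPs), "taxa over",
        object@nStrata, "phylostrata\n")
})

setMethod("show", "FlatLineResult", function(object) {
    cat(sprintf("Flat-line test (%s): observed variance = %.4g, p = %.4g (%d permutations)\n",
                object@profile@weightName, object@observedVariance,
                object@pValue, object@nPermutations))
    if (!is.na(object@pGamma))
        cat(sprintf("  gamma-fit p = %.4g\n", object@pGamma))
})

setMethod("show", "EffectSizeResult", function(object) {
    cat(sprintf("Hedges' g = %.3f; t = %.3f, df = %d, p = %.4g; 95%% CI of difference [%.3f, %.3f]\n",
                object@g, object@t, object@df, object@p,
                object@ci95[1], object@ci95[2]))
})

setMethod("show", "GeneCatalog", function(object) {
    cat("GeneCatalog:", nrow(object@genes), "genes over", object@nStrata,
        "phylostrata\n")
})
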