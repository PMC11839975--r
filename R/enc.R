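## Wright's effective number of codons (Nc): codon-usage bias of a CDS,
## from 20 (one codon per amino acid, maximal bias) to 61 (uniform usage).

# Standard genetic code grouped into synonymous families. Leu/Ser/Arg are
# their own degeneracy-6 families; Met and Trp (single-codon) contribute the
# constant 2 in Nc; stops are not counted.
.CODON_FAMILIES <- list(
    Phe = c("TTT", "TTC"),
    Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    Ile = c("ATT", "ATC", "ATA"),
    Val = c("GTT", "GTC", "GTA", "GTG"),
    Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    Pro = c("CCT", "CCC", "CCA", "CCG"),
    Thr = c("ACT", "ACC", "ACA", "ACG"),
    Ala = c("GCT", "GCC", "GCA", "GCG"),
    Tyr = c("TAT", "TAC"),
    His = c("CAT", "CAC"),
    Gln = c("CAA", "CAG"),
    Asn = c("AAT", "AAC"),
    Lys = c("AAA", "AAG"),
    Asp = c("GAT", "GAC"),
    Glu = c("GAA", "GAG"),
    Cys = c("TGT", "TGC"),
    Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
    Gly = c("GGT", "GGC", "GGA", "GGG"))

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SINGLE_CODONS <- c("ATG", "TGG")

# class sizes in the Nc formula: 9 twofold + 1 threefold + 5 fourfold +
# 3 sixfold families (+ 2 for Met/Trp)
.FAMILY_DEGENERACY <- vapply(.CODON_FAMILIES, length, integer(1))

#' Effective number of codons (Wright's Nc)
#'
#' Computes \eqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}
#' where \eqn{\bar F_k} is the average codon homozygosity
#' \eqn{F = (n \sum \hat p^2 - 1)/(n - 1)} over the amino-acid families of
#' degeneracy \eqn{k} (Leu, Ser and Arg form the sixfold class). Families
#' observed at most once are excluded from their class average; a class with
#' no computable family is imputed - the threefold class (Ile) from the mean
#' of the two- and fourfold averages, any other class from the mean of the
#' computable class averages. The estimate is capped at 61.
#'
#' @param cds a single coding sequence: character string or
#'   \link[Biostrings]{DNAString}; length must be a multiple of 3. A trailing
#'   stop codon is allowed and not counted.
#' @param skipInvalid if TRUE, codons containing non-ACGT symbols or internal
#'   stops are skipped instead of raising an error
#' @return Nc in [20, 61]; attribute \code{"imputed"} lists imputed classes
#'   when any
#' @examples
#' # one codon per family used twice each -> maximal bias
#' cds <- paste(rep(vapply(devoTAI:::.CODON_FAMILIES, `[`, "", 1), 2),
#'              collapse = "")
#' effectiveNumberOfCodons(cds)  # 20
#' @export
effectiveNumberOfCodons <- function(cds, skipInvalid = FALSE) {
    if (inherits(cds, "DNAString")) cds <- as.character(cds)
    if (inherits(cds, "DNAStringSet")) {
        if (length(cds) != 1L)
            return(vapply(as.character(cds), effectiveNumberOfCodons,
                          numeric(1), skipInvalid = skipInvalid))
        cds <- as.character(cds[[1]])
    }
    stopifnot(is.character(cds), length(cds) == 1L)
    cds <- toupper(cds)
    if (nchar(cds) %% 3L != 0L) stop("CDS length must be a multiple of 3")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    if (length(codons) && codons[length(codons)] %in% .STOP_CODONS)
        codons <- codons[-length(codons)]
    known <- c(unlist(.CODON_FAMILIES, use.names = FALSE), .SINGLE_CODONS)
    bad <- !codons %in% known
    if (any(bad)) {
        if (!skipInvalid)
            stop("internal stop codon or non-ACGT codon at position(s) ",
                 paste(utils::head(which(bad), 5), collapse = ", "))
        codons <- codons[!bad]
    }
    counts <- table(factor(codons, levels = known))
    encFromCodonCounts(counts)
}

# Nc from a named codon-count vector (64 or 62 levels); shared with the
# simulator's realized-bias checks.
encFromCodonCounts <- function(counts) {
    famF <- vapply(names(.CODON_FAMILIES), function(fam) {
        n <- sum(counts[.CODON_FAMILIES[[fam]]])
        if (n <= 1L) return(NA_real_)
        p <- counts[.CODON_FAMILIES[[fam]]] / n
        (n * sum(p^2) - 1) / (n - 1)
    }, numeric(1))
    classAvg <- vapply(c(2L, 3L, 4L, 6L), function(k) {
        f <- famF[.FAMILY_DEGENERACY == k]
        f <- f[!is.na(f) & f > 0]
        if (!length(f)) NA_real_ else mean(f)
    }, numeric(1))
    names(classAvg) <- c("F2", "F3", "F4", "F6")
    imputed <- character(0)
    if (is.na(classAvg["F3"]) &&
        !is.na(classAvg["F2"]) && !is.na(classAvg["F4"])) {
        classAvg["F3"] <- mean(classAvg[c("F2", "F4")])
        imputed <- "F3"
    }
    if (anyNA(classAvg)) {
        miss <- names(classAvg)[is.na(classAvg)]
        if (all(is.na(classAvg)))
            stop("no codon family observed more than once: Nc undefined")
        classAvg[miss] <- mean(classAvg, na.rm = TRUE)
        imputed <- union(imputed, miss)
    }
    nc <- 2 + 9 / classAvg[["F2"]] + 1 / classAvg[["F3"]] +
        5 / classAvg[["F4"]] + 3 / classAvg[["F6"]]
    nc <- min(max(nc, 20), 61)
    if (length(imputed)) attr(nc, "imputed") <- imputed
    nc
}

#' ENC for every sequence of a CDS set
#'
#' @param cdsSet a \link[Biostrings]{DNAStringSet} (e.g. from
#'   \code{\link[Biostrings]{readDNAStringSet}}) or named character vector
#' @param skipInvalid passed to \code{\link{effectiveNumberOfCodons}}
#' @return named numeric vector of Nc values
#' @export
encProfile <- function(cdsSet, skipInvalid = FALSE) {
    if (inherits(cdsSet, "DNAStringSet")) {
        nm <- names(cdsSet)
        cdsSet <- as.character(cdsSet)
        names(cdsSet) <- nm
    }
    vapply(cdsSet, function(s)
        as.numeric(effectiveNumberOfCodons(s, skipInvalid = skipInvalid)),
        numeric(1))
}
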