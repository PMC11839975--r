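# Independent oracles and tiny fixture builders used across the suite.

# StageExpression straight from a matrix (bypasses normalization on purpose:
# index math is tested on raw values).
toyStageExpression <- function(m) {
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
    new("StageExpression", values = m, stageOrder = colnames(m))
}

# Naive loop-based weighted transcriptome index (the formula transcribed
# directly, no matrix algebra shared with the implementation).
oracleWeightedIndex <- function(e, w) {
    out <- numeric(ncol(e))
    for (s in seq_len(ncol(e))) {
        num <- 0; den <- 0
        for (i in seq_len(nrow(e))) {
            num <- num + w[i] * e[i, s]
            den <- den + e[i, s]
        }
        out[s] <- num / den
    }
    out
}

# Brute-force ENC: tabulate codons with table(), loop over families, apply
# the homozygosity formula directly, impute per the documented conventions.
oracleEnc <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    fams <- list(
        c("TTT", "TTC"), c("TAT", "TAC"), c("CAT", "CAC"), c("CAA", "CAG"),
        c("AAT", "AAC"), c("AAA", "AAG"), c("GAT", "GAC"), c("GAA", "GAG"),
        c("TGT", "TGC"),
        c("ATT", "ATC", "ATA"),
        c("GTT", "GTC", "GTA", "GTG"), c("CCT", "CCC", "CCA", "CCG"),
        c("ACT", "ACC", "ACA", "ACG"), c("GCT", "GCC", "GCA", "GCG"),
        c("GGT", "GGC", "GGA", "GGG"),
        c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
        c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
        c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
    deg <- sapply(fams, length)
    tab <- table(codons)
    Fs <- rep(NA_real_, length(fams))
    for (fi in seq_along(fams)) {
        n <- 0; ssq <- 0
        cnt <- numeric(length(fams[[fi]]))
        for (ci in seq_along(fams[[fi]])) {
            cd <- fams[[fi]][ci]
            cnt[ci] <- if (cd %in% names(tab)) tab[[cd]] else 0
        }
        n <- sum(cnt)
        if (n > 1) {
            p <- cnt / n
            Fs[fi] <- (n * sum(p^2) - 1) / (n - 1)
        }
    }
    avg <- function(k) {
        f <- Fs[deg == k]; f <- f[!is.na(f) & f > 0]
        if (length(f)) mean(f) else NA_real_
    }
    F2 <- avg(2); F3 <- avg(3); F4 <- avg(4); F6 <- avg(6)
    if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
    cls <- c(F2 = F2, F3 = F3, F4 = F4, F6 = F6)
    if (any(is.na(cls))) cls[is.na(cls)] <- mean(cls, na.rm = TRUE)
    min(61, 2 + 9 / cls["F2"] + 1 / cls["F3"] + 5 / cls["F4"] + 3 / cls["F6"])
}

# Exact two-sided hypergeometric p by direct enumeration with choose().
oracleHyper2s <- function(k, K, n, N) {
    support <- max(0, n - (N - K)):min(n, K)
    pj <- sapply(support, function(j)
        choose(K, j) * choose(N - K, n - j) / choose(N, n))
    pk <- pj[match(k, support)]
    min(1, sum(pj[pj <= pk * (1 + 1e-7)]))
}

# Step-up BH oracle applied literally to the definition.
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (r in m:1) {
        val <- min(prev, p[ord[r]] * m / r)
        adj[ord[r]] <- val
        prev <- val
    }
    adj
}

# Pooled-SD Hedges' g oracle written straight from the formula.
oracleHedges <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
    J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
    J * (mean(b) - mean(a)) / sp
}

# Exhaustive RBH oracle: enumerate all pairs, check mutual-best directly.
oracleRBH <- function(score) {
    pairs <- list()
    for (a in rownames(score)) {
        sa <- score[a, ]
        bestB <- colnames(score)[order(-sa, colnames(score))[1]]
        sb <- score[, bestB]
        bestA <- rownames(score)[order(-sb, rownames(score))[1]]
        if (bestA == a) pairs[[length(pairs) + 1]] <- c(a, bestB)
    }
    do.call(rbind, pairs)
}

# Random codon strings built only from sense codons (no stops).
randomCds <- function(nCodons, seed) {
    set.seed(seed)
    sense <- setdiff(
        apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                          c("T", "C", "A", "G")), 1, paste, collapse = ""),
        c("TAA", "TAG", "TGA", "ATG", "TGG"))
    paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}
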