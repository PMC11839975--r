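## Synthetic-data generator: developmental count matrices with a tunable
## hourglass signal, age-coupled divergence rates, homology hit tables
## consistent with true gene ages, and CDS with prescribed codon bias.
## Every generator is fully reproducible from its seed, and ground truth
## (true phylostrata, designed stage means) is returned alongside the data.

#' Simulation configuration
#'
#' Study conditions for the synthetic developmental series. Defaults emulate
#' a 12-stage somatic-embryogenesis series (early induction through juvenile
#' plant) with 3 replicates per stage except 5 for the C2 and EP stages, 18
#' phylostrata, and an hourglass centred on the heart stage (H).
#'
#' @slot nGenes number of genes
#' @slot nStrata number of phylostrata P (>= 2)
#' @slot stages ordered stage labels
#' @slot repsPerStage integer vector (recycled) of replicates per stage
#' @slot phylotypicStage stage at which old genes peak
#' @slot effectSize log2-scale boost of old-gene expression at the
#'   phylotypic stage and of young-gene expression at the series ends;
#'   0 = age-independent expression
#' @slot dispersion negative-binomial size parameter theta
#'   (var = mu + mu^2/theta); large theta approaches Poisson noise
#' @slot seed integer seed
#' @export
setClass("SimulationConfig",
    representation(nGenes = "integer", nStrata = "integer",
                   stages = "character", repsPerStage = "integer",
                   phylotypicStage = "character", effectSize = "numeric",
                   dispersion = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nGenes < 2L) return("nGenes must be >= 2")
    if (object@nStrata < 2L) return("nStrata must be >= 2")
    if (length(object@stages) < 2L) return("need at least 2 stages")
    if (anyDuplicated(object@stages)) return("stage labels must be unique")
    if (!object@phylotypicStage %in% object@stages)
        return("phylotypicStage must be one of the stages")
    if (length(object@repsPerStage) != length(object@stages))
        return("repsPerStage must align with stages")
    if (any(object@repsPerStage < 1L)) return("repsPerStage must be positive")
    if (object@effectSize < 0) return("effectSize must be non-negative")
    if (object@dispersion <= 0) return("dispersion must be positive")
    TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: %d genes, %d phylostrata, %d stages (phylotypic = %s), effect size %.2f, theta %.2f, seed %d\n",
                object@nGenes, object@nStrata, length(object@stages),
                object@phylotypicStage, object@effectSize,
                object@dispersion, object@seed))
})

#' @rdname SimulationConfig-class
#' @param nGenes,nStrata,stages,repsPerStage,phylotypicStage,effectSize,dispersion,seed
#'   see the slots above
#' @export
simulationConfig <- function(nGenes = 5000,
                             nStrata = 18,
                             stages = c("EI", "PG", "G1", "G2", "H", "T1",
                                        "T2", "C1", "C2", "S", "EP", "JP"),
                             repsPerStage = NULL,
                             phylotypicStage = "H",
                             effectSize = 2,
                             dispersion = 5,
                             seed = 1L) {
    if (length(nGenes) != 1L || !is.finite(nGenes) || nGenes < 2)
        stop("nGenes must be a positive integer >= 2")
    if (length(nStrata) != 1L || !is.finite(nStrata) || nStrata < 2)
        stop("nStrata must be an integer >= 2")
    if (is.null(repsPerStage)) {
        repsPerStage <- ifelse(stages %in% c("C2", "EP"), 5L, 3L)
        if (!all(c("C2", "EP") %in% stages)) repsPerStage <- rep(3L, length(stages))
    }
    repsPerStage <- rep(as.integer(repsPerStage), length.out = length(stages))
    new("SimulationConfig", nGenes = as.integer(nGenes),
        nStrata = as.integer(nStrata), stages = as.character(stages),
        repsPerStage = repsPerStage,
        phylotypicStage = as.character(phylotypicStage),
        effectSize = as.numeric(effectSize),
        dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

#' Simulate a gene catalog with ground-truth evolutionary attributes
#'
#' Draws per-gene true phylostrata (older strata more populated, as in real
#' phylostratigraphic maps), CDS lengths, gamma-distributed dN and dS whose
#' expectations increase with phylostratum (younger genes more diverged),
#' target ENC increasing with phylostratum (older genes more codon-biased),
#' and sparse GO-like labels.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param nTerms size of the annotation-term pool
#' @return a \linkS4class{GeneCatalog}
#' @export
simulateGeneCatalog <- function(config, nTerms = 50L) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed)
    P <- config@nStrata
    n <- config@nGenes
    psProb <- exp(-0.1 * (seq_len(P) - 1))
    truePs <- sample.int(P, n, replace = TRUE, prob = psProb)
    rel <- (truePs - 1) / (P - 1)              # 0 = oldest, 1 = youngest
    dN <- stats::rgamma(n, shape = 2, scale = 0.05 + 0.15 * rel)
    dS <- stats::rgamma(n, shape = 2, scale = 0.5 + 1.0 * rel)
    targetEnc <- pmin(61, pmax(20, 35 + 20 * rel + stats::rnorm(n, 0, 2)))
    cdsLen <- 3L * sample(100:600, n, replace = TRUE)
    terms <- sprintf("TERM%04d", seq_len(nTerms))
    nAnn <- stats::rpois(n, 1.5)
    go <- lapply(nAnn, function(m) sample(terms, min(m, nTerms)))
    ids <- sprintf("g%05d", seq_len(n))
    df <- S4Vectors::DataFrame(
        true_ps = as.integer(truePs), cds_length = cdsLen,
        dN = dN, dS = dS, target_enc = targetEnc,
        go_terms = IRanges::CharacterList(go),
        row.names = ids)
    new("GeneCatalog", genes = df, nStrata = P)
}

# Gaussian bump over stage index centred on the phylotypic stage; the
# hourglass is bump for old genes and its complement for young genes.
stageBump <- function(stages, phylotypicStage) {
    s0 <- match(phylotypicStage, stages)
    idx <- seq_along(stages)
    sigma <- length(stages) / 6
    exp(-((idx - s0)^2) / (2 * sigma^2))
}

#' Simulate a developmental count matrix with a designed hourglass
#'
#' Per-gene log2 baselines are Normal; with \code{effectSize > 0} genes of
#' low true phylostratum (old) get a Gaussian expression bump centred on the
#' phylotypic stage and young genes get its complement (peaks at the series
#' ends), each scaled by the gene's age and the effect size. Counts are
#' negative-binomial draws around the designed stage means with log-normal
#' library sizes. With \code{effectSize = 0} stage means are exchangeable
#' across stages.
#'
#' @param catalog a \linkS4class{GeneCatalog}
#' @param config the \linkS4class{SimulationConfig} used for the catalog
#' @return list with \code{counts} (a \linkS4class{StageCounts}) and
#'   \code{stageMeans} (gene x stage matrix of designed mean expression
#'   fractions, the ground truth)
#' @export
simulateCounts <- function(catalog, config) {
    stopifnot(is(catalog, "GeneCatalog"), is(config, "SimulationConfig"))
    if (nrow(catalog@genes) != config@nGenes)
        stop("catalog and config disagree on the number of genes")
    set.seed(config@seed + 1L)
    g <- catalog@genes
    n <- nrow(g)
    stages <- config@stages
    P <- config@nStrata
    age <- (P - g$true_ps) / (P - 1)           # 1 = oldest, 0 = youngest
    bump <- stageBump(stages, config@phylotypicStage)
    base <- stats::rnorm(n, mean = 5, sd = 1.5)
    log2mu <- outer(base, rep(0, length(stages)), "+") +
        config@effectSize * (age %o% bump + (1 - age) %o% (1 - bump))
    mu <- 2^log2mu
    frac <- sweep(mu, 2, colSums(mu), "/")     # designed expression fractions
    dimnames(frac) <- list(rownames(g), stages)
    reps <- config@repsPerStage
    sampleStage <- rep(stages, reps)
    sampleRep <- unlist(lapply(reps, seq_len))
    sampleIds <- paste0(sampleStage, "_r", sampleRep)
    lib <- stats::rlnorm(length(sampleIds), meanlog = log(3e6), sdlog = 0.2)
    counts <- matrix(0L, n, length(sampleIds),
                     dimnames = list(rownames(g), sampleIds))
    for (j in seq_along(sampleIds)) {
        m <- frac[, sampleStage[j]] * lib[j]
        counts[, j] <- stats::rnbinom(n, mu = m, size = config@dispersion)
    }
    sc <- StageCounts(counts, stage = factor(sampleStage, levels = stages),
                      replicate = sampleRep,
                      geneLengths = stats::setNames(g$cds_length, rownames(g)))
    list(counts = sc, stageMeans = frac)
}

#' Simulate a homology hit table consistent with true gene ages
#'
#' Each gene hits \code{taxaPerPs} taxa in every phylostratum from its true
#' origin through the focal stratum, with e-values drawn log-uniform in
#' [1e-30, 1e-5] (well under the generating cutoff of 1e-3), so the
#' oldest-hit rule at that cutoff recovers \code{true_ps} exactly when
#' \code{noise = 0}. With probability \code{noise} a gene additionally gets
#' one spurious hit to a phylostratum-1 taxon, so the expected mis-ageing
#' rate is \code{noise} times the fraction of genes with \code{true_ps > 1}.
#'
#' @param catalog a \linkS4class{GeneCatalog}
#' @param taxaPerPs taxa per phylostratum (>= 1)
#' @param noise spurious-hit probability per gene, in [0, 1]
#' @param seed integer seed
#' @return list with \code{hits} (data.frame query/taxon/e_value),
#'   \code{lineage} (the matching \linkS4class{LineageMap}) and
#'   \code{generatingCutoff} (1e-3)
#' @export
simulateHitTable <- function(catalog, taxaPerPs = 2L, noise = 0, seed = 1L) {
    stopifnot(is(catalog, "GeneCatalog"))
    if (taxaPerPs < 1L) stop("taxaPerPs must be >= 1")
    if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
    set.seed(seed)
    P <- catalog@nStrata
    taxa <- outer(seq_len(P), seq_len(taxaPerPs),
                  function(p, t) sprintf("ps%02d_t%d", p, t))
    lineage <- LineageMap(stats::setNames(rep(seq_len(P), taxaPerPs),
                                          as.vector(taxa)), nStrata = P)
    g <- catalog@genes
    rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
        strata <- g$true_ps[i]:P
        tx <- as.vector(taxa[strata, , drop = FALSE])
        ev <- 10^stats::runif(length(tx), -30, -5)
        if (noise > 0 && stats::runif(1) < noise) {
            tx <- c(tx, taxa[1L, sample.int(taxaPerPs, 1)])
            ev <- c(ev, 10^stats::runif(1, -30, -5))
        }
        rows[[i]] <- data.frame(query = rownames(g)[i], taxon = tx,
                                e_value = ev, stringsAsFactors = FALSE)
    }
    list(hits = do.call(rbind, rows), lineage = lineage,
         generatingCutoff = 1e-3)
}

# Expected codon homozygosity of a degeneracy-k family under the biased
# mixture: first codon has probability a + (1-a)/k, the rest (1-a)/k.
.familyFexpected <- function(a, k) {
    p1 <- a + (1 - a) / k
    p1^2 + (k - 1) * ((1 - a) / k)^2
}

.encExpected <- function(a) {
    2 + 9 / .familyFexpected(a, 2) + 1 / .familyFexpected(a, 3) +
        5 / .familyFexpected(a, 4) + 3 / .familyFexpected(a, 6)
}

# Observed homozygosity of one family's codon-count composition.
.famFFromComp <- function(comp) {
    n <- sum(comp)
    if (n <= 1) return(NA_real_)
    p <- comp / n
    (n * sum(p^2) - 1) / (n - 1)
}

# Nc from per-family homozygosities, using the same class-average and
# imputation conventions as the ENC estimator.
.ncFromFamF <- function(famF) {
    classAvg <- vapply(c(2L, 3L, 4L, 6L), function(k) {
        f <- famF[.FAMILY_DEGENERACY == k]
        f <- f[!is.na(f) & f > 0]
        if (!length(f)) NA_real_ else mean(f)
    }, numeric(1))
    names(classAvg) <- c("F2", "F3", "F4", "F6")
    if (is.na(classAvg["F3"]) && !is.na(classAvg["F2"]) &&
        !is.na(classAvg["F4"]))
        classAvg["F3"] <- mean(classAvg[c("F2", "F4")])
    if (anyNA(classAvg)) {
        if (all(is.na(classAvg))) return(NA_real_)
        classAvg[is.na(classAvg)] <- mean(classAvg, na.rm = TRUE)
    }
    nc <- 2 + 9 / classAvg[["F2"]] + 1 / classAvg[["F3"]] +
        5 / classAvg[["F4"]] + 3 / classAvg[["F6"]]
    min(max(nc, 20), 61)
}

# Greedy refinement: single-unit moves within families (toward or away from
# concentration), chosen to pull the realized Nc to the target.
.refineComps <- function(comps, target, tol = 0.25, maxIter = 200L) {
    famF <- vapply(comps, .famFFromComp, numeric(1))
    nc <- .ncFromFamF(famF)
    for (it in seq_len(maxIter)) {
        if (is.na(nc) || abs(nc - target) <= tol) break
        bestErr <- abs(nc - target)
        bestFi <- 0L; bestComp <- NULL; bestF <- NA_real_; bestNc <- NA_real_
        for (fi in seq_along(comps)) {
            cc <- comps[[fi]]
            k <- length(cc)
            if (sum(cc) <= 1L) next
            for (dir in c(1L, -1L)) {
                cand <- cc
                i <- which.max(cand)
                if (dir == 1L) {               # toward concentration
                    rest <- setdiff(seq_len(k), i)
                    rest <- rest[cand[rest] > 0L]
                    if (!length(rest)) next
                    j <- rest[which.min(cand[rest])]
                    cand[i] <- cand[i] + 1L; cand[j] <- cand[j] - 1L
                } else {                       # toward uniformity
                    j <- which.min(cand)
                    if (i == j || cand[i] - cand[j] <= 1L) next
                    cand[i] <- cand[i] - 1L; cand[j] <- cand[j] + 1L
                }
                f2 <- famF
                f2[fi] <- .famFFromComp(cand)
                nc2 <- .ncFromFamF(f2)
                if (!is.na(nc2) && abs(nc2 - target) < bestErr) {
                    bestErr <- abs(nc2 - target)
                    bestFi <- fi; bestComp <- cand
                    bestF <- f2[fi]; bestNc <- nc2
                }
            }
        }
        if (bestFi == 0L) break
        comps[[bestFi]] <- bestComp
        famF[bestFi] <- bestF
        nc <- bestNc
    }
    comps
}

# Solve for the bias-mixture parameter whose expected Nc equals the target.
.biasForTargetEnc <- function(targetEnc) {
    if (targetEnc >= 61) return(0)
    if (targetEnc <= 20) return(1)
    stats::uniroot(function(a) .encExpected(a) - targetEnc,
                   interval = c(0, 1), tol = 1e-10)$root
}

# Integer composition of n codons over a degeneracy-k family whose observed
# homozygosity sum(p_hat^2) is as close as possible to S: start from the
# balanced split (minimal sum of squares) and move one unit at a time from
# the least- to the most-loaded codon (each move strictly increases the sum
# of squares), keeping the closest composition visited.
.composeFamilyCounts <- function(n, k, S) {
    cur <- rep(n %/% k, k)
    r <- n %% k
    if (r > 0) cur[seq_len(r)] <- cur[seq_len(r)] + 1L
    score <- function(cc) sum((cc / n)^2)
    best <- cur; bestErr <- abs(score(cur) - S)
    while (score(cur) < S) {
        i <- which.max(cur)
        rest <- setdiff(seq_len(k), i)
        rest <- rest[cur[rest] > 0L]
        if (!length(rest)) break
        j <- rest[which.min(cur[rest])]
        cur[i] <- cur[i] + 1L; cur[j] <- cur[j] - 1L
        err <- abs(score(cur) - S)
        if (err < bestErr) { best <- cur; bestErr <- err }
    }
    best
}

#' Simulate coding sequences with prescribed codon bias
#'
#' Emits one CDS per catalog gene of its \code{cds_length}. Codon usage per
#' amino-acid family follows a mixture between uniform usage (ENC 61) and a
#' single preferred codon (ENC 20) whose mixing weight solves the gene's
#' \code{target_enc}; codon counts are then composed so the realized family
#' homozygosities match the mixture's, which keeps the realized ENC within a
#' fraction of a unit of the target even for short sequences. Amino acids
#' are spread evenly over the 18 degenerate families, the preferred codon of
#' each family and the codon order are randomized from the seed, and no
#' stop codons are produced.
#'
#' @param catalog a \linkS4class{GeneCatalog}
#' @param seed integer seed
#' @return a \link[Biostrings]{DNAStringSet} named by gene id
#' @export
simulateCds <- function(catalog, seed = 1L) {
    stopifnot(is(catalog, "GeneCatalog"))
    set.seed(seed)
    g <- catalog@genes
    fams <- .CODON_FAMILIES
    nfam <- length(fams)
    degs <- .FAMILY_DEGENERACY
    seqs <- character(nrow(g))
    for (i in seq_len(nrow(g))) {
        a <- .biasForTargetEnc(g$target_enc[i])
        nCodons <- g$cds_length[i] %/% 3L
        nPerFam <- rep(nCodons %/% nfam, nfam)
        extra <- nCodons %% nfam
        if (extra > 0) {
            pick <- sample.int(nfam, extra)
            nPerFam[pick] <- nPerFam[pick] + 1L
        }
        comps <- vector("list", nfam)
        for (fi in seq_len(nfam)) {
            nf <- nPerFam[fi]
            k <- degs[fi]
            if (nf == 0L) { comps[[fi]] <- integer(k); next }
            # target the observed homozygosity F, not sum(p^2): with fixed
            # counts there is no multinomial inflation to correct for
            Ft <- .familyFexpected(a, k)
            S <- min(1, (Ft * (nf - 1) + 1) / nf)
            comps[[fi]] <- .composeFamilyCounts(nf, k, S)
        }
        comps <- .refineComps(comps, g$target_enc[i])
        codons <- character(0)
        for (fi in seq_len(nfam)) {
            if (!sum(comps[[fi]])) next
            codonSet <- sample(fams[[fi]])   # seeded preferred-codon choice
            codons <- c(codons, rep(codonSet, comps[[fi]]))
        }
        seqs[i] <- paste(sample(codons), collapse = "")
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- rownames(g)
    out
}

#' Ground-truth GeneEvolStats from a catalog
#'
#' Convenience view of the simulator's ground truth in the container the
#' index functions consume (true phylostrata, dN, dS, target ENC).
#'
#' @param catalog a \linkS4class{GeneCatalog}
#' @return a \linkS4class{GeneEvolStats}
#' @export
catalogEvolStats <- function(catalog) {
    stopifnot(is(catalog, "GeneCatalog"))
    g <- catalog@genes
    GeneEvolStats(rownames(g), ps = g$true_ps, dN = g$dN, dS = g$dS,
                  enc = g$target_enc)
}
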