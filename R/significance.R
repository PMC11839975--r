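## Permutation significance of index-profile shape and small-sample effect
## sizes.

#' Flat-line permutation test
#'
#' Tests whether a weighted transcriptome index profile deviates from a flat
#' line. The statistic is the variance across stages of the observed profile;
#' the null is built by permuting the gene-level weights across genes while
#' keeping the stage-wise expression structure fixed, so only the
#' age(weight)-expression association is tested. The default p value is the
#' empirical permutation p with the +1 correction,
#' \eqn{p = (1 + \#\{V_{null} \ge V_{obs}\})/(1 + n_{perm})}; a gamma
#' distribution fitted to the null variances is available as an alternative
#' (\code{gammaFit = TRUE}). The per-stage mean and standard deviation of the
#' permuted profiles form the null band used for plotting.
#'
#' @param expr a \linkS4class{StageExpression}
#' @param weights named numeric gene-level weights (e.g. phylostrata, dN)
#' @param nPerm number of permutations (>= 100)
#' @param seed integer seed (mandatory for reproducibility)
#' @param gammaFit also compute a gamma-fit p value on the null variances
#' @param weightName label for the underlying index
#' @return a \linkS4class{FlatLineResult}
#' @export
flatLineTest <- function(expr, weights, nPerm = 1000L, seed,
                         gammaFit = FALSE, weightName = "weight") {
    stopifnot(is(expr, "StageExpression"))
    if (missing(seed)) stop("'seed' is required")
    nPerm <- as.integer(nPerm)
    if (nPerm < 100L) stop("at least 100 permutations are required")
    if (ncol(expr@values) < 2L) stop("need at least 2 stages")
    obs <- weightedTranscriptomeIndex(expr, weights, weightName = weightName)
    common <- intersect(rownames(expr@values), names(weights))
    common <- common[!is.na(weights[common])]
    if (length(common) < 2L) stop("need at least 2 genes with weights")
    e <- expr@values[common, , drop = FALSE]
    w <- as.numeric(weights[common])
    eNorm <- sweep(e, 2, colSums(e), "/")      # stage columns sum to 1
    obsVar <- stats::var(obs@values)
    set.seed(seed)
    perm <- matrix(0, nrow = length(w), ncol = nPerm)
    for (j in seq_len(nPerm)) perm[, j] <- w[sample.int(length(w))]
    nullProfiles <- crossprod(eNorm, perm)     # stages x nPerm
    nullVar <- apply(nullProfiles, 2, stats::var)
    # a profile whose sd is < 1e-8 of its level is flat up to round-off
    # (e.g. constant weights); clamp so such variances compare as equal
    flatEps <- (1e-8 * mean(abs(obs@values)))^2
    obsVar <- if (obsVar < flatEps) 0 else obsVar
    nullVar[nullVar < flatEps] <- 0
    p <- (1 + sum(nullVar >= obsVar)) / (1 + nPerm)
    pGamma <- NA_real_
    if (gammaFit) {
        pGamma <- tryCatch({
            fit <- suppressWarnings(MASS::fitdistr(nullVar, "gamma"))
            stats::pgamma(obsVar, shape = fit$estimate["shape"],
                          rate = fit$estimate["rate"], lower.tail = FALSE)
        }, error = function(e) {
            warning("gamma fit failed: ", conditionMessage(e))
            NA_real_
        })
        if (!is.na(pGamma)) pGamma <- max(pGamma, .Machine$double.xmin)
    }
    band <- data.frame(stage = colnames(e),
                       mean = rowMeans(nullProfiles),
                       sd = apply(nullProfiles, 1, stats::sd))
    new("FlatLineResult", observedVariance = obsVar, pValue = p,
        pGamma = pGamma, nullBand = band, nPermutations = nPerm,
        seed = as.integer(seed), profile = obs)
}

#' Hedges' g with pooled two-sided t test
#'
#' Standardized mean difference with the small-sample correction
#' \eqn{J = 1 - 3/(4(n_1 + n_2 - 2) - 1)}:
#' \eqn{g = J (\bar b - \bar a)/s_{pooled}}. Also reports the two-sided
#' pooled-variance Student t test and the 95 percent confidence interval of
#' the mean difference. Swapping the samples flips the sign of g.
#'
#' @param a,b numeric samples (n >= 2 each); the difference is b - a
#' @return an \linkS4class{EffectSizeResult}
#' @examples
#' hedgesG(c(30, 31, 35), c(60, 64, 68))
#' @export
hedgesG <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2L || n2 < 2L) stop("both samples need at least 2 observations")
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
    if (sp2 == 0) stop("zero pooled variance: effect size undefined")
    sp <- sqrt(sp2)
    J <- 1 - 3 / (4 * df - 1)
    g <- J * (mean(b) - mean(a)) / sp
    se <- sp * sqrt(1 / n1 + 1 / n2)
    t <- (mean(b) - mean(a)) / se
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    crit <- stats::qt(0.975, df)
    ci <- (mean(b) - mean(a)) + c(-1, 1) * crit * se
    new("EffectSizeResult", g = g, t = t, df = as.integer(df), p = p,
        ci95 = ci)
}
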