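test_that("weighted transcriptome index equals the hand weighted mean", {
    e <- toyStageExpression(matrix(c(1, 3), 2, 1,
                                   dimnames = list(c("a", "b"), "S1")))
    p <- weightedTranscriptomeIndex(e, c(a = 1, b = 5))
    expect_equal(unname(profileValues(p)), 4)  # (1*1 + 3*5)/(1+3)
    # constant weights give a constant profile
    e2 <- toyStageExpression(matrix(runif(20, 1, 5), 5, 4))
    pc <- weightedTranscriptomeIndex(e2, setNames(rep(7, 5), rownames(exprValues(e2))))
    expect_equal(unname(profileValues(pc)), rep(7, 4))
    # per-stage rescaling cancels
    v <- exprValues(e2); v[, 2] <- v[, 2] * 10
    w <- setNames(1:5, rownames(v))
    expect_equal(profileValues(weightedTranscriptomeIndex(toyStageExpression(v), w)),
                 profileValues(weightedTranscriptomeIndex(e2, w)))
})

test_that("indices match the naive loop oracle and stay within weight bounds", {
    set.seed(7)
    for (rep in 1:20) {
        e <- matrix(runif(50 * 12, 0.01, 2), 50, 12,
                    dimnames = list(paste0("g", 1:50), paste0("S", 1:12)))
        w <- setNames(sample(1:18, 50, replace = TRUE), rownames(e))
        p <- weightedTranscriptomeIndex(toyStageExpression(e), w)
        expect_equal(unname(profileValues(p)), oracleWeightedIndex(e, w),
                     tolerance = 1e-12)
        expect_true(all(profileValues(p) >= min(w) - 1e-12))
        expect_true(all(profileValues(p) <= max(w) + 1e-12))
    }
})

test_that("raising the expression of an above-average-weight gene raises the index", {
    set.seed(8)
    e <- matrix(runif(30, 0.1, 1), 10, 3,
                dimnames = list(paste0("g", 1:10), paste0("S", 1:3)))
    w <- setNames(1:10, rownames(e))
    p0 <- profileValues(weightedTranscriptomeIndex(toyStageExpression(e), w))
    heavy <- names(which.max(w))  # weight above every stage's index value
    e2 <- e; e2[heavy, 1] <- e2[heavy, 1] * 3
    p1 <- profileValues(weightedTranscriptomeIndex(toyStageExpression(e2), w))
    expect_gt(p1[1], p0[1])
    expect_equal(p1[-1], p0[-1])
})

test_that("tai/tdni/tdsi/tcbi select their weights and report gene counts", {
    set.seed(9)
    genes <- paste0("g", 1:30)
    e <- toyStageExpression(matrix(runif(90, 0.1, 1), 30, 3,
                                   dimnames = list(genes, paste0("S", 1:3))))
    evol <- GeneEvolStats(genes,
                          ps = sample(1:18, 30, TRUE),
                          dN = c(runif(20), rep(NA, 10)),
                          dS = runif(30),
                          enc = runif(30, 20, 61))
    expect_equal(nGenesUsed(tai(e, evol)), 30L)
    expect_equal(nGenesUsed(tdni(e, evol)), 20L)  # NA-weight genes excluded
    expect_identical(weightName(tdsi(e, evol)), "dS")
    expect_identical(weightName(tcbi(e, evol)), "enc")
    # all genes in one stratum -> constant TAI
    ev5 <- GeneEvolStats(genes, ps = rep(5, 30))
    expect_equal(unname(profileValues(tai(e, ev5))), rep(5, 3))
})

test_that("cumulative TAI restricts strata and reproduces tai at k = P", {
    set.seed(10)
    genes <- paste0("g", 1:40)
    e <- toyStageExpression(matrix(runif(120, 0.1, 1), 40, 3,
                                   dimnames = list(genes, paste0("S", 1:3))))
    ps <- setNames(sample(1:6, 40, TRUE), genes)
    evol <- GeneEvolStats(genes, ps = ps)
    expect_equal(profileValues(cumulativeTai(e, evol, 6)),
                 profileValues(tai(e, evol)))
    expect_equal(unname(profileValues(cumulativeTai(e, evol, 1))),
                 rep(1, 3))
    # k = 3 equals a direct computation on the restricted set
    sub <- names(ps)[ps <= 3]
    expect_equal(profileValues(cumulativeTai(e, evol, 3)),
                 profileValues(weightedTranscriptomeIndex(
                     toyStageExpression(exprValues(e)[sub, ]), ps[sub])))
    expect_error(cumulativeTai(e, evol, 0.5), "k >= 1")
    ev9 <- GeneEvolStats(genes, ps = rep(9, 40))
    expect_error(cumulativeTai(e, ev9, 2), "no genes with ps <= 2")
})

test_that("min-max normalization maps profiles onto [0, 1]", {
    p <- new("IndexProfile", values = c(A = 2, B = 5, C = 3),
             nGenesUsed = 10L, weightName = "ps")
    np <- minMaxNormalizeProfile(p)
    expect_equal(unname(profileValues(np)), c(0, 1, 1 / 3))
    flat <- new("IndexProfile", values = c(A = 2, B = 2), nGenesUsed = 2L,
                weightName = "ps")
    expect_error(minMaxNormalizeProfile(flat), "constant")
})

test_that("relative expression min-max scales stratum means across stages", {
    genes <- c("g1", "g2", "g3", "g4")
    e <- toyStageExpression(matrix(c(1, 2, 3,
                                     1, 2, 5,
                                     1, 1, 4,
                                     2, 2, 2), 4, 3, byrow = TRUE,
                                   dimnames = list(genes, c("A", "B", "C"))))
    evol <- GeneEvolStats(genes, ps = c(1, 1, 2, 2))
    re <- relativeExpression(e, evol)
    # hand oracle: stratum 1 means (1, 2, 4) -> RE (0, 1/3, 1);
    # stratum 2 means (1.5, 1.5, 3) -> RE (0, 0, 1)
    expect_equal(unname(re["ps1", ]), c(0, 1 / 3, 1))
    expect_equal(unname(re["ps2", ]), c(0, 0, 1))
    expect_true(all(re >= 0 & re <= 1))
    expect_equal(unname(apply(re, 1, min)), rep(0, nrow(re)))
    expect_equal(unname(apply(re, 1, max)), rep(1, nrow(re)))
})

test_that("constant stratum mean row is an error, not a silent zero", {
    genes <- c("g1", "g2")
    e <- toyStageExpression(matrix(c(1, 1, 1, 2, 2, 2), 2, 3, byrow = TRUE,
                                   dimnames = list(genes, c("A", "B", "C"))))
    evol <- GeneEvolStats(genes, ps = c(1, 1))
    expect_error(relativeExpression(e, evol), "constant")
})

test_that("divergence tables round-trip and reject malformed input", {
    tmp <- tempfile(fileext = ".tsv")
    df <- data.frame(gene = c("g1", "g2"), dN = c(0.1, 0.2),
                     dS = c(1.1, 2.2))
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    div <- readDivergenceTable(tmp)
    expect_equal(div$dN, c(g1 = 0.1, g2 = 0.2))
    expect_equal(div$dS, c(g1 = 1.1, g2 = 2.2))
    dup <- rbind(df, df[1, ])
    write.table(dup, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readDivergenceTable(tmp), "duplicate")
    bad <- data.frame(gene = "g1", dN = -1, dS = 0.5)
    write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readDivergenceTable(tmp), "line")
})
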