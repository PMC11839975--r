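test_that("fraction-of-transcripts normalization matches hand computation", {
    m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s1"))
    sc <- StageCounts(m, stage = "A", replicate = 1,
                      geneLengths = c(a = 2000, b = 1000))
    expect_equal(unname(normalizeFractions(sc, useLengths = FALSE)[, 1]),
                 c(0.25, 0.75))
    # (c/l)/sum(c/l): (10/2000, 30/1000) -> (1/7, 6/7)
    expect_equal(unname(normalizeFractions(sc, useLengths = TRUE)[, 1]),
                 c(1 / 7, 6 / 7))
    one <- StageCounts(matrix(7, 1, 1, dimnames = list("g", "s")),
                       stage = "A", replicate = 1)
    expect_equal(unname(normalizeFractions(one)[, 1]), 1)
    # every sample column sums to one
    m2 <- matrix(rpois(30, 20) + 1, 5, 6)
    sc2 <- StageCounts(m2, stage = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2))
    expect_equal(unname(colSums(normalizeFractions(sc2))), rep(1, 6))
})

test_that("normalization errors are informative", {
    m <- matrix(c(1, 0, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    sc <- StageCounts(m, stage = c("A", "B"), replicate = c(1, 1))
    expect_error(normalizeFractions(sc), "s2")
    expect_error(normalizeFractions(sc, useLengths = TRUE), "length")
})

test_that("replicate collapse takes the stage median and keeps order", {
    m <- matrix(c(1, 2, 4, 10,   # gene1, stage A replicates
                  5, 5, 5, 5),   # gene2
                nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("A_r", 1:4)))
    design <- data.frame(stage = factor(rep("A", 4)), replicate = 1:4,
                         row.names = colnames(m))
    st <- collapseReplicates(m, design, renormalize = FALSE)
    # even-count median = mean of middle pair: (2+4)/2 = 3
    expect_equal(unname(exprValues(st)["g1", "A"]), 3)
    expect_equal(unname(exprValues(st)["g2", "A"]), 5)
    # identical replicates: output equals any replicate, stage order kept
    m2 <- cbind(m[, c(1, 1)], m[, c(2, 2)])
    colnames(m2) <- c("B_r1", "B_r2", "A_r1", "A_r2")
    d2 <- data.frame(stage = factor(c("B", "B", "A", "A"),
                                    levels = c("B", "A")),
                     replicate = c(1, 2, 1, 2), row.names = colnames(m2))
    st2 <- collapseReplicates(m2, d2, renormalize = FALSE)
    expect_identical(stageNames(st2), c("B", "A"))
    expect_equal(unname(exprValues(st2)[, "B"]), unname(m2[, "B_r1"]))
    expect_error(collapseReplicates(m, data.frame(stage = "A", replicate = 1,
                                                  row.names = "missing")),
                 "missing")
})

test_that("replicate collapse renormalizes stage columns to sum to one", {
    cfg <- simulationConfig(nGenes = 50, seed = 3)
    sim <- simulateCounts(simulateGeneCatalog(cfg), cfg)
    fr <- normalizeFractions(sim$counts)
    st <- collapseReplicates(fr, SummarizedExperiment::colData(sim$counts))
    expect_equal(unname(colSums(exprValues(st))),
                 rep(1, length(stageNames(st))), tolerance = 1e-9)
    expect_true(all(exprValues(st) >= 0))
})

test_that("standardization applies the zero rules and centres on the median", {
    # profile (1, 2, 4): log2(v / median) = (-1, 0, 1)
    m <- matrix(c(1, 2, 4), 1, 3, dimnames = list("g", c("S1", "S2", "S3")))
    std <- standardizeExpression(toyStageExpression(m))
    expect_equal(unname(exprValues(std)[1, ]), c(-1, 0, 1))
    # boundary zero takes the single neighbor before the transform
    m2 <- rbind(gA = c(0, 4, 8, 16), gB = c(2, 2, 2, 2))
    colnames(m2) <- paste0("S", 1:4)
    std2 <- standardizeExpression(toyStageExpression(m2))
    # filled profile (4, 4, 8, 16), centred on the log2 median
    expect_equal(unname(exprValues(std2)["gA", ]),
                 unname(log2(c(4, 4, 8, 16)) - median(log2(c(4, 4, 8, 16)))))
    expect_equal(auditCounts(std2)$edge_filled, 1L)
    # interior zero interpolated with mean of neighbors
    m3 <- rbind(gA = c(4, 0, 8, 16), gB = c(2, 2, 2, 2))
    colnames(m3) <- paste0("S", 1:4)
    std3 <- standardizeExpression(toyStageExpression(m3))
    expect_equal(unname(exprValues(std3)["gA", 2]),
                 log2(6) - median(log2(c(4, 6, 8, 16))))
    expect_equal(auditCounts(std3)$interpolated, 1L)
    # more than two zero stages -> discarded
    m4 <- rbind(gA = c(0, 0, 0, 5, 5, 5, 5, 5, 5, 5, 5, 5),
                gB = rep(2, 12))
    colnames(m4) <- paste0("S", 1:12)
    std4 <- standardizeExpression(toyStageExpression(m4))
    expect_equal(auditCounts(std4)$discarded, 1L)
    expect_false("gA" %in% rownames(exprValues(std4)))
})

test_that("standardization audit identity holds and retained medians are 0", {
    cfg <- simulationConfig(nGenes = 100, seed = 5)
    sim <- simulateCounts(simulateGeneCatalog(cfg), cfg)
    fr <- normalizeFractions(sim$counts)
    st <- collapseReplicates(fr, SummarizedExperiment::colData(sim$counts))
    std <- standardizeExpression(st)
    a <- auditCounts(std)
    expect_identical(a$discarded + a$retained, nrow(exprValues(st)))
    expect_lte(a$interpolated + a$edge_filled, a$retained)
    meds <- apply(exprValues(std), 1, median)
    expect_equal(unname(meds), rep(0, length(meds)), tolerance = 1e-9)
})

test_that("two adjacent zeros are filled left to right", {
    m <- rbind(gA = c(4, 0, 0, 8), gB = rep(1, 4))
    colnames(m) <- paste0("S", 1:4)
    std <- standardizeExpression(toyStageExpression(m))
    # left zero first: (4+0)/2 = 2, then right: (2+8)/2 = 5
    prof <- c(4, 2, 5, 8)
    expect_equal(unname(exprValues(std)["gA", ]),
                 unname(log2(prof) - median(log2(prof))))
})

test_that("stage correlation is symmetric, unit-diagonal, and matches the formula", {
    set.seed(1)
    m <- matrix(2^rnorm(15), 5, 3, dimnames = list(paste0("g", 1:5), NULL))
    colnames(m) <- paste0("S", 1:3)
    std <- standardizeExpression(toyStageExpression(m))
    cc <- stageCorrelation(std)
    expect_equal(unname(diag(cc)), rep(1, 3))
    expect_equal(cc, t(cc))
    v <- exprValues(std)
    # textbook covariance / (sd * sd) oracle
    byHand <- sum((v[, 1] - mean(v[, 1])) * (v[, 2] - mean(v[, 2]))) /
        ((nrow(v) - 1) * sd(v[, 1]) * sd(v[, 2]))
    expect_equal(cc[1, 2], byHand)
    # anticorrelated stage
    v2 <- cbind(A = v[, 1], B = -v[, 1], C = v[, 2])
    stdLike <- new("StandardizedExpression", values = v2,
                   audit = list(discarded = 0L, interpolated = 0L,
                                edge_filled = 0L, retained = nrow(v2)))
    expect_equal(stageCorrelation(stdLike)["A", "B"], -1)
    # zero-variance stage is reported, not silently zeroed
    v3 <- cbind(A = v[, 1], B = rep(0, 5))
    stdZ <- new("StandardizedExpression", values = v3,
                audit = list(discarded = 0L, interpolated = 0L,
                             edge_filled = 0L, retained = 5L))
    expect_warning(stageCorrelation(stdZ), "B")
})

test_that("gene-row permutation permutes outputs identically", {
    set.seed(2)
    m <- matrix(2^rnorm(40), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("S", 1:4)))
    std1 <- standardizeExpression(toyStageExpression(m))
    perm <- sample(nrow(m))
    std2 <- standardizeExpression(toyStageExpression(m[perm, ]))
    expect_equal(exprValues(std2), exprValues(std1)[rownames(m)[perm], ])
})
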