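mkStd <- function(m) {
    new("StandardizedExpression", values = m,
        audit = list(discarded = 0L, interpolated = 0L, edge_filled = 0L,
                     retained = nrow(m)))
}

test_that("upregulation threshold is inclusive at 0.5", {
    m <- matrix(c(0.5, 0.49, 0.51, -1), 4, 1,
                dimnames = list(paste0("g", 1:4), "S1"))
    std <- mkStd(m)
    expect_setequal(selectUpregulated(std, "S1"), c("g1", "g3"))
    # direct one-line comparison oracle on a larger matrix
    set.seed(30)
    m2 <- matrix(rnorm(100 * 3), 100, 3,
                 dimnames = list(paste0("g", 1:100), c("A", "B", "C")))
    std2 <- mkStd(m2)
    expect_setequal(selectUpregulated(std2, "B"),
                    rownames(m2)[m2[, "B"] >= 0.5])
    expect_error(selectUpregulated(std2, "Z"), "Z")
})

test_that("two-sided hypergeometric p matches enumeration on spot cases", {
    # K = N forces k = n and p = 1
    expect_equal(hypergeomTwoSided(4, 10, 4, 10), 1)
    expect_equal(hypergeomTwoSided(4, 5, 4, 10), oracleHyper2s(4, 5, 4, 10))
    # mode with symmetric tails -> p = 1
    expect_equal(hypergeomTwoSided(2, 4, 4, 8), 1)
    expect_error(hypergeomTwoSided(5, 4, 4, 10), "inconsistent")
    # doubling convention never below the minlik convention's smaller tail
    p1 <- hypergeomTwoSided(9, 10, 10, 100)
    p2 <- hypergeomTwoSided(9, 10, 10, 100, method = "doubling")
    expect_true(p1 > 0 && p1 <= 1 && p2 > 0)
})

test_that("log odds follow the log2 frequency ratio with 0.5 correction at zero cells", {
    expect_equal(logOdds(5, 50, 10, 100), 0)      # equal frequencies
    expect_equal(logOdds(10, 50, 10, 100), 1)     # double frequency
    # documented correction: log2(((k+0.5)/(n+1)) / ((K+0.5)/(N+1)))
    expect_equal(logOdds(0, 100, 50, 10000),
                 log2((0.5 / 51) / (100.5 / 10001)))
    expect_error(logOdds(0, 0, 10, 100), "undefined")
})

test_that("BH adjustment matches the hand step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.05, 4)), rep(0.05, 4))
    set.seed(31)
    p <- runif(50)
    expect_equal(bhAdjust(p), oracleBH(p))
    expect_true(all(bhAdjust(p) >= p))
    # permutation invariance (up to reordering)
    perm <- sample(50)
    expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("a planted 5x over-represented term is recovered as significant", {
    set.seed(32)
    N <- 2000
    genes <- paste0("g", seq_len(N))
    terms <- paste0("T", 1:20)
    ann <- data.frame(gene = rep(genes, 2),
                      term = sample(terms[-1], 2 * N, replace = TRUE))
    # plant: term T1 annotates 10% of genes overall ...
    t1genes <- sample(genes, 200)
    ann <- rbind(ann, data.frame(gene = t1genes, term = "T1"))
    aset <- AnnotationSet(ann, universe = genes)
    # ... and the upregulated set of stage A is strongly enriched for T1
    up <- c(sample(t1genes, 100), sample(setdiff(genes, t1genes), 100))
    m <- matrix(-1, N, 2, dimnames = list(genes, c("A", "B")))
    m[up, "A"] <- 1
    scan <- enrichmentScan(mkStd(m), aset)
    row <- scan[scan$stage == "A" & scan$term == "T1", ]
    expect_true(row$significant)
    expect_gt(row$log_odds, 1)   # 50% vs 10% background: log2(5) = 2.3
    expect_equal(row$k, 100L)
    expect_equal(row$n, 200L)
    expect_equal(row$K, 200L)
    expect_equal(row$N, N)
})

test_that("a term annotating every gene is never enriched", {
    genes <- paste0("g", 1:50)
    ann <- data.frame(gene = genes, term = "ALL")
    aset <- AnnotationSet(ann)
    m <- matrix(rep(c(1, -1), c(20, 30)), 50, 1,
                dimnames = list(genes, "A"))
    scan <- enrichmentScan(mkStd(m), aset)
    expect_equal(scan$log_odds, 0)
    expect_equal(scan$p, 1)
})

test_that("scan bookkeeping: rows, empty stages, term-subset restriction", {
    genes <- paste0("g", 1:30)
    ann <- data.frame(gene = rep(genes, 2),
                      term = rep(c("T1", "T2"), each = 30))
    aset <- AnnotationSet(ann)
    m <- matrix(-1, 30, 3, dimnames = list(genes, c("A", "B", "C")))
    m[1:5, "A"] <- 1
    scan <- enrichmentScan(mkStd(m), aset)
    expect_equal(nrow(scan), 3 * 2)  # |stages| x |terms|
    expect_true(all(scan$n[scan$stage == "B"] == 0))
    expect_true(all(is.na(scan$p[scan$stage == "B"])))
    # subset restriction drops terms before testing
    asub <- AnnotationSet(ann, termSubset = "T1")
    expect_equal(unique(enrichmentScan(mkStd(m), asub)$term), "T1")
})

test_that("random annotations produce no systematic inflation", {
    set.seed(33)
    N <- 300
    genes <- paste0("g", seq_len(N))
    falsePos <- 0L; tests <- 0L
    for (r in 1:25) {
        ann <- data.frame(gene = sample(genes, 500, replace = TRUE),
                          term = sample(paste0("T", 1:10), 500, replace = TRUE))
        aset <- AnnotationSet(ann, universe = genes)
        m <- matrix(rnorm(N * 2), N, 2, dimnames = list(genes, c("A", "B")))
        scan <- enrichmentScan(mkStd(m), aset)
        falsePos <- falsePos + sum(scan$significant, na.rm = TRUE)
        tests <- tests + sum(!is.na(scan$p_adj))
    }
    expect_lt(falsePos / tests, 0.02)
})
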