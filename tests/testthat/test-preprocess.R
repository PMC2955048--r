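test_that("percentile truncation clamps to global linear-interpolation quantiles", {
    # identity truncation leaves the matrix alone
    m <- matrix(as.numeric(1:20), nrow = 10)
    expect_identical(truncatePercentiles(m, 0, 1), m)

    # a constant matrix is a degenerate distribution: unchanged
    const <- matrix(7, 5, 4)
    expect_identical(truncatePercentiles(const, 0.005, 0.995), const)

    # clamped extremes equal the sort-and-index percentiles of the input
    set.seed(11)
    x <- matrix(rexp(1000, 1 / 200), nrow = 100)
    tr <- truncatePercentiles(x, 0.005, 0.995)
    expect_equal(min(tr), naiveQuantile(as.vector(x), 0.005))
    expect_equal(max(tr), naiveQuantile(as.vector(x), 0.995))
    expect_identical(dim(tr), dim(x))
    # interior values untouched
    inside <- x >= min(tr) & x <= max(tr)
    expect_identical(tr[inside], x[inside])

    expect_error(truncatePercentiles(matrix(numeric(0), 0, 0)), "empty")
    expect_error(truncatePercentiles(x, 0.9, 0.1), "lo < hi")
})

test_that("truncation of an EDRSet preserves class, ids and design", {
    es <- simulateExpression(m = 50, s0 = 0, seed = 3)
    tr <- truncatePercentiles(es, 0.01, 0.99)
    expect_s4_class(tr, "EDRSet")
    expect_identical(rownames(tr), rownames(es))
    expect_identical(sampleGroups(tr), sampleGroups(es))
})

test_that("two-sample p-values match closed-form and stats::t.test", {
    mk <- function(rows) {
        m <- do.call(rbind, rows)
        rownames(m) <- paste0("g", seq_len(nrow(m)))
        colnames(m) <- paste0("s", seq_len(ncol(m)))
        EDRSet(m, rep(c("a", "b"), each = ncol(m) / 2))
    }
    # identical samples in both groups: no evidence against the null
    es <- mk(list(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)))
    expect_equal(unname(testPValues(es, logTransform = FALSE)), 1)

    # hand-computed pooled t: {10,11,12} vs {20,21,22}, s_p = 1, 4 df
    es <- mk(list(c(10, 11, 12, 20, 21, 22)))
    tstat <- 10 / (1 * sqrt(2 / 3))
    expect_equal(unname(testPValues(es, logTransform = FALSE)),
                 2 * pt(-abs(tstat), df = 4))

    # random rows against t.test, equal-variance and Welch
    set.seed(21)
    m <- matrix(rexp(200, 1 / 100) + 1, nrow = 20)
    rownames(m) <- paste0("g", 1:20); colnames(m) <- paste0("s", 1:10)
    es <- EDRSet(m, rep(c("a", "b"), each = 5))
    for (logt in c(TRUE, FALSE)) {
        v <- if (logt) log(m) else m
        pEq <- testPValues(es, logTransform = logt, test = "t_equal_var")
        pW <- testPValues(es, logTransform = logt, test = "t_welch")
        pPair <- testPValues(es, logTransform = logt, test = "t_paired")
        for (i in c(1, 7, 20)) {
            expect_equal(unname(pEq[i]),
                         t.test(v[i, 1:5], v[i, 6:10], var.equal = TRUE)$p.value)
            expect_equal(unname(pW[i]),
                         t.test(v[i, 1:5], v[i, 6:10])$p.value)
            expect_equal(unname(pPair[i]),
                         t.test(v[i, 1:5], v[i, 6:10], paired = TRUE)$p.value)
        }
    }
})

test_that("anova p-values match stats::oneway.test and handle >2 groups", {
    set.seed(31)
    m <- matrix(rexp(120, 1 / 50) + 1, nrow = 10)
    rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("s", 1:12)
    es <- EDRSet(m, rep(c("a", "b", "c"), each = 4))
    p <- testPValues(es, logTransform = FALSE, test = "anova")
    g <- factor(rep(c("a", "b", "c"), each = 4))
    for (i in c(2, 9))
        expect_equal(unname(p[i]),
                     oneway.test(m[i, ] ~ g, var.equal = TRUE)$p.value)
    expect_error(testPValues(es, test = "t_equal_var"), "exactly 2 groups")
})

test_that("degenerate rows give p = 1 (equal means) or p = 0 with warning", {
    m <- rbind(g1 = c(5, 5, 5, 5), g2 = c(2, 2, 9, 9))
    colnames(m) <- paste0("s", 1:4)
    es <- EDRSet(m, c("a", "a", "b", "b"))
    expect_warning(p <- testPValues(es, logTransform = FALSE),
                   "zero within-group variance")
    expect_equal(unname(p), c(1, 0))
})

test_that("null-simulated p-values are approximately uniform", {
    es <- simulateExpression(m = 10000, s0 = 0, seed = 99)
    p <- testPValues(truncatePercentiles(es))
    D <- unname(suppressWarnings(ks.test(p, "punif"))$statistic)
    expect_lt(D, 0.05)
})

test_that("gene summaries give the max-over-median ratio and folded fold", {
    # group means (10, 10) against a global median of 5: x = 2, f = 1
    m <- rbind(a = c(10, 10, 10, 10), b = c(5, 5, 5, 5))
    # entries: 10 x4, 5 x4 -> median 7.5; build the stated median instead
    m <- rbind(a = c(10, 10, 10, 10), b = c(5, 5, 5, 5),
               c = c(5, 5, 4, 4), d = c(1, 1, 5, 5))
    colnames(m) <- paste0("s", 1:4)
    es <- EDRSet(m, c("g1", "g1", "g2", "g2"))
    gs <- geneSummaries(es)
    expect_equal(S4Vectors::metadata(gs)$globalMedian, 5)
    expect_equal(unname(gs["a", "x"]), 2)
    expect_equal(unname(gs["a", "f"]), 1)

    # three groups, means (8, 2, 4), median 4: x = 2, f = 4 (brute max/min)
    m3 <- matrix(c(8, 8, 2, 2, 4, 4), nrow = 1,
                 dimnames = list("g", paste0("s", 1:6)))
    m3 <- rbind(g = c(8, 8, 2, 2, 4, 4), pad = c(4, 4, 4, 4, 4, 4))
    colnames(m3) <- paste0("s", 1:6)
    es3 <- EDRSet(m3, rep(c("x", "y", "z"), each = 2))
    gs3 <- geneSummaries(es3)
    expect_equal(S4Vectors::metadata(gs3)$globalMedian, 4)
    expect_equal(unname(gs3["g", "x"]), 2)
    expect_equal(unname(gs3["g", "f"]), 4)
    expect_equal(unname(gs3["g", "f"]),
                 max(8, 2, 4) / min(8, 2, 4))
})

test_that("x and f are invariant to group relabeling and positive scaling", {
    set.seed(41)
    m <- matrix(rexp(120, 1 / 100) + 1, nrow = 12)
    rownames(m) <- paste0("g", 1:12); colnames(m) <- paste0("s", 1:10)
    gsAB <- geneSummaries(EDRSet(m, rep(c("a", "b"), each = 5)))
    gsBA <- geneSummaries(EDRSet(m, rep(c("b", "a"), each = 5)))
    expect_equal(gsAB$f, gsBA$f)
    expect_equal(gsAB$x, gsBA$x)
    # a positive rescaling cancels in both the ratio and the fold
    gsScaled <- geneSummaries(EDRSet(m * 3.7, rep(c("a", "b"), each = 5)))
    expect_equal(gsScaled$x, gsAB$x)
    expect_equal(gsScaled$f, gsAB$f)
})
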