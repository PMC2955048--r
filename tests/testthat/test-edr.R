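test_that("parallel-negative census counts p-values at or above 1 - t", {
    expect_identical(countParallelNegatives(c(0.1, 0.5, 0.96, 0.99), 0.05), 2L)
    expect_identical(countParallelNegatives(c(0.1, 0.5, 0.9, 0.99), 0.05), 1L)
    # closed boundary: a tie at exactly 1 - t is counted in
    expect_identical(countParallelNegatives(c(0.95, 0.94), 0.05), 1L)
    p <- runif(20)
    expect_identical(countParallelNegatives(p, 1), 20L)
    expect_error(countParallelNegatives(p, 1.5), "\\[0, 1\\]")
    expect_error(countParallelNegatives(c(0.5, 2), 0.1), "\\[0, 1\\]")
})

test_that("census matches the binomial expectation under the uniform null", {
    set.seed(7)
    p <- runif(10000)
    np <- countParallelNegatives(p, 0.01)
    expect_lt(abs(np - 100), 3 * sqrt(10000 * 0.01 * 0.99))
})

test_that("census is monotone in t, exact at the boundaries, and scan-equivalent", {
    set.seed(13)
    for (rep in 1:5) {
        p <- round(runif(200), sample(1:3, 1))  # rounding forces ties
        ts <- sort(c(0, 1, runif(20), p[1:5]))
        counts <- vapply(ts, function(t) countParallelNegatives(p, t),
                         integer(1))
        expect_true(all(diff(counts) >= 0))
        expect_identical(counts[1], sum(p == 1))       # N'(0): only p = 1
        expect_identical(counts[length(ts)], length(p)) # N'(1) = m
        # vectorized census used by runEDR agrees with the linear scan
        batch <- parallelEDR:::parallelNegativesAll(p, ts)
        oracle <- vapply(ts, function(t) naiveParallelNegatives(p, t),
                         integer(1))
        expect_identical(as.integer(batch), oracle)
        expect_identical(counts, oracle)
    }
})

test_that("global EDR is N' t / R with an undefined signal when R = 0", {
    p <- c(0.001, 0.002, 0.5, 0.97, 0.98, 0.99)
    expect_equal(edrGlobal(p, 0.05), 3 * 0.05 / 2)
    expect_warning(res <- edrGlobal(c(0.4, 0.6, 0.99), 0.05), "undefined")
    expect_true(is.na(res))
})

test_that("global EDR calibrates under the pure null", {
    # N'(t) mirrors R(t) when every gene is null, so EDR(t) = N' t / R
    # concentrates at t and the census-to-rejection ratio EDR(t)/t at 1
    set.seed(17)
    vals <- replicate(20, edrGlobal(runif(10000), 0.05))
    expect_lt(abs(mean(vals) / 0.05 - 1), 0.1)
})

test_that("local EDR is the census at the gene's own p-value times that p", {
    expect_equal(edrLocal(c(0, 0.5, 0.9), 1), 0)
    expect_equal(edrLocal(c(0.01, 0.5, 0.995), 1), 0.01)  # N' = 1
    # published inputs: p = 0.00018432 with two parallel negatives
    p <- c(0.00018432, 0.99985, 0.9999, 0.5, 0.2)
    expect_equal(edrLocal(p, 1), 0.00036864)
})

test_that("reality factor is 1/(x(f-1)) with the published rows reproduced", {
    expect_equal(realityFactor(1, 2), 1)
    expect_equal(realityFactor(309.453094, 5.318301),
                 1 / (309.453094 * 4.318301))
    expect_equal(realityFactor(2.773653, 1.332583), 1.08404, tolerance = 1e-5)
    expect_true(is.na(realityFactor(2, 1)))       # f = 1: undefined
    expect_error(realityFactor(0, 2), "positive")
    expect_error(realityFactor(-1, 2), "positive")
    expect_error(realityFactor(1, 0.5), ">= 1")
    # the factor grows as expression or fold reliability shrinks
    expect_gt(realityFactor(0.5, 1.2), realityFactor(0.5, 2))
    expect_gt(realityFactor(0.5, 1.2), realityFactor(5, 1.2))
})

test_that("edrScore caps at 1 and treats f = 1 or bad x as maximal error", {
    # published row whose raw product ~ 8.6 is capped
    expect_equal(edrScore(0.00625588, 53, 0.582200, 1.066264), 1)
    expect_equal(edrScore(0.00625588, 53, 0.582200, 1.066264, cap = FALSE),
                 53 * 0.00625588 / (0.582200 * 0.066264))
    expect_equal(edrScore(0.00342428, 30, 20.312435, 1.910159),
                 0.00555663, tolerance = 1e-6)
    expect_equal(edrScore(0, 10, 5, 2), 0)       # zero p, valid sigma
    expect_equal(edrScore(0.5, 3, 5, 1), 1)      # f = 1: unreliable
    expect_equal(edrScore(0.5, 3, NA, 2), 1)     # flagged x
    # cap idempotence
    e1 <- edrScore(c(0.1, 0.9), c(100, 500), c(0.1, 0.2), c(1.1, 1.2))
    expect_identical(pmin(e1, 1), e1)
    expect_true(all(e1 >= 0 & e1 <= 1))
})

test_that("runEDR stores a census equal to an independent scan and is capped", {
    es <- simulateExpression(m = 300, s0 = 0.05, seed = 5)
    res <- runEDR(es)
    expect_s4_class(res, "EDRResults")
    expect_identical(nrow(res), 300L)
    oracle <- vapply(res$pRaw, function(t) naiveParallelNegatives(res$pRaw, t),
                     integer(1))
    expect_identical(res$nParallel, oracle)
    expect_true(all(res$edr >= 0 & res$edr <= 1))
    # tied p-values share a census (it depends on the value, not the rank)
    dup <- duplicated(res$pRaw) | duplicated(res$pRaw, fromLast = TRUE)
    if (any(dup))
        expect_identical(res$nParallel[dup],
                         oracle[dup])
    # EDR at the stored alpha drives the selected flag
    expect_identical(res$selected, res$edr <= 0.05)
})

test_that("EDR rank can invert the p-value rank", {
    res <- publishedEDRResults()
    # PMP22 has a larger raw p than IGL@ yet a smaller error estimate
    expect_gt(res["PMP22", "pRaw"], res["IGL@", "pRaw"])
    expect_lt(res["PMP22", "edr"], res["IGL@", "edr"])
})

test_that("selectDEGs applies the cutoff with a total order and handles edges", {
    res <- publishedEDRResults()
    expect_identical(selectDEGs(res, 1), rownames(res)[order(res$edr,
                                                             res$pRaw,
                                                             rownames(res))])
    empty <- methods::new("EDRResults", S4Vectors::DataFrame(
        pRaw = numeric(0), nParallel = integer(0),
        edr = numeric(0), selected = logical(0)))
    expect_identical(selectDEGs(empty, 0.05), character(0))
    expect_error(selectDEGs(res, 0), "alpha")
})

test_that("the p-value-only path computes local EDR without a reality factor", {
    p <- c(a = 0.001, b = 0.2, c = 0.97, d = 0.999)
    res <- edrFromPValues(p)
    expect_identical(res$nParallel,
                     vapply(p, function(t) naiveParallelNegatives(p, t),
                            integer(1), USE.NAMES = FALSE))
    expect_equal(res$edr, pmin(1, res$nParallel * p), ignore_attr = TRUE)
    expect_true(all(is.na(res$sigma)))
    expect_identical(rownames(res), names(p))
})
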