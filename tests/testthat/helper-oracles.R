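# Independent brute-force oracles. Deliberately written with explicit
# loops and textbook recursions, sharing no code with the package.

# parallel-negative census by linear scan
naiveParallelNegatives <- function(p, t) {
    n <- 0L
    for (pp in p) if (pp >= 1 - t) n <- n + 1L
    n
}

# linear-interpolation percentile by sort-and-index
naiveQuantile <- function(x, prob) {
    s <- sort(x)
    n <- length(s)
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    if (lo >= n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# textbook multiplicity corrections, one explicit recursion each
bruteAdjust <- function(p, method, lambda = 0.5) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    if (method == "pcer") {
        return(p)
    } else if (method == "pfer") {
        return(m * p)
    } else if (method == "bonferroni") {
        for (i in seq_len(m)) adj[i] <- min(1, m * ps[i])
    } else if (method == "holm") {
        run <- 0
        for (i in seq_len(m)) {
            run <- max(run, (m - i + 1) * ps[i])
            adj[i] <- min(1, run)
        }
    } else if (method == "hochberg") {
        run <- Inf
        for (i in rev(seq_len(m))) {
            run <- min(run, (m - i + 1) * ps[i])
            adj[i] <- min(1, run)
        }
    } else if (method == "sidak_sd") {
        run <- 0
        for (i in seq_len(m)) {
            run <- max(run, 1 - (1 - ps[i])^(m - i + 1))
            adj[i] <- min(1, run)
        }
    } else if (method == "bh") {
        run <- Inf
        for (i in rev(seq_len(m))) {
            run <- min(run, m * ps[i] / i)
            adj[i] <- min(1, run)
        }
    } else if (method == "by") {
        cm <- sum(1 / seq_len(m))
        run <- Inf
        for (i in rev(seq_len(m))) {
            run <- min(run, cm * m * ps[i] / i)
            adj[i] <- min(1, run)
        }
    } else if (method == "qvalue") {
        pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
        bh <- bruteAdjust(p, "bh")
        return(pmin(1, bh * pi0))
    } else stop("unknown method in oracle: ", method)
    out <- numeric(m)
    out[o] <- adj
    out
}

# published seven-gene worked example, loaded once for several tests
publishedEDRTable <- function() hyperinsulinemiaExample()

# EDRResults wrapper around the published rows (no census recomputation:
# the printed N' came from the full 7129-gene experiment)
publishedEDRResults <- function(alpha = 0.05) {
    tab <- publishedEDRTable()
    edr <- edrScore(tab$raw_p, tab$N_prime, tab$x_i, tab$f_i)
    res <- S4Vectors::DataFrame(
        pRaw = tab$raw_p, x = tab$x_i, f = tab$f_i,
        nParallel = as.integer(tab$N_prime),
        sigma = 1 / (tab$x_i * (tab$f_i - 1)),
        edr = edr, selected = edr <= alpha,
        row.names = tab$gene)
    S4Vectors::metadata(res) <- list(alpha = alpha)
    methods::new("EDRResults", res)
}
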