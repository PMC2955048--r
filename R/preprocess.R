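#' Truncate an expression matrix to global percentile bounds
#'
#' Clamps extreme values before fold and expression-ratio calculations:
#' every entry below the global `lo` quantile of all matrix entries is
#' raised to that quantile, every entry above the global `hi` quantile is
#' lowered to it. The quantiles are linear-interpolation quantiles
#' (type 7) pooled over the whole matrix, so the post-truncation global
#' median is well defined. Shape and identifiers are unchanged.
#'
#' @param x an [EDRSet-class] or a numeric matrix.
#' @param lo,hi truncation fractions, `0 <= lo < hi <= 1`. The defaults
#'   clamp to the 0.5\% and 99.5\% percentiles.
#' @return an object of the same class as `x`, truncated.
#' @examples
#' m <- matrix(1:1000, 100, 10)
#' range(truncatePercentiles(m, 0.005, 0.995))
#' @export
truncatePercentiles <- function(x, lo = 0.005, hi = 0.995) {
    if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi > 1 || lo >= hi)
        stop("need 0 <= lo < hi <= 1")
    v <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "exprs") else x
    if (length(v) == 0L)
        stop("empty matrix")
    q <- stats::quantile(as.vector(v), probs = c(lo, hi),
                         names = FALSE, type = 7)
    v[v < q[1L]] <- q[1L]
    v[v > q[2L]] <- q[2L]
    if (methods::is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "exprs") <- v
        x
    } else {
        v
    }
}

## Vectorized two-sided two-sample t over matrix rows. Returns p-values.
## Degenerate rows (zero variance in both groups): equal means -> p = 1,
## unequal means -> p = 0 (the t statistic diverges); a warning is raised
## for the latter.
rowTTestP <- function(v, idx1, idx2, equalVar = TRUE) {
    n1 <- length(idx1); n2 <- length(idx2)
    x1 <- v[, idx1, drop = FALSE]; x2 <- v[, idx2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    s1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    s2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    if (equalVar) {
        sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
        se2 <- sp2 * (1 / n1 + 1 / n2)
        df <- rep.int(n1 + n2 - 2, nrow(v))
    } else {
        se2 <- s1 / n1 + s2 / n2
        ## Welch-Satterthwaite df; degenerate rows fixed up below
        df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
    }
    p <- numeric(nrow(v))
    degen <- se2 <= 0 | !is.finite(se2)
    if (any(degen)) {
        eq <- degen & (m1 == m2)
        p[eq] <- 1
        if (any(degen & !eq)) {
            warning("zero within-group variance with unequal means: p set to 0")
            p[degen & !eq] <- 0
        }
    }
    ok <- !degen
    if (any(ok)) {
        tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
        p[ok] <- 2 * stats::pt(abs(tstat), df[ok], lower.tail = FALSE)
    }
    p
}

rowPairedTTestP <- function(v, idx1, idx2) {
    if (length(idx1) != length(idx2))
        stop("paired test needs equal group sizes")
    d <- v[, idx1, drop = FALSE] - v[, idx2, drop = FALSE]
    n <- ncol(d)
    if (n < 2L) stop("paired test needs >= 2 pairs")
    md <- rowMeans(d)
    sd2 <- rowSums((d - md)^2) / (n - 1)
    p <- numeric(nrow(v))
    degen <- sd2 <= 0
    p[degen & md == 0] <- 1
    if (any(degen & md != 0)) {
        warning("zero variance of differences with nonzero mean: p set to 0")
        p[degen & md != 0] <- 0
    }
    ok <- !degen
    if (any(ok)) {
        tstat <- md[ok] / sqrt(sd2[ok] / n)
        p[ok] <- 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
    }
    p
}

rowAnovaP <- function(v, groupIdx) {
    k <- length(groupIdx)
    n <- sum(lengths(groupIdx))
    gm <- vapply(groupIdx, function(ix) rowMeans(v[, ix, drop = FALSE]),
                 numeric(nrow(v)))
    if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(v))
    gss <- vapply(seq_len(k), function(j) {
        ix <- groupIdx[[j]]
        rowSums((v[, ix, drop = FALSE] - gm[, j])^2)
    }, numeric(nrow(v)))
    if (is.null(dim(gss))) gss <- matrix(gss, nrow = nrow(v))
    ssw <- rowSums(gss)
    grand <- rowSums(v[, unlist(groupIdx), drop = FALSE]) / n
    ssb <- vapply(seq_len(k), function(j)
        lengths(groupIdx)[j] * (gm[, j] - grand)^2, numeric(nrow(v)))
    if (is.null(dim(ssb))) ssb <- matrix(ssb, nrow = nrow(v))
    ssb <- rowSums(ssb)
    dfb <- k - 1L; dfw <- n - k
    p <- numeric(nrow(v))
    degen <- ssw <= 0
    p[degen & ssb == 0] <- 1
    if (any(degen & ssb > 0)) {
        warning("zero within-group variance with unequal means: p set to 0")
        p[degen & ssb > 0] <- 0
    }
    ok <- !degen
    if (any(ok)) {
        f <- (ssb[ok] / dfb) / (ssw[ok] / dfw)
        p[ok] <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
    }
    p
}

#' Per-gene raw p-values for group differences
#'
#' Computes one two-sided p-value per gene. By default values are
#' natural-log transformed first (log intensities conform better to the
#' normality assumption of the t test); fold and ratio summaries are
#' always taken on the raw scale elsewhere, never here. Values that are
#' not strictly positive are raised to the smallest positive value in the
#' matrix before logging.
#'
#' @param x an [EDRSet-class].
#' @param logTransform logical; test on natural-log values (default TRUE).
#' @param test `"t_equal_var"` (pooled-variance two-sample t, the
#'   default), `"t_welch"`, `"t_paired"` (samples paired by position
#'   within each group), or `"anova"` (one-way, required for >2 groups).
#' @return named numeric vector of raw p-values, one per gene, in matrix
#'   row order.
#' @examples
#' es <- simulateExpression(m = 50, s0 = 0.2, seed = 1)
#' p <- testPValues(es)
#' head(p)
#' @export
testPValues <- function(x, logTransform = TRUE,
                        test = c("t_equal_var", "t_welch", "t_paired",
                                 "anova")) {
    test <- match.arg(test)
    stopifnot(methods::is(x, "SummarizedExperiment"))
    v <- SummarizedExperiment::assay(x, "exprs")
    g <- as.character(sampleGroups(x))
    groupIdx <- split(seq_len(ncol(v)), factor(g, levels = unique(g)))
    if (any(lengths(groupIdx) < 2L))
        stop("every group needs >= 2 samples")
    if (test %in% c("t_equal_var", "t_welch", "t_paired") &&
        length(groupIdx) != 2L)
        stop("t tests require exactly 2 groups; use test = 'anova'")
    if (logTransform) {
        minPos <- suppressWarnings(min(v[v > 0]))
        if (!is.finite(minPos))
            stop("log transform requires at least one positive value")
        v[v <= 0] <- minPos
        v <- log(v)
    }
    p <- switch(test,
        t_equal_var = rowTTestP(v, groupIdx[[1L]], groupIdx[[2L]], TRUE),
        t_welch     = rowTTestP(v, groupIdx[[1L]], groupIdx[[2L]], FALSE),
        t_paired    = rowPairedTTestP(v, groupIdx[[1L]], groupIdx[[2L]]),
        anova       = rowAnovaP(v, groupIdx))
    names(p) <- rownames(v)
    p
}

#' Per-gene expression summaries feeding the reality factor
#'
#' From a percentile-truncated matrix on the raw (linear) scale, computes
#' per gene: the group means, the expression-magnitude ratio
#' \eqn{x = \max_g \bar{v}_g / \mathrm{median}(\mathrm{all\ entries})},
#' and the direction-folded fold change
#' \eqn{f = \max_g \bar{v}_g / \min_g \bar{v}_g \ge 1}, which treats up-
#' and down-regulation symmetrically. Genes whose minimum group mean is
#' not positive are flagged (`ok = FALSE`): their reality factor is
#' undefined and they are treated as maximally unreliable downstream.
#'
#' @param x an [EDRSet-class], already truncated (see
#'   [truncatePercentiles()]).
#' @return a [S4Vectors::DataFrame] with columns `x`, `f`, `ok` and one
#'   `mean.<group>` column per group; the global median is stored in
#'   `metadata()$globalMedian`.
#' @examples
#' es <- simulateExpression(m = 20, s0 = 0, seed = 1)
#' gs <- geneSummaries(es)
#' head(gs)
#' @export
geneSummaries <- function(x) {
    stopifnot(methods::is(x, "SummarizedExperiment"))
    v <- SummarizedExperiment::assay(x, "exprs")
    g <- as.character(sampleGroups(x))
    groupIdx <- split(seq_len(ncol(v)), factor(g, levels = unique(g)))
    med <- stats::median(as.vector(v))
    if (med <= 0)
        stop("global median of the expression matrix must be positive")
    gm <- vapply(groupIdx, function(ix) rowMeans(v[, ix, drop = FALSE]),
                 numeric(nrow(v)))
    if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1L)
    maxMean <- apply(gm, 1L, max)
    minMean <- apply(gm, 1L, min)
    ok <- minMean > 0
    out <- S4Vectors::DataFrame(
        x = maxMean / med,
        f = ifelse(ok, maxMean / minMean, NA_real_),
        ok = ok,
        row.names = rownames(v))
    for (j in seq_along(groupIdx))
        out[[paste0("mean.", names(groupIdx)[j])]] <- gm[, j]
    S4Vectors::metadata(out)$globalMedian <- med
    out
}
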