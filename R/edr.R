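#' Count parallel negatives
#'
#' The parallel-negative census \eqn{N'(t) = \#\{j : p_j \ge 1 - t\}}:
#' the number of genes whose p-values sit at or above \eqn{1 - t},
#' mirroring the rejection region \eqn{p \le t} at the opposite tail of
#' the p-value distribution. Under a uniform null, \eqn{N'(t)} has
#' expectation \eqn{m t}, so \eqn{N' t} estimates the error count
#' \eqn{m_0 t} among the rejections without using \eqn{m_0} itself. The
#' boundary is closed: ties at exactly \eqn{1 - t} are counted.
#'
#' @param pvalues numeric vector of p-values in \eqn{[0, 1]}.
#' @param t significance threshold in \eqn{[0, 1]}.
#' @return nonnegative integer count.
#' @examples
#' countParallelNegatives(c(0.1, 0.5, 0.95, 0.99), t = 0.05)  # 1
#' @export
countParallelNegatives <- function(pvalues, t) {
    checkPValues(pvalues)
    if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
        stop("'t' must be a single value in [0, 1]")
    sum(pvalues >= 1 - t)
}

checkPValues <- function(pvalues) {
    if (!is.numeric(pvalues) || length(pvalues) == 0L)
        stop("'pvalues' must be a nonempty numeric vector")
    if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1] with no missing values")
    invisible(pvalues)
}

## N'(t_i) for many thresholds at once: m - #{p_j < 1 - t_i}, computed
## against the sorted p-vector so ties at the closed boundary count in.
parallelNegativesAll <- function(pvalues, t) {
    sp <- sort(pvalues)
    length(pvalues) - findInterval(1 - t, sp, left.open = TRUE)
}

#' Global error discovery rate at a threshold
#'
#' \eqn{\mathrm{EDR}(t) = N'(t)\, t / R(t)} where \eqn{R(t)} is the
#' number of rejections at \eqn{p \le t}. This is the parallel-negative
#' analogue of the FDR estimate \eqn{m_0 t / R(t)}: it replaces the null
#' count \eqn{m_0} by the census of negatives mirroring the rejections.
#' The value is reported as a rate estimate, uncapped; `NA` is returned
#' (with a warning) when no gene is rejected at `t`, since the rate is
#' then undefined.
#'
#' @inheritParams countParallelNegatives
#' @return a single nonnegative rate, or `NA` when \eqn{R(t) = 0}.
#' @examples
#' edrGlobal(c(0.001, 0.002, 0.5, 0.97, 0.98, 0.99), t = 0.05)  # 0.075
#' @export
edrGlobal <- function(pvalues, t) {
    checkPValues(pvalues)
    if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
        stop("'t' must be a single value in [0, 1]")
    R <- sum(pvalues <= t)
    if (R == 0L) {
        warning("no rejections at t = ", t, "; EDR(t) undefined")
        return(NA_real_)
    }
    countParallelNegatives(pvalues, t) * t / R
}

#' Local error discovery rate of one gene
#'
#' \eqn{\mathrm{EDR}'_i = N'(p_i)\, p_i}: the per-gene error estimate
#' obtained by dropping the denominator of the global rate and taking the
#' census at the gene's own p-value. This is the path available when only
#' p-values (no expression matrix) are given.
#'
#' @inheritParams countParallelNegatives
#' @param i index of the gene under evaluation.
#' @return nonnegative real.
#' @examples
#' edrLocal(c(0.01, 0.5, 0.995), 1)  # 0.01: one p-value >= 0.99
#' @export
edrLocal <- function(pvalues, i) {
    checkPValues(pvalues)
    if (!(is.numeric(i) || is.character(i)) || length(i) != 1L)
        stop("'i' must be a single index")
    pi <- pvalues[[i]]
    countParallelNegatives(pvalues, pi) * pi
}

#' Reality factor
#'
#' \eqn{\sigma_i = 1 / (x_i (f_i - 1))}, the reliability adjustment that
#' inflates the error of genes with low expression (small `x`) or a fold
#' change near 1. `f == 1` (no change between groups) yields `NA`, which
#' downstream code interprets as maximal error.
#'
#' @param x expression-magnitude ratio: maximum group mean over the
#'   global median expression; must be positive.
#' @param f direction-folded fold change, \eqn{f \ge 1}.
#' @return positive real, or `NA` when `f == 1`. Vectorized.
#' @examples
#' realityFactor(1, 2)                       # 1
#' realityFactor(309.453094, 5.318301)       # ~ 7.48e-4
#' @export
realityFactor <- function(x, f) {
    if (any(!is.finite(x)) || any(x <= 0))
        stop("'x' must be positive and finite")
    if (any(!is.finite(f)) || any(f < 1))
        stop("'f' must be >= 1 (direction-folded fold change)")
    out <- ifelse(f == 1, NA_real_, 1 / (x * (f - 1)))
    out
}

#' Per-gene EDR from its components
#'
#' The arithmetic core \eqn{\mathrm{EDR}_i = N'_i\, p_i\, \sigma_i} with
#' \eqn{\sigma_i = 1/(x_i (f_i - 1))}, capped at 1. Genes with
#' \eqn{f = 1} or a missing/nonpositive reliability input are assigned
#' EDR 1 (maximally unreliable). Vectorized; used both by [runEDR()] on a
#' full experiment and directly on published per-gene rows.
#'
#' @param p raw p-values in \eqn{[0, 1]}.
#' @param nParallel parallel-negative counts \eqn{N'_i}.
#' @param x,f reliability inputs (see [realityFactor()]); `NA` allowed
#'   and treated as unreliable.
#' @param cap logical; cap the product at 1 (default TRUE).
#' @return numeric vector of EDR values.
#' @examples
#' edrScore(p = 0.00018432, nParallel = 2, x = 309.453094, f = 5.318301)
#' @export
edrScore <- function(p, nParallel, x, f, cap = TRUE) {
    checkPValues(p)
    if (any(nParallel < 0, na.rm = TRUE))
        stop("'nParallel' must be nonnegative")
    n <- max(length(p), length(nParallel), length(x), length(f))
    p <- rep_len(p, n); nParallel <- rep_len(nParallel, n)
    x <- rep_len(x, n); f <- rep_len(f, n)
    bad <- is.na(x) | is.na(f) | x <= 0 | f <= 1
    edr <- numeric(n)
    edr[bad] <- 1
    if (any(!bad))
        edr[!bad] <- nParallel[!bad] * p[!bad] /
            (x[!bad] * (f[!bad] - 1))
    if (cap) edr <- pmin(edr, 1)
    edr
}

#' Run the full per-gene EDR analysis on an expression experiment
#'
#' End-to-end per-gene error discovery rates: percentile truncation of
#' the raw matrix, raw p-values on (optionally) log-transformed values,
#' reliability summaries `x` and `f` on the raw truncated scale, the
#' parallel-negative census \eqn{N'_i = \#\{j : p_j \ge 1 - p_i\}} over
#' the full p-value vector, and finally
#' \eqn{\mathrm{EDR}_i = \min(1,\ N'_i p_i \sigma_i)}.
#'
#' @param x an [EDRSet-class].
#' @param alpha selection cutoff applied to the EDR values (default
#'   0.05).
#' @param lo,hi truncation percentiles (defaults 0.005 and 0.995, see
#'   [truncatePercentiles()]).
#' @param logTransform,test passed to [testPValues()].
#' @param cap cap EDR at 1 (default TRUE).
#' @return an [EDRResults-class] with columns `pRaw`, `x`, `f`,
#'   `nParallel`, `sigma`, `edr`, `selected`; `metadata()` records
#'   `alpha` and the analysis settings.
#' @examples
#' es <- simulateExpression(m = 200, s0 = 0.1, seed = 42)
#' res <- runEDR(es)
#' res[res$selected, ]
#' @export
runEDR <- function(x, alpha = 0.05, lo = 0.005, hi = 0.995,
                   logTransform = TRUE,
                   test = c("t_equal_var", "t_welch", "t_paired", "anova"),
                   cap = TRUE) {
    test <- match.arg(test)
    stopifnot(methods::is(x, "SummarizedExperiment"))
    if (nrow(x) == 0L) stop("empty experiment")
    trunc <- truncatePercentiles(x, lo, hi)
    p <- testPValues(trunc, logTransform = logTransform, test = test)
    gs <- geneSummaries(trunc)
    np <- parallelNegativesAll(p, p)
    sigma <- ifelse(gs$ok & gs$f > 1 & gs$x > 0,
                    1 / (gs$x * (gs$f - 1)), NA_real_)
    edr <- edrScore(p, np, gs$x, ifelse(gs$ok, gs$f, NA_real_), cap = cap)
    res <- S4Vectors::DataFrame(
        pRaw = unname(p),
        x = gs$x, f = gs$f,
        nParallel = as.integer(np),
        sigma = sigma,
        edr = edr,
        selected = edr <= alpha,
        row.names = rownames(x))
    S4Vectors::metadata(res) <- list(alpha = alpha, lo = lo, hi = hi,
                                     logTransform = logTransform,
                                     test = test, cap = cap,
                                     m = nrow(x),
                                     globalMedian =
                                         S4Vectors::metadata(gs)$globalMedian)
    methods::new("EDRResults", res)
}

#' Per-gene local EDR from a bare p-value vector
#'
#' The p-value-only analysis path: no expression matrix, hence no
#' reality factor. Each gene gets \eqn{\mathrm{EDR}'_i = N'(p_i)\, p_i}
#' (capped at 1 when `cap` is set); `x`, `f` and `sigma` are `NA`.
#'
#' @param pvalues named or unnamed vector of raw p-values.
#' @param alpha selection cutoff (default 0.05).
#' @param cap cap at 1 (default TRUE).
#' @return an [EDRResults-class].
#' @examples
#' edrFromPValues(c(a = 0.001, b = 0.2, c = 0.97, d = 0.999))
#' @export
edrFromPValues <- function(pvalues, alpha = 0.05, cap = TRUE) {
    checkPValues(pvalues)
    np <- parallelNegativesAll(pvalues, pvalues)
    edr <- np * pvalues
    if (cap) edr <- pmin(edr, 1)
    ids <- names(pvalues)
    if (is.null(ids)) ids <- paste0("gene", seq_along(pvalues))
    res <- S4Vectors::DataFrame(
        pRaw = unname(pvalues),
        x = NA_real_, f = NA_real_,
        nParallel = as.integer(np),
        sigma = NA_real_,
        edr = unname(edr),
        selected = unname(edr <= alpha),
        row.names = ids)
    S4Vectors::metadata(res) <- list(alpha = alpha, cap = cap,
                                     m = length(pvalues), local = TRUE)
    methods::new("EDRResults", res)
}

#' Select differentially expressed genes at an EDR cutoff
#'
#' Genes with \eqn{\mathrm{EDR}_i \le \alpha}, ordered by EDR, then raw
#' p-value, then identifier (a total order, so output is reproducible
#' under ties).
#'
#' @param res an [EDRResults-class].
#' @param alpha cutoff in \eqn{(0, 1]}; defaults to the alpha stored in
#'   the results' metadata.
#' @return character vector of selected gene identifiers.
#' @examples
#' r <- edrFromPValues(c(a = 0.001, b = 0.2, c = 0.97, d = 0.999))
#' selectDEGs(r, 0.05)
#' @export
selectDEGs <- function(res, alpha = NULL) {
    stopifnot(methods::is(res, "EDRResults"))
    if (is.null(alpha))
        alpha <- S4Vectors::metadata(res)$alpha
    if (is.null(alpha) || !is.numeric(alpha) || alpha <= 0 || alpha > 1)
        stop("'alpha' must be in (0, 1]")
    if (nrow(res) == 0L) return(character(0))
    keep <- !is.na(res$edr) & res$edr <= alpha
    sub <- res[keep, , drop = FALSE]
    ids <- rownames(sub)
    ord <- order(sub$edr, sub$pRaw, ids)
    ids[ord]
}
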