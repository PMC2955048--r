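#' Simulate a two-group expression experiment with known truth
#'
#' Generates a genes-by-samples matrix emulating a GC-RMA-normalized
#' two-group microarray study with a known proportion `s0` of true
#' differentially expressed genes (DEGs).
#'
#' Null genes share one mean \eqn{m_i \sim U(\mathrm{meanRange})} and one
#' standard deviation \eqn{sd_i \sim U(\mathrm{sdRange})} across both
#' groups (a strict null: exactly equal group means). DEGs draw their
#' group-1 mean like a null gene, then set the group-2 mean to
#' \eqn{m_i \times \mathrm{fold}} or \eqn{m_i / \mathrm{fold}} with equal
#' probability, fold \eqn{\sim U(\mathrm{foldRange})} (default 1.5- to
#' 3-fold); each DEG group's standard deviation is
#' `degSdFraction` (default one-fifth) of that group's mean. All values
#' are normal draws clipped from below at `floor` so logs and ratios
#' stay defined.
#'
#' @param m total number of genes.
#' @param s0 proportion of true DEGs in \eqn{[0, 1]}; `round(m * s0)`
#'   DEGs are produced (at least 1 when `s0 > 0`, with a warning if
#'   rounding would give 0).
#' @param nPerGroup replicates per group (default 5, two groups).
#' @param meanRange,sdRange uniform ranges for null-gene group means and
#'   standard deviations; defaults (10, 10000) and (1, 500) mimic the
#'   linear-scale spread of GC-RMA output.
#' @param foldRange uniform range of DEG fold changes, default (1.5, 3).
#' @param degSdFraction DEG standard deviation as a fraction of the group
#'   mean, default 0.2.
#' @param floor positive clipping floor for simulated values (default
#'   0.01).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   so the dataset is fully reproducible.
#' @return an [EDRSet-class] whose `rowData()$isDEG` flags the true DEGs,
#'   whose `rowData()$trueFold` records the generating fold change (1 for
#'   nulls) and whose `metadata()` records the simulation parameters.
#' @examples
#' es <- simulateExpression(m = 1000, s0 = 0.1, seed = 1)
#' sum(SummarizedExperiment::rowData(es)$isDEG)  # 100
#' @export
simulateExpression <- function(m, s0, nPerGroup = 5L,
                               meanRange = c(10, 10000),
                               sdRange = c(1, 500),
                               foldRange = c(1.5, 3),
                               degSdFraction = 0.2,
                               floor = 0.01,
                               seed = NULL) {
    if (!is.numeric(m) || m < 1) stop("'m' must be a positive gene count")
    m <- as.integer(m)
    if (!is.numeric(s0) || s0 < 0 || s0 > 1) stop("'s0' must be in [0, 1]")
    if (nPerGroup < 2L) stop("'nPerGroup' must be >= 2")
    for (rng in list(meanRange, sdRange, foldRange)) {
        if (length(rng) != 2L || rng[1L] <= 0 || rng[1L] > rng[2L])
            stop("ranges must satisfy 0 < lo <= hi")
    }
    if (foldRange[1L] < 1) stop("fold changes must be >= 1")
    if (degSdFraction <= 0) stop("'degSdFraction' must be positive")
    if (floor <= 0) stop("'floor' must be positive")
    if (!is.null(seed)) set.seed(seed)

    nDEG <- round(m * s0)
    if (s0 > 0 && nDEG < 1) {
        warning("m * s0 < 1; forcing a single true DEG")
        nDEG <- 1L
    }
    nDEG <- as.integer(nDEG)
    isDEG <- c(rep(TRUE, nDEG), rep(FALSE, m - nDEG))

    n <- as.integer(nPerGroup)
    vals <- matrix(0, nrow = m, ncol = 2L * n)

    mean1 <- stats::runif(m, meanRange[1L], meanRange[2L])
    sdNull <- stats::runif(m, sdRange[1L], sdRange[2L])
    mean2 <- mean1
    sd1 <- sdNull
    sd2 <- sdNull
    if (nDEG > 0L) {
        fold <- stats::runif(nDEG, foldRange[1L], foldRange[2L])
        up <- stats::runif(nDEG) < 0.5
        mean2[seq_len(nDEG)] <- ifelse(up, mean1[seq_len(nDEG)] * fold,
                                       mean1[seq_len(nDEG)] / fold)
        sd1[seq_len(nDEG)] <- degSdFraction * mean1[seq_len(nDEG)]
        sd2[seq_len(nDEG)] <- degSdFraction * mean2[seq_len(nDEG)]
    }
    vals[, seq_len(n)] <- stats::rnorm(m * n, mean = mean1, sd = sd1)
    vals[, n + seq_len(n)] <- stats::rnorm(m * n, mean = mean2, sd = sd2)
    vals[vals < floor] <- floor

    rownames(vals) <- sprintf("gene%0*d", nchar(m), seq_len(m))
    colnames(vals) <- c(paste0("g1_s", seq_len(n)), paste0("g2_s", seq_len(n)))
    es <- EDRSet(vals, groups = rep(c("group1", "group2"), each = n))
    SummarizedExperiment::rowData(es)$isDEG <- isDEG
    trueFold <- rep(1, m)
    if (nDEG > 0L) trueFold[seq_len(nDEG)] <- fold
    SummarizedExperiment::rowData(es)$trueFold <- trueFold
    S4Vectors::metadata(es) <- list(
        m = m, s0 = s0, nPerGroup = n, nDEG = nDEG,
        meanRange = meanRange, sdRange = sdRange, foldRange = foldRange,
        degSdFraction = degSdFraction, floor = floor, seed = seed)
    es
}

#' True-DEG flags of a simulated experiment
#'
#' @param x an [EDRSet-class] produced by [simulateExpression()].
#' @return named logical vector, `TRUE` for true DEGs.
#' @export
simulatedTruth <- function(x) {
    stopifnot(methods::is(x, "SummarizedExperiment"))
    rd <- SummarizedExperiment::rowData(x)
    if (!"isDEG" %in% colnames(rd))
        stop("no 'isDEG' flags: not a simulated experiment")
    stats::setNames(rd$isDEG, rownames(x))
}
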