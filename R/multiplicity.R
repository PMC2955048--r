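#' Classical multiplicity corrections
#'
#' Per-gene adjusted values for the standard Type-I-error procedures the
#' parallel-negative EDR is benchmarked against. All procedures are
#' expressed in adjusted-p form so they share one rejection interface
#' ([rejectAt()]): rejecting adjusted values at level \eqn{\alpha} gives
#' the same set as applying each procedure's per-comparison threshold.
#'
#' Methods:
#' \describe{
#'   \item{pcer}{per-comparison error rate: unadjusted, identity.}
#'   \item{pfer}{per-family error rate: \eqn{m p_i}, uncapped — an
#'     expected count of errors, compared against an error budget.}
#'   \item{bonferroni}{\eqn{\min(1, m p_i)} (via [stats::p.adjust()]).}
#'   \item{holm}{step-down running max of \eqn{(m-i+1) p_{(i)}}.}
#'   \item{hochberg}{step-up counterpart of Holm.}
#'   \item{sidak_sd}{Šidák step-down: running max of
#'     \eqn{1-(1-p_{(i)})^{m-i+1}}.}
#'   \item{bh}{Benjamini–Hochberg step-up FDR.}
#'   \item{by}{Benjamini–Yekutieli: BH times \eqn{\sum_{k=1}^m 1/k}.}
#'   \item{qvalue}{Storey q-values: BH scaled by
#'     \eqn{\hat\pi_0 = \#\{p_j > \lambda\} / (m (1-\lambda))} (capped at
#'     1), with the single-\eqn{\lambda} plug-in estimator.}
#' }
#'
#' @param pvalues numeric vector of raw p-values in \eqn{[0, 1]}.
#' @param method one of the names above.
#' @param lambda tuning parameter of the q-value \eqn{\pi_0} estimator,
#'   in \eqn{[0, 1)}; default 0.5.
#' @return an [AdjustedPValues-class] aligned with the input order and
#'   carrying the input names.
#' @examples
#' adjustPValues(c(0.01, 0.02, 0.03), "bonferroni")
#' adjustPValues(c(0.01, 0.04), "by")
#' @export
adjustPValues <- function(pvalues,
                          method = c("pcer", "pfer", "bonferroni", "holm",
                                     "hochberg", "sidak_sd", "bh", "by",
                                     "qvalue"),
                          lambda = 0.5) {
    method <- match.arg(method)
    checkPValues(pvalues)
    m <- length(pvalues)
    params <- list()
    adj <- switch(method,
        pcer = as.numeric(pvalues),
        pfer = m * as.numeric(pvalues),
        bonferroni = stats::p.adjust(pvalues, "bonferroni"),
        holm = stats::p.adjust(pvalues, "holm"),
        hochberg = stats::p.adjust(pvalues, "hochberg"),
        bh = stats::p.adjust(pvalues, "BH"),
        by = stats::p.adjust(pvalues, "BY"),
        sidak_sd = sidakStepDown(pvalues),
        qvalue = {
            if (!is.numeric(lambda) || length(lambda) != 1L ||
                lambda < 0 || lambda >= 1)
                stop("'lambda' must lie in [0, 1)")
            pi0 <- min(1, sum(pvalues > lambda) / (m * (1 - lambda)))
            params <- list(lambda = lambda, pi0 = pi0)
            pmin(1, stats::p.adjust(pvalues, "BH") * pi0)
        })
    adj <- as.numeric(adj)
    names(adj) <- names(pvalues)
    methods::new("AdjustedPValues", adj, method = method, params = params)
}

## Sidak single-step exponents applied step-down, Holm-style.
sidakStepDown <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- cummax(1 - (1 - p[o])^(m - seq_len(m) + 1L))
    adj <- pmin(1, adj)
    out <- numeric(m)
    out[o] <- adj
    out
}

#' Reject hypotheses from adjusted values
#'
#' @param adjusted an [AdjustedPValues-class].
#' @param alpha rejection level; for PFER this is an expected-error-count
#'   budget (default 1 error) rather than a probability.
#' @return integer indices of rejected hypotheses (adjusted value
#'   \eqn{\le \alpha}), in input order.
#' @examples
#' a <- adjustPValues(c(0.01, 0.02, 0.03), "bonferroni")
#' rejectAt(a, 0.05)
#' @export
rejectAt <- function(adjusted, alpha = if (adjustmentMethod(adjusted) ==
                                           "pfer") 1 else 0.05) {
    stopifnot(methods::is(adjusted, "AdjustedPValues"))
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
        stop("'alpha' must be a positive level")
    if (adjusted@method != "pfer" && alpha > 1)
        stop("'alpha' must be in (0, 1] for probability-scale methods")
    which(adjusted@.Data <= alpha)
}
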