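#' Confusion counts against known truth
#'
#' Cross-tabulates a selection of genes against truth flags.
#'
#' @param selected the declared DEGs: either a character vector of gene
#'   identifiers (every one must appear in `names(truth)`) or a logical
#'   vector aligned with `truth`.
#' @param truth logical vector of true-DEG flags, named when `selected`
#'   is given as identifiers.
#' @return named integer vector `c(tp, fp, tn, fn)`; the four counts sum
#'   to `length(truth)`.
#' @examples
#' confusionCounts(c("a", "c"), c(a = TRUE, b = FALSE, c = FALSE, d = TRUE))
#' @export
confusionCounts <- function(selected, truth) {
    if (!is.logical(truth) || length(truth) == 0L || any(is.na(truth)))
        stop("'truth' must be a nonempty logical vector without NAs")
    if (is.character(selected)) {
        if (is.null(names(truth)))
            stop("'truth' must be named when 'selected' holds identifiers")
        unknown <- setdiff(selected, names(truth))
        if (length(unknown))
            stop("selected genes absent from truth: ",
                 paste(utils::head(unknown, 5L), collapse = ", "))
        sel <- names(truth) %in% selected
    } else if (is.logical(selected)) {
        if (length(selected) != length(truth))
            stop("logical 'selected' must align with 'truth'")
        sel <- selected
    } else stop("'selected' must be character identifiers or a logical vector")
    c(tp = sum(sel & truth), fp = sum(sel & !truth),
      tn = sum(!sel & !truth), fn = sum(!sel & truth))
}

#' Classification rates from confusion counts
#'
#' \eqn{TPR = TP/(TP+FN)} (= recall), \eqn{FPR = FP/(FP+TN)},
#' \eqn{Precision = TP/(TP+FP)}. A rate whose denominator is zero is
#' returned as `NA` (undefined), never as 0.
#'
#' @param counts named vector with elements `tp`, `fp`, `tn`, `fn` (as
#'   produced by [confusionCounts()]).
#' @return named numeric vector `c(tpr, fpr, precision, recall)`.
#' @examples
#' rates(c(tp = 90, fp = 980, tn = 3774, fn = 91))
#' @export
rates <- function(counts) {
    need <- c("tp", "fp", "tn", "fn")
    if (!all(need %in% names(counts)))
        stop("'counts' must carry tp, fp, tn, fn")
    counts <- as.numeric(counts[need])
    if (any(counts < 0) || any(is.na(counts)))
        stop("counts must be nonnegative")
    tp <- counts[1L]; fp <- counts[2L]; tn <- counts[3L]; fn <- counts[4L]
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    tpr <- safe(tp, tp + fn)
    c(tpr = tpr, fpr = safe(fp, fp + tn),
      precision = safe(tp, tp + fp), recall = tpr)
}

#' Statistical power at a significance cutoff
#'
#' The proportion of true DEGs whose score (adjusted value or EDR) falls
#' at or below `alpha`.
#'
#' @param scores per-gene values on the p-value scale (lower = more
#'   significant): an [AdjustedPValues-class], an [EDRResults-class]
#'   (its `edr` column is used) or a bare numeric vector, aligned with
#'   `truth`.
#' @param truth logical true-DEG flags.
#' @param alpha cutoff (default 0.05).
#' @return proportion in \eqn{[0, 1]}, or `NA` with a warning when there
#'   are no true DEGs.
#' @examples
#' powerAt(c(0.01, 0.2, 0.5), truth = c(TRUE, TRUE, FALSE), alpha = 0.05)
#' @export
powerAt <- function(scores, truth, alpha = 0.05) {
    s <- extractScores(scores)
    if (!is.logical(truth) || length(truth) != length(s))
        stop("'truth' must be a logical vector aligned with the scores")
    if (sum(truth) == 0L) {
        warning("no true DEGs: power undefined")
        return(NA_real_)
    }
    mean(s[truth] <= alpha)
}

extractScores <- function(scores) {
    if (methods::is(scores, "EDRResults")) scores$edr
    else if (methods::is(scores, "AdjustedPValues")) scores@.Data
    else if (is.numeric(scores)) as.numeric(scores)
    else stop("unsupported score object")
}

#' ROC curve over a score sweep
#'
#' Sweeps the rejection threshold over the sorted unique score values
#' (lower score = more significant); all genes tied at a score enter the
#' selection together. Points are anchored at (0, 0) and (1, 1) and the
#' area under the curve is computed by the trapezoidal rule, so a mass
#' point of capped scores (e.g. EDR = 1) forms a terminal tie block and
#' still yields a well-defined AUC.
#'
#' @inheritParams powerAt
#' @return a list with `method` (score class name), `thresholds`,
#'   `points` (data.frame with `x` = FPR, `y` = TPR) and `auc`.
#' @examples
#' rocCurve(c(0.01, 0.02, 0.6, 0.9), c(TRUE, TRUE, FALSE, FALSE))$auc  # 1
#' @export
rocCurve <- function(scores, truth) {
    sw <- curveSweep(scores, truth)
    fpr <- sw$fp / (sw$fp[length(sw$fp)])   # final point selects all
    tpr <- sw$tp / (sw$tp[length(sw$tp)])
    x <- c(0, fpr); y <- c(0, tpr)
    auc <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
    list(method = class(scores)[1L], thresholds = sw$thresholds,
         points = data.frame(x = x, y = y), auc = auc)
}

#' Precision-recall curve over a score sweep
#'
#' Same unique-score threshold sweep as [rocCurve()], reporting
#' (recall, precision) pairs. The AUC uses the step-wise
#' achievable-points convention (sum of recall increments times the
#' precision attained at each achieved point, from recall 0 up to the
#' full-selection point at recall 1) rather than linear interpolation,
#' which is known to overstate PR performance. Preferred over ROC when
#' true negatives vastly outnumber positives.
#'
#' @inheritParams powerAt
#' @return a list with `method`, `thresholds`, `points` (data.frame with
#'   `x` = recall, `y` = precision) and `auc`.
#' @export
prCurve <- function(scores, truth) {
    sw <- curveSweep(scores, truth)
    recall <- sw$tp / sw$tp[length(sw$tp)]
    precision <- sw$tp / (sw$tp + sw$fp)
    auc <- sum(diff(c(0, recall)) * precision)
    list(method = class(scores)[1L], thresholds = sw$thresholds,
         points = data.frame(x = recall, y = precision), auc = auc)
}

curveSweep <- function(scores, truth) {
    s <- extractScores(scores)
    if (!is.logical(truth) || length(truth) != length(s))
        stop("'truth' must be a logical vector aligned with the scores")
    if (any(is.na(s)) || any(is.na(truth)))
        stop("scores and truth must be complete")
    nPos <- sum(truth); nNeg <- sum(!truth)
    if (nPos == 0L || nNeg == 0L)
        stop("truth must contain both classes")
    thr <- sort(unique(s))
    ord <- order(s)
    cumTP <- cumsum(truth[ord])
    cumFP <- cumsum(!truth[ord])
    ## index of the last gene covered by each unique threshold
    last <- cumsum(tabulate(match(s, thr), nbins = length(thr)))
    list(thresholds = thr, tp = cumTP[last], fp = cumFP[last])
}
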