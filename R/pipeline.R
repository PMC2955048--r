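#' End-to-end analysis pipeline
#'
#' Wires preprocessing, the per-gene EDR analysis, the classical
#' corrections and (when truth is available) the power/ROC/PR evaluation
#' into one call, writing TSV outputs. Identical inputs and settings
#' produce byte-identical outputs.
#'
#' Two input modes:
#' \itemize{
#'   \item an expression matrix plus group design — the full analysis
#'     with the reality factor;
#'   \item a bare p-value vector — the local-EDR path (no matrix, no
#'     reality factor).
#' }
#'
#' @param exprs path to an expression TSV (see
#'   [readExpressionMatrix()]), or an [EDRSet-class], or a numeric
#'   matrix; `NULL` when `pvalues` is given.
#' @param groups path to a design TSV, or a vector of group labels
#'   (named by sample or positional over columns); ignored for an
#'   `EDRSet`.
#' @param pvalues path to a p-value file or a numeric vector; used when
#'   no matrix is given.
#' @param outDir output directory (created if needed).
#' @param alpha significance cutoff (default 0.05).
#' @param methods classical procedures to compute alongside the EDR
#'   (default all of them).
#' @param lo,hi,logTransform,test analysis settings, see [runEDR()];
#'   defaults reproduce the published preprocessing (0.5\%/99.5\%
#'   truncation, natural-log values for the t test).
#' @param truth optional logical truth flags (or a `gene_id<TAB>is_deg`
#'   TSV path) enabling the evaluation report.
#' @param verbose print progress (default TRUE).
#' @return invisibly, a list with `edr` ([EDRResults-class]),
#'   `adjusted` (named list of [AdjustedPValues-class]), `selected`
#'   (gene ids at `alpha`), `evaluation` (data.frame or NULL) and
#'   `files` (paths written).
#' @export
edrPipeline <- function(exprs = NULL, groups = NULL, pvalues = NULL,
                        outDir = ".", alpha = 0.05,
                        methods = c("pcer", "pfer", "bonferroni", "holm",
                                    "hochberg", "sidak_sd", "bh", "by",
                                    "qvalue"),
                        lo = 0.005, hi = 0.995, logTransform = TRUE,
                        test = "t_equal_var", truth = NULL,
                        verbose = TRUE) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    say <- function(...) if (verbose) message(...)

    if (!is.null(exprs)) {
        es <- if (methods::is(exprs, "EDRSet")) {
            exprs
        } else {
            mat <- if (is.character(exprs)) readExpressionMatrix(exprs)
                   else exprs
            grp <- if (is.character(groups) && length(groups) == 1L &&
                       file.exists(groups)) readGroupDesign(groups)
                   else groups
            if (is.null(grp)) stop("a group design is required with a matrix")
            EDRSet(mat, grp)
        }
        say("EDR analysis of ", nrow(es), " genes x ", ncol(es),
            " samples (alpha = ", alpha, ", truncation ", lo, "/", hi,
            ", log = ", logTransform, ", test = ", test, ")")
        res <- runEDR(es, alpha = alpha, lo = lo, hi = hi,
                      logTransform = logTransform, test = test)
    } else if (!is.null(pvalues)) {
        p <- if (is.character(pvalues)) readPValues(pvalues) else pvalues
        say("local EDR from ", length(p), " p-values (no expression matrix)")
        res <- edrFromPValues(p, alpha = alpha)
    } else {
        stop("give either an expression matrix + design or a p-value vector")
    }

    p <- stats::setNames(res$pRaw, rownames(res))
    adjusted <- lapply(methods, function(mth) adjustPValues(p, mth))
    names(adjusted) <- methods

    files <- character(0)
    f <- file.path(outDir, "edr_table.tsv")
    writeEDRTable(res, f); files <- c(files, f)
    if (length(adjusted)) {
        f <- file.path(outDir, "adjusted_values.tsv")
        writeAdjustedTable(adjusted, rownames(res), f)
        files <- c(files, f)
    }
    sel <- selectDEGs(res, alpha)
    f <- file.path(outDir, "selected_degs.tsv")
    writeLines(c("gene_id", sel), f); files <- c(files, f)
    say(length(sel), " genes selected at EDR <= ", alpha)

    evaluation <- NULL
    if (!is.null(truth)) {
        if (is.character(truth) && length(truth) == 1L) {
            tt <- utils::read.delim(truth, stringsAsFactors = FALSE)
            truth <- stats::setNames(tt[[2L]] != 0, tt[[1L]])
        }
        if (!is.null(names(truth))) truth <- truth[rownames(res)]
        if (length(truth) != nrow(res) || any(is.na(truth)))
            stop("truth flags do not cover the analysed genes")
        scoreSets <- c(list(edr = res), adjusted)
        evaluation <- do.call(rbind, lapply(names(scoreSets), function(nm) {
            s <- extractScores(scoreSets[[nm]])
            lvl <- if (nm == "pfer") 1 else alpha
            cc <- confusionCounts(s <= lvl, unname(truth))
            r <- rates(cc)
            data.frame(method = nm, t(cc), t(r), power = r[["tpr"]],
                       row.names = NULL)
        }))
        f <- file.path(outDir, "evaluation.tsv")
        utils::write.table(evaluation, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, f)
    }
    invisible(list(edr = res, adjusted = adjusted, selected = sel,
                   evaluation = evaluation, files = files))
}
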