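#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' EDRSet: an expression matrix with a group design
#'
#' `EDRSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay `"exprs"` holding nonnegative, finite expression
#' intensities on the linear scale (genes in rows, samples in columns)
#' and a mandatory `colData` column `group` giving the sample-to-group
#' assignment. Every group must contain at least two samples so that a
#' within-group variance is estimable.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra
#'   slots are added, the class exists for its validity contract.
#'
#' @seealso [EDRSet()] for the constructor, [sampleGroups()] for the
#'   design accessor.
#' @name EDRSet-class
#' @rdname EDRSet-class
#' @exportClass EDRSet
setClass("EDRSet", contains = "SummarizedExperiment")

setValidity("EDRSet", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'exprs' must be numeric")
        else if (any(!is.finite(v)))
            msg <- c(msg, "assay 'exprs' must be finite (no NA/NaN/Inf)")
        else if (any(v < 0))
            msg <- c(msg, "assay 'exprs' must be nonnegative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- SummarizedExperiment::colData(object)$group
        if (any(is.na(g)))
            msg <- c(msg, "every sample must be assigned to a group")
        else {
            tab <- table(as.character(g))
            if (length(tab) < 2L)
                msg <- c(msg, "at least two groups are required")
            if (any(tab < 2L))
                msg <- c(msg, sprintf(
                    "every group needs >= 2 samples (offending: %s)",
                    paste(names(tab)[tab < 2L], collapse = ", ")))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an EDRSet from a matrix and a group assignment
#'
#' @param exprs numeric matrix of expression intensities, genes in rows
#'   (unique rownames) and samples in columns (unique colnames). Values
#'   must be finite and nonnegative (linear scale, e.g. GC-RMA output).
#' @param groups group label per sample: either an unnamed vector
#'   positional over the columns of `exprs`, or a named vector/factor
#'   whose names are the sample identifiers.
#'
#' @return an [EDRSet-class] object.
#'
#' @examples
#' m <- matrix(rexp(40, 1 / 100), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' es <- EDRSet(m, groups = c("ctl", "ctl", "trt", "trt"))
#' sampleGroups(es)
#' @export
EDRSet <- function(exprs, groups) {
    if (!is.matrix(exprs))
        exprs <- as.matrix(exprs)
    if (length(dim(exprs)) != 2L || nrow(exprs) == 0L || ncol(exprs) == 0L)
        stop("'exprs' must be a nonempty genes x samples matrix")
    if (is.null(rownames(exprs)))
        rownames(exprs) <- paste0("gene", seq_len(nrow(exprs)))
    if (is.null(colnames(exprs)))
        colnames(exprs) <- paste0("sample", seq_len(ncol(exprs)))
    if (!is.null(names(groups))) {
        missing <- setdiff(colnames(exprs), names(groups))
        if (length(missing))
            stop("samples without a group assignment: ",
                 paste(missing, collapse = ", "))
        groups <- groups[colnames(exprs)]
    } else if (length(groups) != ncol(exprs)) {
        stop("positional 'groups' must have one label per sample column (",
             ncol(exprs), "), got ", length(groups))
    }
    cd <- S4Vectors::DataFrame(group = factor(as.character(groups),
                                              levels = unique(as.character(groups))),
                               row.names = colnames(exprs))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(exprs = exprs), colData = cd)
    methods::new("EDRSet", se)
}

#' @describeIn EDRSet group assignment of the samples, as a factor whose
#'   level order is the order of first appearance.
#' @param x an `EDRSet`.
#' @export
sampleGroups <- function(x) {
    stopifnot(methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::colData(x)$group
}

#' EDRResults: per-gene error discovery rates
#'
#' A [S4Vectors::DataFrame] subclass holding one row per gene with the
#' raw p-value, the reliability inputs `x` and `f`, the parallel-negative
#' count `nParallel`, the reality factor `sigma`, the final `edr` and the
#' selection decision at the cutoff stored in `metadata(x)$alpha`.
#' P-value-only analyses (local EDR, no expression matrix) carry `NA` in
#' `x`, `f` and `sigma`.
#'
#' @name EDRResults-class
#' @rdname EDRResults-class
#' @exportClass EDRResults
setClass("EDRResults", contains = "DFrame")

setValidity("EDRResults", function(object) {
    msg <- NULL
    need <- c("pRaw", "nParallel", "edr", "selected")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        msg <- c(msg, paste0("missing columns: ", paste(miss, collapse = ", ")))
    if ("edr" %in% colnames(object)) {
        e <- object$edr
        if (any(!is.na(e) & (e < 0 | e > 1)))
            msg <- c(msg, "edr values must lie in [0, 1]")
    }
    if ("nParallel" %in% colnames(object)) {
        np <- object$nParallel
        if (any(!is.na(np) & (np < 0 | np != floor(np))))
            msg <- c(msg, "nParallel must be nonnegative integers")
    }
    if (is.null(msg)) TRUE else msg
})

#' @importMethodsFrom S4Vectors show
setMethod("show", "EDRResults", function(object) {
    alpha <- S4Vectors::metadata(object)$alpha
    cat(sprintf("EDRResults with %d genes", nrow(object)))
    if (!is.null(alpha))
        cat(sprintf("; %d selected at EDR <= %g",
                    sum(object$selected, na.rm = TRUE), alpha))
    cat("\n")
    methods::callNextMethod()
})

#' AdjustedPValues: one classical multiplicity correction
#'
#' Per-gene adjusted values for a single named procedure, aligned with the
#' input p-value order. All methods except PFER produce values in
#' \eqn{[0, 1]}; PFER values lie in \eqn{[0, m]} (an expected error
#' count, not a probability).
#'
#' @slot method the procedure name.
#' @slot params method parameters (e.g. `lambda` for the q-value).
#' @name AdjustedPValues-class
#' @rdname AdjustedPValues-class
#' @exportClass AdjustedPValues
setClass("AdjustedPValues",
         contains = "numeric",
         slots = c(method = "character", params = "list"))

setValidity("AdjustedPValues", function(object) {
    msg <- NULL
    v <- object@.Data
    if (any(!is.finite(v)))
        msg <- c(msg, "adjusted values must be finite")
    else if (object@method != "pfer" && length(v) && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "adjusted values must lie in [0, 1]")
    else if (object@method == "pfer" && length(v) && min(v) < 0)
        msg <- c(msg, "PFER values must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "AdjustedPValues", function(object) {
    cat(sprintf("AdjustedPValues: method '%s', %d values\n",
                object@method, length(object)))
    print(utils::head(object@.Data, 6L))
    if (length(object) > 6L) cat("...\n")
})

#' @describeIn AdjustedPValues the name of the correction procedure.
#' @param x an `AdjustedPValues` object.
#' @export
adjustmentMethod <- function(x) {
    stopifnot(methods::is(x, "AdjustedPValues"))
    x@method
}
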