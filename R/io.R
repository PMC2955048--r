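#' Read a tab-separated expression matrix
#'
#' Expected layout: a header row `gene_id<TAB>sample1<TAB>...`, then one
#' gene per row with a unique identifier in the first column and numeric
#' intensities in the rest. Malformed rows are reported with their line
#' number; missing values are rejected (no imputation).
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    if (length(lines) < 2L) stop("expression file needs a header and >= 1 gene")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L)
        stop("line 1: header must carry a gene-id column and >= 1 sample")
    samples <- header[-1L]
    if (anyDuplicated(samples))
        stop("line 1: duplicate sample names")
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != length(header))
    if (length(bad))
        stop("line ", bad[1L] + 1L, ": expected ", length(header),
             " fields, found ", nf[bad[1L]])
    ids <- vapply(fields, `[[`, character(1L), 1L)
    if (anyDuplicated(ids))
        stop("duplicate gene identifiers: ",
             paste(utils::head(unique(ids[duplicated(ids)]), 3L),
                   collapse = ", "))
    vals <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
    for (i in seq_along(fields)) {
        row <- suppressWarnings(as.numeric(fields[[i]][-1L]))
        if (any(is.na(row)))
            stop("line ", i + 1L, ": non-numeric or missing value")
        vals[i, ] <- row
    }
    vals
}

#' Read a sample-to-group design file
#'
#' Two tab-separated columns, `sample_id<TAB>group`, one sample per
#' line; a header line is detected and skipped when its second field is
#' literally `group`.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping sample id to group label.
#' @export
readGroupDesign <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty design file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 2L))
        stop("line ", which(lengths(fields) != 2L)[1L],
             ": expected 'sample_id<TAB>group'")
    if (tolower(fields[[1L]][2L]) == "group") fields <- fields[-1L]
    ids <- vapply(fields, `[[`, character(1L), 1L)
    grp <- vapply(fields, `[[`, character(1L), 2L)
    if (anyDuplicated(ids)) stop("duplicate sample ids in design")
    stats::setNames(grp, ids)
}

#' Read a bare p-value vector
#'
#' One p-value per line, optionally preceded by a gene identifier and a
#' tab; a header line is skipped when its last field is non-numeric.
#'
#' @param path path to the file.
#' @return numeric vector of p-values, named when identifiers are
#'   present.
#' @export
readPValues <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty p-value file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) > 2L))
        stop("line ", which(lengths(fields) > 2L)[1L],
             ": expected 'p' or 'gene_id<TAB>p'")
    lastNum <- suppressWarnings(as.numeric(
        vapply(fields, function(f) f[[length(f)]], character(1L))))
    if (is.na(lastNum[1L])) {        # header
        fields <- fields[-1L]
        lastNum <- lastNum[-1L]
    }
    if (any(is.na(lastNum)))
        stop("non-numeric p-value on line ",
             which(is.na(lastNum))[1L] + (length(lines) - length(lastNum)))
    p <- lastNum
    if (all(lengths(fields) == 2L))
        names(p) <- vapply(fields, `[[`, character(1L), 1L)
    checkPValues(p)
    p
}

#' Write per-gene EDR results as TSV
#'
#' Columns `id  raw_p  x_i  f_i  N_prime  EDR` (plus `selected`), with
#' numeric values printed to 8 decimal places.
#'
#' @param res an [EDRResults-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDRTable <- function(res, path) {
    stopifnot(methods::is(res, "EDRResults"))
    fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.8f", v))
    df <- data.frame(id = rownames(res),
                     raw_p = fmt(res$pRaw),
                     x_i = fmt(res$x),
                     f_i = fmt(res$f),
                     N_prime = res$nParallel,
                     EDR = fmt(res$edr),
                     selected = as.integer(res$selected),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a table of adjusted values as TSV
#'
#' @param adjusted a named list of [AdjustedPValues-class] objects (one
#'   column each), all of equal length.
#' @param ids gene identifiers (row order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAdjustedTable <- function(adjusted, ids, path) {
    stopifnot(is.list(adjusted), length(adjusted) >= 1L)
    cols <- lapply(adjusted, function(a) sprintf("%.8f", extractScores(a)))
    df <- data.frame(gene_id = ids, cols, stringsAsFactors = FALSE)
    names(df) <- c("gene_id", names(adjusted))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an expression matrix (and optional truth flags) as TSV
#'
#' @param x an [EDRSet-class] or numeric matrix.
#' @param path output path for the matrix.
#' @param truthPath optional path for a `gene_id<TAB>is_deg` file (only
#'   for simulated experiments carrying `rowData()$isDEG`).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, truthPath = NULL) {
    v <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "exprs") else x
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(truthPath)) {
        truth <- simulatedTruth(x)
        utils::write.table(
            data.frame(gene_id = names(truth), is_deg = as.integer(truth)),
            truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Published worked example: hyperinsulinemia EDR table
#'
#' The seven-gene per-gene EDR table from the hyperinsulinemic
#' case study (human skeletal muscle, insulin infusion, Hu6800 array):
#' raw p-value, expression ratio `x_i`, fold change `f_i`,
#' parallel-negative count `N_prime` and the published EDR for each
#' probe set. Shipped as plain text under `extdata`; used as a worked
#' example and as a regression fixture.
#'
#' @return data.frame with columns `id`, `gene`, `raw_p`, `x_i`, `f_i`,
#'   `N_prime`, `EDR`.
#' @examples
#' tab <- hyperinsulinemiaExample()
#' with(tab, edrScore(raw_p, N_prime, x_i, f_i))
#' @export
hyperinsulinemiaExample <- function() {
    path <- system.file("extdata", "hyperinsulinemia_edr_table.tsv",
                        package = "parallelEDR", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
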