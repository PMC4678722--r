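#' Construct an expression SummarizedExperiment
#'
#' Wraps a genes-by-samples numeric matrix into a
#' [SummarizedExperiment::SummarizedExperiment] with a single `exprs` assay,
#' checking the invariants the pipeline relies on: unique gene ids, unique
#' sample ids, no missing values, all-numeric entries. Values are expected
#' on a log-like scale for arrays; raw RNA-seq counts should go through
#' [logTransform()] first.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param geneIds,sampleIds identifiers; default to the dimnames of `values`.
#' @return a `SummarizedExperiment` with assay `exprs`.
#' @export
expressionMatrix <- function(values, geneIds = rownames(values),
                             sampleIds = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(geneIds) || is.null(sampleIds))
        stop("gene and sample identifiers are required")
    if (length(geneIds) != nrow(values) || length(sampleIds) != ncol(values))
        stop("identifier lengths do not match matrix dimensions")
    dup <- unique(geneIds[duplicated(geneIds)])
    if (length(dup))
        stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
    dup <- unique(sampleIds[duplicated(sampleIds)])
    if (length(dup))
        stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
    if (!is.numeric(values))
        stop("expression values must be numeric")
    if (anyNA(values)) {
        idx <- which(is.na(values), arr.ind = TRUE)[1, ]
        stop(sprintf("missing value at gene '%s', sample '%s'",
                     geneIds[idx[1]], sampleIds[idx[2]]))
    }
    dimnames(values) <- list(geneIds, sampleIds)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
}

.exprs <- function(se) {
    if (is.matrix(se)) return(se)
    SummarizedExperiment::assay(se, "exprs")
}

.replaceExprs <- function(se, values) {
    SummarizedExperiment::assay(se, "exprs") <- values
    se
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' The TSV dialect is tab-delimited UTF-8 with a header row of sample ids
#' whose first column (conventionally named `gene`) holds gene identifiers.
#' GCT 1.2 is the Broad convention: a `#1.2` version line, a dimensions
#' line, then `Name`/`Description` columns ahead of the samples.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"gct"`.
#' @return a `SummarizedExperiment` (see [expressionMatrix()]); row and
#'   column order follow the file.
#' @export
readExpression <- function(path, format = c("tsv", "gct")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "gct") {
        lines <- readLines(path)
        if (length(lines) < 3 || !startsWith(lines[1], "#1.2"))
            stop("not a GCT 1.2 file (missing #1.2 header): ", path)
        dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]])
        tab <- read.delim(text = lines[-(1:2)], header = TRUE,
                          sep = "\t", check.names = FALSE,
                          colClasses = "character")
        if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2])
            stop(sprintf(
                "GCT dimension line says %d x %d but table is %d x %d",
                dims[1], dims[2], nrow(tab), ncol(tab) - 2L))
        geneIds <- tab[[1]]
        num <- tab[, -(1:2), drop = FALSE]
    } else {
        tab <- read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
        if (ncol(tab) < 2)
            stop("TSV needs a gene id column plus at least one sample")
        geneIds <- tab[[1]]
        num <- tab[, -1, drop = FALSE]
    }
    sampleIds <- colnames(num)
    values <- matrix(NA_real_, nrow(num), ncol(num))
    for (j in seq_len(ncol(num))) {
        raw <- num[[j]]
        bad <- is.na(raw) | raw == "" | raw == "NA"
        if (any(bad))
            stop(sprintf("missing value at gene '%s', sample '%s'",
                         geneIds[which(bad)[1]], sampleIds[j]))
        v <- suppressWarnings(as.numeric(raw))
        if (anyNA(v))
            stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                         raw[which(is.na(v))[1]],
                         geneIds[which(is.na(v))[1]], sampleIds[j]))
        values[, j] <- v
    }
    expressionMatrix(values, geneIds, sampleIds)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param se a `SummarizedExperiment` with an `exprs` assay.
#' @param path output file.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(se, path, format = c("tsv", "gct")) {
    format <- match.arg(format)
    m <- .exprs(se)
    if (format == "gct") {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
        tab <- data.frame(Name = rownames(m), Description = rownames(m),
                          m, check.names = FALSE)
        write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
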