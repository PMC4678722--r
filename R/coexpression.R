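#' Pairwise Pearson correlation of gene expression profiles
#'
#' Builds the symmetric gene-by-gene Pearson correlation matrix across
#' samples. Correlation is computed on the filtered, log-scale expression
#' (before any min-max scaling). Constant genes have no defined correlation
#' and are rejected; run [quantileFilter()] first.
#'
#' @param se expression `SummarizedExperiment` with at least 3 samples.
#' @return numeric matrix of Pearson correlations with gene ids as
#'   dimnames; symmetric with unit diagonal.
#' @export
geneCorrelation <- function(se) {
    m <- .exprs(se)
    if (ncol(m) < 3)
        stop("need at least 3 samples for correlation")
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0))
        stop("constant gene(s) have undefined correlation: ",
             paste(head(rownames(m)[sds == 0], 5), collapse = ", "))
    r <- stats::cor(t(m), method = "pearson")
    # enforce exact symmetry and unit diagonal against fp round-off
    r <- (r + t(r)) / 2
    diag(r) <- 1
    r
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' An edge joins genes `i` and `j` (i != j) when `|r[i, j]| >= threshold`;
#' strong negative correlation is as informative as positive for
#' prediction, so the absolute value is used. Ties at exactly the
#' threshold are edges. The diagonal is forced to zero.
#'
#' @param corr symmetric correlation matrix with gene ids as dimnames
#'   (from [geneCorrelation()]).
#' @param threshold `|r_P|` cutoff in (0, 1).
#' @return a [CoexpressionAdjacency-class].
#' @export
binarize <- function(corr, threshold) {
    stopifnot(is.matrix(corr), threshold > 0, threshold < 1)
    if (is.null(rownames(corr)) || !identical(rownames(corr), colnames(corr)))
        stop("correlation matrix needs identical row/column gene ids")
    if (max(abs(corr)) > 1 + 1e-8)
        stop("correlation entries must lie in [-1, 1]")
    e <- (abs(corr) >= threshold) * 1L
    storage.mode(e) <- "integer"
    diag(e) <- 0L
    e[e != t(e)] <- 0L  # guard: asymmetric float dust cannot create edges
    new("CoexpressionAdjacency", edges = e, threshold = threshold)
}

#' Adjacency constructor from a raw 0/1 matrix
#'
#' Convenience for building small graphs directly (tests, examples).
#'
#' @param edges square symmetric 0/1 matrix with gene-id dimnames.
#' @param threshold optional `|r_P|` the matrix was built at.
#' @return a [CoexpressionAdjacency-class].
#' @export
coexpressionAdjacency <- function(edges, threshold = NA_real_) {
    storage.mode(edges) <- "integer"
    new("CoexpressionAdjacency", edges = edges, threshold = threshold)
}

#' Per-gene degree in the co-expression graph
#'
#' @param adj a [CoexpressionAdjacency-class].
#' @return named integer vector: for each gene, the number of genes it is
#'   correlated with beyond the threshold (row sums of the adjacency).
#' @export
geneDegrees <- function(adj) {
    d <- rowSums(edgeMatrix(adj))
    storage.mode(d) <- "integer"
    d
}

#' Genes eligible for direct measurement or prediction
#'
#' A gene is eligible when it is correlated beyond the threshold with at
#' least `redundancy` other genes, i.e. its degree is at least
#' `redundancy`. Eligibility is determined once on the full adjacency; it
#' is not re-derived after restricting the graph (degrees can drop below
#' `redundancy` for redundancy >= 2 after restriction, which is
#' intentional and documented).
#'
#' @param adj a [CoexpressionAdjacency-class].
#' @param redundancy minimum number of correlated genes (integer >= 1).
#' @return character vector of eligible gene ids, in adjacency order.
#' @export
eligibleGenes <- function(adj, redundancy = 1L) {
    stopifnot(redundancy >= 1)
    d <- geneDegrees(adj)
    names(d)[d >= redundancy]
}

#' Restrict an adjacency to its eligible genes
#'
#' Subsets the graph to eligible-by-eligible, the universe from which both
#' the DM and predictable sets are drawn.
#'
#' @inheritParams eligibleGenes
#' @return a [CoexpressionAdjacency-class] over the eligible genes.
#' @export
restrictToEligible <- function(adj, redundancy = 1L) {
    keep <- eligibleGenes(adj, redundancy)
    coexpressionAdjacency(edgeMatrix(adj)[keep, keep, drop = FALSE],
                          threshold = adj@threshold)
}

#' Connected components and mean degree of the co-expression graph
#'
#' Summarizes graph structure: sizes of connected components and the mean
#' degree over non-isolated vertices. Isolated vertices (degree 0) can be
#' reported as singleton components or dropped.
#'
#' @param adj a [CoexpressionAdjacency-class].
#' @param includeIsolated report isolated vertices as size-1 components
#'   (default `FALSE`).
#' @return list with `componentSizes` (decreasing integer vector) and
#'   `meanDegree` (mean over non-isolated vertices; `NaN` on an empty
#'   graph).
#' @export
componentSummary <- function(adj, includeIsolated = FALSE) {
    e <- edgeMatrix(adj)
    g <- igraph::graph_from_adjacency_matrix(e, mode = "undirected")
    comp <- igraph::components(g)
    sizes <- sort(comp$csize, decreasing = TRUE)
    d <- geneDegrees(adj)
    if (!includeIsolated)
        sizes <- sizes[sizes > 1]
    list(componentSizes = as.integer(sizes),
         meanDegree = mean(d[d > 0]))
}

#' Write / read a matrix with gene ids as header and first column
#'
#' Serialization used for correlation and adjacency matrices: TSV with the
#' gene ids as both the header and the first column.
#'
#' @param m matrix with identical row/column names (or a
#'   [CoexpressionAdjacency-class]).
#' @param path file path.
#' @return `writeGeneMatrix`: `path` invisibly; `readGeneMatrix`: the
#'   numeric matrix.
#' @export
writeGeneMatrix <- function(m, path) {
    if (is(m, "CoexpressionAdjacency"))
        m <- edgeMatrix(m)
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneMatrix
#' @export
readGeneMatrix <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m
}
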