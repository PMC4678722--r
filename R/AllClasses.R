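#' @import methods
#' @importFrom stats cor quantile sd predict lm setNames
#' @importFrom utils head read.delim write.table
NULL

#' Binary gene co-expression adjacency matrix
#'
#' Symmetric 0/1 gene-by-gene matrix obtained by thresholding the absolute
#' Pearson correlation of expression profiles. An edge `(i, j)` means
#' `|r_P(i, j)| >= threshold`. The diagonal is always zero. This is the
#' undirected co-expression graph G = (V, E) that drives gene selection.
#'
#' @slot edges integer matrix with 0/1 entries, gene identifiers as both
#'   dimnames, symmetric, zero diagonal.
#' @slot threshold the `|r_P|` cutoff used to build the matrix (`NA_real_`
#'   for adjacencies constructed directly, e.g. in tests).
#'
#' @seealso [binarize()], [ggsSelect()], [eligibleGenes()]
#' @export
setClass("CoexpressionAdjacency",
    slots = c(edges = "matrix", threshold = "numeric"))

setValidity("CoexpressionAdjacency", function(object) {
    e <- object@edges
    msg <- character()
    if (nrow(e) != ncol(e))
        msg <- c(msg, "adjacency matrix must be square")
    if (is.null(rownames(e)) || is.null(colnames(e)) ||
        !identical(rownames(e), colnames(e)))
        msg <- c(msg, "row and column names must be identical gene ids")
    if (anyDuplicated(rownames(e)))
        msg <- c(msg, "duplicate gene ids in adjacency")
    if (nrow(e) > 0) {
        if (!all(e %in% c(0L, 1L)))
            msg <- c(msg, "adjacency entries must be 0 or 1")
        if (!identical(e[cbind(seq_len(nrow(e)), seq_len(nrow(e)))],
                       rep(0L, nrow(e))))
            msg <- c(msg, "adjacency diagonal must be zero")
        if (!identical(e, t(e)))
            msg <- c(msg, "adjacency must be symmetric")
    }
    if (length(object@threshold) != 1L)
        msg <- c(msg, "threshold must be a single value")
    if (length(msg)) msg else TRUE
})

#' Result of a gene panel selection run
#'
#' Holds the ordered directly measured (DM) gene list, the predictable gene
#' set, any user-seeded candidate genes, the selection parameters, and a
#' per-iteration log of the greedy loop.
#'
#' @slot method `"ggs"` or `"ranked"`.
#' @slot dmGenes character, DM genes in selection order (candidates first).
#' @slot predictableGenes character, genes inferable from the DM set.
#' @slot candidateGenes character, the user-seeded subset of `dmGenes`.
#' @slot threshold,redundancy,dmSize selection parameters. `dmSize` is the
#'   number of greedy-selected genes requested (beyond candidates, unless
#'   total-count semantics were used at call time).
#' @slot iterationLog data.frame with one row per greedy iteration: the
#'   chosen gene, its degree in the pruned working adjacency at selection
#'   time, the number of newly predictable genes, and the cumulative
#'   predictable count.
#'
#' @seealso [ggsSelect()], [rankedDegreeSelect()], [predictorSets()]
#' @export
setClass("GeneSelection",
    slots = c(method = "character", dmGenes = "character",
              predictableGenes = "character", candidateGenes = "character",
              threshold = "numeric", redundancy = "integer",
              dmSize = "integer", iterationLog = "data.frame"))

setValidity("GeneSelection", function(object) {
    msg <- character()
    if (length(intersect(object@dmGenes, object@predictableGenes)))
        msg <- c(msg, "DM and predictable sets must be disjoint")
    if (anyDuplicated(object@dmGenes))
        msg <- c(msg, "duplicate genes in DM list")
    if (!all(object@candidateGenes %in% object@dmGenes))
        msg <- c(msg, "candidate genes must all be in the DM list")
    if (length(object@redundancy) != 1L || object@redundancy < 1L)
        msg <- c(msg, "redundancy must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' Per-gene imputation models
#'
#' One fitted regression model per predictable gene. Genes with at least two
#' predictors get a random forest of regression trees; single-predictor
#' genes get a polynomial least-squares fit (intercept + x + x^2 by
#' default). Fitting happens on expression scaled to [0, 1].
#'
#' @slot models named list, one entry per predictable gene with elements
#'   `predictors` (character), `kind` (`"forest"` or `"polynomial"`) and
#'   `fit` (the fitted model object).
#' @slot metadata list of training settings: threshold, redundancy, seed,
#'   forest size, polynomial degree, package version.
#'
#' @seealso [trainModels()], [predictExpression()]
#' @export
setClass("ImputationModelSet",
    slots = c(models = "list", metadata = "list"))

setValidity("ImputationModelSet", function(object) {
    msg <- character()
    if (length(object@models) && is.null(names(object@models)))
        msg <- c(msg, "models must be named by response gene")
    ok <- vapply(object@models, function(m) {
        all(c("predictors", "kind", "fit") %in% names(m)) &&
            m$kind %in% c("forest", "polynomial") &&
            (m$kind == "forest") == (length(m$predictors) >= 2L)
    }, logical(1))
    if (!all(ok))
        msg <- c(msg, "each model needs predictors/kind/fit, forest iff >= 2 predictors")
    if (length(msg)) msg else TRUE
})

#' Imputation accuracy summary
#'
#' Per-gene Spearman rank correlation between observed and predicted
#' expression across samples, its mean over genes, and a bootstrapped
#' standard error of that mean. Models whose response or any predictor was
#' absent from the evaluated dataset are counted as skipped.
#'
#' @slot perGene data.frame with columns `gene` and `rS`.
#' @slot meanRS mean Spearman correlation over evaluated genes.
#' @slot bootstrapSE bootstrap standard error of `meanRS` (NA until
#'   [bootstrapSE()] has been applied by the caller, e.g. [evaluatePredictions()]).
#' @slot nModelsUsed,nModelsSkipped model application counts.
#'
#' @seealso [evaluatePredictions()], [bootstrapSE()]
#' @export
setClass("ImputationEval",
    slots = c(perGene = "data.frame", meanRS = "numeric",
              bootstrapSE = "numeric", nModelsUsed = "integer",
              nModelsSkipped = "integer"))

setValidity("ImputationEval", function(object) {
    msg <- character()
    if (!all(c("gene", "rS") %in% colnames(object@perGene)))
        msg <- c(msg, "perGene needs columns 'gene' and 'rS'")
    rs <- object@perGene$rS
    if (length(rs) && any(!is.na(rs) & abs(rs) > 1 + 1e-12))
        msg <- c(msg, "Spearman correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})
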