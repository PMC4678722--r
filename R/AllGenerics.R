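#' Gene identifiers of a co-expression object
#'
#' @param x a [CoexpressionAdjacency-class] or [GeneSelection-class] object.
#' @return character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "CoexpressionAdjacency", function(x) rownames(x@edges))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSelection",
    function(x) c(x@dmGenes, x@predictableGenes))

#' Edge matrix of a co-expression adjacency
#'
#' @param x a [CoexpressionAdjacency-class].
#' @return the symmetric 0/1 integer matrix of edges.
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname edgeMatrix
#' @export
setMethod("edgeMatrix", "CoexpressionAdjacency", function(x) x@edges)

#' Accessors for selection results
#'
#' @param x a [GeneSelection-class].
#' @return `dmGenes()`: DM genes in selection order; `predictableGenes()`:
#'   the predictable gene set; `candidateGenes()`: user-seeded genes;
#'   `iterationLog()`: per-iteration data.frame of the greedy loop.
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
setGeneric("dmGenes", function(x) standardGeneric("dmGenes"))
#' @rdname selection-accessors
#' @export
setMethod("dmGenes", "GeneSelection", function(x) x@dmGenes)

#' @rdname selection-accessors
#' @export
setGeneric("predictableGenes", function(x) standardGeneric("predictableGenes"))
#' @rdname selection-accessors
#' @export
setMethod("predictableGenes", "GeneSelection", function(x) x@predictableGenes)

#' @rdname selection-accessors
#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))
#' @rdname selection-accessors
#' @export
setMethod("candidateGenes", "GeneSelection", function(x) x@candidateGenes)

#' @rdname selection-accessors
#' @export
setGeneric("iterationLog", function(x) standardGeneric("iterationLog"))
#' @rdname selection-accessors
#' @export
setMethod("iterationLog", "GeneSelection", function(x) x@iterationLog)

#' Accessors for imputation evaluations
#'
#' @param x an [ImputationEval-class].
#' @return `spearmanPerGene()`: data.frame of per-gene Spearman r_S;
#'   `spearmanMean()`: mean r_S over genes; `spearmanSE()`: bootstrap
#'   standard error of the mean; `modelsUsed()` / `modelsSkipped()`:
#'   application counts.
#' @name evaluation-accessors
NULL

#' @rdname evaluation-accessors
#' @export
setGeneric("spearmanPerGene", function(x) standardGeneric("spearmanPerGene"))
#' @rdname evaluation-accessors
#' @export
setMethod("spearmanPerGene", "ImputationEval", function(x) x@perGene)

#' @rdname evaluation-accessors
#' @export
setGeneric("spearmanMean", function(x) standardGeneric("spearmanMean"))
#' @rdname evaluation-accessors
#' @export
setMethod("spearmanMean", "ImputationEval", function(x) x@meanRS)

#' @rdname evaluation-accessors
#' @export
setGeneric("spearmanSE", function(x) standardGeneric("spearmanSE"))
#' @rdname evaluation-accessors
#' @export
setMethod("spearmanSE", "ImputationEval", function(x) x@bootstrapSE)

#' @rdname evaluation-accessors
#' @export
setGeneric("modelsUsed", function(x) standardGeneric("modelsUsed"))
#' @rdname evaluation-accessors
#' @export
setMethod("modelsUsed", "ImputationEval", function(x) x@nModelsUsed)

#' @rdname evaluation-accessors
#' @export
setGeneric("modelsSkipped", function(x) standardGeneric("modelsSkipped"))
#' @rdname evaluation-accessors
#' @export
setMethod("modelsSkipped", "ImputationEval", function(x) x@nModelsSkipped)

#' Models in an imputation model set
#'
#' @param x an [ImputationModelSet-class].
#' @return named list of per-gene model records.
#' @export
setGeneric("imputationModels", function(x) standardGeneric("imputationModels"))
#' @rdname imputationModels
#' @export
setMethod("imputationModels", "ImputationModelSet", function(x) x@models)

setMethod("show", "CoexpressionAdjacency", function(object) {
    n <- nrow(object@edges)
    ne <- sum(object@edges) / 2
    cat(sprintf("CoexpressionAdjacency: %d genes, %d edges", n, ne))
    if (!is.na(object@threshold))
        cat(sprintf(" (|r_P| >= %.2f)", object@threshold))
    cat("\n")
    if (n > 0)
        cat(sprintf("  mean degree %.2f; genes: %s%s\n",
            2 * ne / n, paste(head(rownames(object@edges), 4), collapse = ", "),
            if (n > 4) ", ..." else ""))
})

setMethod("show", "GeneSelection", function(object) {
    cat(sprintf(
        "GeneSelection (%s): %d DM genes (%d candidates), %d predictable\n",
        object@method, length(object@dmGenes), length(object@candidateGenes),
        length(object@predictableGenes)))
    cat(sprintf("  threshold %s, redundancy %d, requested size %d\n",
        format(object@threshold), object@redundancy, object@dmSize))
})

setMethod("show", "ImputationModelSet", function(object) {
    kinds <- vapply(object@models, `[[`, character(1), "kind")
    cat(sprintf("ImputationModelSet: %d models (%d forest, %d polynomial)\n",
        length(kinds), sum(kinds == "forest"), sum(kinds == "polynomial")))
})

setMethod("show", "ImputationEval", function(object) {
    cat(sprintf(
        "ImputationEval: %d genes evaluated (%d skipped); mean r_S = %.3f (SE %.4f)\n",
        object@nModelsUsed, object@nModelsSkipped, object@meanRS,
        object@bootstrapSE))
})
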