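.checkUnit <- function(m, what) {
    if (min(m) < -1e-8 || max(m) > 1 + 1e-8)
        stop(what, " must be scaled to [0, 1]; see minmaxScale()")
}

#' Train per-gene expression imputation models
#'
#' Fits one regression model per predictable gene on the (min-max scaled)
#' training partition. When a gene has at least two predictors a random
#' forest of regression trees is used; with a single predictor a
#' polynomial least-squares model with intercept, `x` and `x^2` terms is
#' fitted (the degree is configurable). Genes are fitted in a fixed
#' (byte-sorted) order under a seeded RNG, so the model set is
#' reproducible.
#'
#' @param trainSE training `SummarizedExperiment`, values in [0, 1]
#'   (see [minmaxScale()]).
#' @param predictors named list mapping each response gene to its DM
#'   predictor genes, as produced by [predictorSets()].
#' @param seed integer RNG seed for forest fitting.
#' @param nTrees trees per random forest (default 500).
#' @param degree polynomial degree for single-predictor models
#'   (default 2: intercept + x + x^2).
#' @param metadata optional list of extra settings to record (threshold,
#'   redundancy, ...).
#' @return an [ImputationModelSet-class].
#' @export
trainModels <- function(trainSE, predictors, seed = 1L, nTrees = 500L,
                        degree = 2L, metadata = list()) {
    m <- .exprs(trainSE)
    .checkUnit(m, "training expression")
    genes <- .radixSort(names(predictors))
    missing <- setdiff(
        unique(c(genes, unlist(predictors, use.names = FALSE))),
        rownames(m))
    if (length(missing))
        stop("gene(s) required for training absent from the matrix: ",
             paste(head(missing, 5), collapse = ", "))
    models <- withr::with_seed(seed, lapply(genes, function(g) {
        px <- predictors[[g]]
        y <- m[g, ]
        if (length(px) >= 2L) {
            x <- t(m[px, , drop = FALSE])
            fit <- randomForest::randomForest(x = x, y = y,
                                              ntree = nTrees)
            list(predictors = px, kind = "forest", fit = fit)
        } else {
            df <- data.frame(y = y, x = m[px, ])
            terms <- paste0("I(x^", seq_len(degree), ")")
            fit <- stats::lm(stats::reformulate(terms, "y"), data = df)
            list(predictors = px, kind = "polynomial", fit = fit)
        }
    }))
    names(models) <- genes
    md <- c(list(seed = seed, nTrees = nTrees, degree = degree,
                 nSamplesTrain = ncol(m),
                 packageVersion = as.character(utils::packageVersion("ggsel"))),
            metadata)
    new("ImputationModelSet", models = models, metadata = md)
}

#' Predict expression of unmeasured genes
#'
#' Applies the fitted models to a dataset. A model is used only when its
#' response gene and every one of its predictor genes are present in the
#' dataset (so that the prediction can later be scored against the truth);
#' other models are skipped and counted. Gene matching is exact and
#' case-sensitive.
#'
#' @param models an [ImputationModelSet-class].
#' @param se dataset `SummarizedExperiment`, values in [0, 1]; must
#'   contain the predictor (and response) genes of the models to apply.
#' @return `SummarizedExperiment` of predicted expression over the
#'   applicable predictable genes and all samples of `se`;
#'   `metadata()$nModelsUsed` / `$nModelsSkipped` hold the counts.
#' @export
predictExpression <- function(models, se) {
    m <- .exprs(se)
    .checkUnit(m, "expression to predict from")
    mods <- imputationModels(models)
    usable <- vapply(names(mods), function(g) {
        g %in% rownames(m) && all(mods[[g]]$predictors %in% rownames(m))
    }, logical(1))
    if (!any(usable))
        stop("no model is applicable: every model has its response or ",
             "a predictor absent from this dataset")
    pred <- vapply(names(mods)[usable], function(g) {
        mod <- mods[[g]]
        if (mod$kind == "forest") {
            x <- t(m[mod$predictors, , drop = FALSE])
            unname(stats::predict(mod$fit, newdata = x))
        } else {
            unname(stats::predict(mod$fit,
                                  newdata = data.frame(x = m[mod$predictors, ])))
        }
    }, numeric(ncol(m)))
    out <- expressionMatrix(t(pred), names(mods)[usable], colnames(m))
    S4Vectors::metadata(out)$nModelsUsed <- sum(usable)
    S4Vectors::metadata(out)$nModelsSkipped <- sum(!usable)
    out
}

#' Score predictions against observed expression
#'
#' For every gene shared between the predicted and observed matrices,
#' computes the Spearman rank correlation `r_S` across the shared samples
#' (average ranks for ties), then summarizes with the mean over genes and
#' a bootstrapped standard error of that mean. Because the score is
#' rank-based it is invariant to any strictly monotone per-gene transform
#' of the predictions, which is what makes it robust across platforms.
#'
#' @param predicted `SummarizedExperiment` from [predictExpression()].
#' @param truth `SummarizedExperiment` of observed expression.
#' @param nBoot bootstrap resamples for the standard error (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an [ImputationEval-class].
#' @export
evaluatePredictions <- function(predicted, truth, nBoot = 1000L,
                                seed = 1L) {
    p <- .exprs(predicted)
    o <- .exprs(truth)
    genes <- intersect(rownames(p), rownames(o))
    samples <- intersect(colnames(p), colnames(o))
    if (length(samples) < 3)
        stop("need at least 3 shared samples to evaluate")
    if (!length(genes))
        stop("no shared genes between predictions and truth")
    rS <- vapply(genes, function(g) {
        suppressWarnings(
            stats::cor(p[g, samples], o[g, samples], method = "spearman"))
    }, numeric(1))
    ok <- !is.na(rS)
    md <- S4Vectors::metadata(predicted)
    nUsed <- if (!is.null(md$nModelsUsed)) md$nModelsUsed else length(genes)
    nSkip <- if (!is.null(md$nModelsSkipped)) md$nModelsSkipped else 0L
    new("ImputationEval",
        perGene = data.frame(gene = genes, rS = unname(rS)),
        meanRS = mean(rS[ok]),
        bootstrapSE = bootstrapSE(rS[ok], B = nBoot, seed = seed),
        nModelsUsed = as.integer(nUsed),
        nModelsSkipped = as.integer(nSkip))
}

#' Bootstrap standard error of a mean
#'
#' Standard deviation of the means of `B` seeded with-replacement
#' resamples of the input values; used to put an error bar on the mean
#' per-gene Spearman correlation.
#'
#' @param values numeric vector (e.g. per-gene `r_S`).
#' @param B number of resamples (default 1000).
#' @param seed RNG seed.
#' @return the bootstrap standard error (0 for constant or singleton
#'   input).
#' @export
bootstrapSE <- function(values, B = 1000L, seed = 1L) {
    stopifnot(length(values) >= 1, B >= 2)
    n <- length(values)
    means <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
        mean(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1)))
    stats::sd(means)
}
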