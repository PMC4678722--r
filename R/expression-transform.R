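#' Remove genes with no or low expression
#'
#' Computes a per-gene expression quantile across samples (default the 90th
#' percentile, linear-interpolation convention, `stats::quantile` type 7)
#' and keeps only genes whose quantile is at least `cutoff`. On array data
#' with a bimodal quantile distribution this separates truly expressed
#' genes from background; the default cutoff of 5 sits between the two
#' modes on log-scale Affymetrix data.
#'
#' The per-gene quantile values are attached to the returned object as
#' `rowData(se)$exprQuantile`, and the full pre-filter report (every input
#' gene, its quantile, and the retention decision) is stored in
#' `metadata(se)$filterReport` for plotting.
#'
#' @param se expression `SummarizedExperiment`.
#' @param quantile quantile level in (0, 1); default 0.90.
#' @param cutoff minimum quantile value for retention; default 5.
#' @return the filtered `SummarizedExperiment`.
#' @export
quantileFilter <- function(se, quantile = 0.90, cutoff = 5) {
    stopifnot(quantile > 0, quantile < 1)
    m <- .exprs(se)
    if (ncol(m) < 2)
        stop("quantile filtering needs at least 2 samples")
    q <- apply(m, 1, stats::quantile, probs = quantile, names = FALSE,
               type = 7)
    keep <- q >= cutoff
    if (!any(keep))
        stop("no genes pass the expression filter; the cutoff (", cutoff,
             ") is too strict for these data")
    out <- se[keep, ]
    SummarizedExperiment::rowData(out)$exprQuantile <- q[keep]
    S4Vectors::metadata(out)$filterReport <- data.frame(
        gene = rownames(m), exprQuantile = q, retained = keep,
        row.names = NULL)
    out
}

#' Scale each gene to the range [0, 1]
#'
#' Per-gene min-max scaling, `(x - min) / (max - min)`, applied
#' independently within a dataset. Used immediately before regression model
#' training or application; evaluation is rank-based, so scaling each
#' cohort separately does not affect accuracy.
#'
#' @param se expression `SummarizedExperiment`.
#' @return the scaled `SummarizedExperiment`; every gene attains 0 and 1.
#' @export
minmaxScale <- function(se) {
    m <- .exprs(se)
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    flat <- hi <= lo
    if (any(flat))
        stop("constant gene(s) cannot be min-max scaled: ",
             paste(head(rownames(m)[flat], 5), collapse = ", "))
    .replaceExprs(se, (m - lo) / (hi - lo))
}

#' Log-transform expression values
#'
#' Element-wise `log(x + pseudocount)`; intended for RNA-seq counts before
#' scaling. Defaults to base 2 with pseudocount 1, so zero counts map to 0.
#'
#' @param se expression `SummarizedExperiment` with non-negative values.
#' @param base logarithm base (default 2).
#' @param pseudocount value added before the log (default 1).
#' @return the transformed `SummarizedExperiment`.
#' @export
logTransform <- function(se, base = 2, pseudocount = 1) {
    m <- .exprs(se)
    if (any(m < 0))
        stop("log transform requires non-negative values")
    .replaceExprs(se, log(m + pseudocount, base = base))
}

#' Split samples into training and testing partitions
#'
#' Samples are shuffled with a seeded RNG and cut; the training partition
#' receives `round(trainFraction * n)` samples and the testing partition
#' the rest. No stratification is applied. The split is deterministic given
#' the seed and leaves the caller's RNG state untouched.
#'
#' @param se expression `SummarizedExperiment` with at least 3 samples.
#' @param trainFraction fraction of samples to train on (default 2/3).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`, both
#'   `SummarizedExperiment`s over disjoint sample sets whose union is the
#'   input.
#' @export
trainTestSplit <- function(se, trainFraction = 2 / 3, seed = 1L) {
    stopifnot(trainFraction > 0, trainFraction < 1)
    n <- ncol(.exprs(se))
    if (n < 3)
        stop("need at least 3 samples to split")
    perm <- withr::with_seed(seed, sample.int(n))
    nTrain <- round(trainFraction * n)
    nTrain <- max(1L, min(n - 1L, nTrain))
    list(train = se[, sort(perm[seq_len(nTrain)])],
         test = se[, sort(perm[-seq_len(nTrain)])])
}
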