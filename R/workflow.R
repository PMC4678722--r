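#' Assemble a configuration for the full workflow
#'
#' Collects paths, parameters and seeds for [runFullWorkflow()]. Either
#' `input` (a TSV/GCT expression file) or `synthetic` (a [syntheticSpec()],
#' simulated at run time) must be given. Every stochastic stage has its
#' own explicit seed so a run is reproducible end to end.
#'
#' @param outDir output directory (created if needed).
#' @param input path to an expression matrix file, or `NULL`.
#' @param inputFormat `"tsv"` or `"gct"`.
#' @param synthetic a [syntheticSpec()] to simulate instead of reading
#'   `input`.
#' @param logInput log-transform the input first (RNA-seq counts).
#' @param filterQuantile,filterCutoff expression filter settings
#'   (see [quantileFilter()]).
#' @param threshold,redundancy,dmSize selection parameters for the main
#'   run.
#' @param method `"ggs"` or `"ranked"`.
#' @param candidates optional character vector, or path to a file of gene
#'   symbols (one per line), seeded into the DM set.
#' @param sweep optional list with `thresholds`, `redundancies`,
#'   `dmSizes` to also run [parameterSweep()].
#' @param trainFraction training fraction for the sample split.
#' @param nTrees,nBoot forest size and bootstrap resamples.
#' @param seeds list of seeds: `split`, `forest`, `bootstrap`.
#' @param verbose emit per-stage messages.
#' @return list of class `ggsel_config`.
#' @export
runConfig <- function(outDir, input = NULL, inputFormat = "tsv",
                      synthetic = NULL, logInput = FALSE,
                      filterQuantile = 0.90, filterCutoff = 5,
                      threshold = 0.70, redundancy = 3L, dmSize = 50L,
                      method = c("ggs", "ranked"), candidates = NULL,
                      sweep = NULL, trainFraction = 2 / 3,
                      nTrees = 500L, nBoot = 1000L,
                      seeds = list(split = 1L, forest = 2L,
                                   bootstrap = 3L),
                      verbose = TRUE) {
    if (is.null(input) && is.null(synthetic))
        stop("either 'input' or 'synthetic' must be provided")
    cfg <- list(outDir = outDir, input = input, inputFormat = inputFormat,
                synthetic = synthetic, logInput = logInput,
                filterQuantile = filterQuantile,
                filterCutoff = filterCutoff, threshold = threshold,
                redundancy = as.integer(redundancy),
                dmSize = as.integer(dmSize),
                method = match.arg(method), candidates = candidates,
                sweep = sweep, trainFraction = trainFraction,
                nTrees = as.integer(nTrees), nBoot = as.integer(nBoot),
                seeds = seeds, verbose = verbose)
    class(cfg) <- "ggsel_config"
    cfg
}

.stageMsg <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

.selectionAsList <- function(sel) {
    log <- iterationLog(sel)
    attr(log, "notes") <- NULL
    list(method = sel@method,
         dm_genes = dmGenes(sel),
         predictable_genes = predictableGenes(sel),
         candidate_genes = candidateGenes(sel),
         params = list(threshold = sel@threshold,
                       redundancy = sel@redundancy,
                       dm_size = sel@dmSize),
         notes = attr(iterationLog(sel), "notes"),
         iteration_log = log)
}

.evalAsList <- function(ev) {
    list(per_gene = spearmanPerGene(ev),
         mean_rS = spearmanMean(ev),
         bootstrap_se = spearmanSE(ev),
         n_models_used = modelsUsed(ev),
         n_models_skipped = modelsSkipped(ev))
}

#' Run the complete selection and imputation workflow
#'
#' Executes, in order: expression ingestion (file or simulation), optional
#' log transform, quantile filtering, correlation, thresholding to a
#' binary adjacency, eligibility restriction, gene selection (and an
#' optional parameter sweep), train/test sample split, per-dataset
#' min-max scaling, model training, prediction on the test partition, and
#' Spearman evaluation. All artifacts are written under `config$outDir`
#' together with a machine-readable `manifest.json` recording inputs,
#' parameters, seeds, package versions, completed stages, and an MD5
#' checksum for every output file. Any stage failure aborts with the
#' stage name attached.
#'
#' @param config a [runConfig()].
#' @return (invisibly) list with the in-memory results: `selection`,
#'   `models`, `evaluation`, `sweep`, and `manifest`.
#' @export
runFullWorkflow <- function(config) {
    stopifnot(inherits(config, "ggsel_config"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    outputs <- character()
    stages <- character()
    out <- function(name) file.path(config$outDir, name)
    stage <- function(name, fun) {
        .stageMsg(config, "[", name, "] ...")
        res <- tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        stages <<- c(stages, name)
        res
    }

    se <- stage("ingest", function() {
        if (!is.null(config$synthetic)) {
            sim <- generateBlockExpression(config$synthetic)
            sim$se
        } else {
            readExpression(config$input, config$inputFormat)
        }
    })
    if (config$logInput)
        se <- stage("log_transform", function() logTransform(se))

    filtered <- stage("filter", function() {
        f <- quantileFilter(se, config$filterQuantile, config$filterCutoff)
        writeExpression(f, out("filtered.tsv"))
        outputs <<- c(outputs, out("filtered.tsv"))
        f
    })

    corr <- stage("correlate", function() {
        r <- geneCorrelation(filtered)
        writeGeneMatrix(round(r, 10), out("correlation.tsv"))
        outputs <<- c(outputs, out("correlation.tsv"))
        r
    })

    adj <- stage("binarize", function() {
        a <- binarize(corr, config$threshold)
        writeGeneMatrix(a, out("adjacency.tsv"))
        outputs <<- c(outputs, out("adjacency.tsv"))
        a
    })

    candidates <- config$candidates
    if (length(candidates) == 1 && is.character(candidates) &&
        file.exists(candidates))
        candidates <- readLines(candidates)

    selection <- stage("select", function() {
        adjE <- restrictToEligible(adj, config$redundancy)
        sel <- if (config$method == "ggs")
            ggsSelect(adjE, dmSize = config$dmSize,
                      redundancy = config$redundancy,
                      candidates = candidates)
        else
            rankedDegreeSelect(adjE, dmSize = config$dmSize,
                               redundancy = config$redundancy)
        jsonlite::write_json(.selectionAsList(sel), out("selection.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        outputs <<- c(outputs, out("selection.json"))
        sel
    })

    sweepTab <- NULL
    if (!is.null(config$sweep)) {
        sweepTab <- stage("sweep", function() {
            tab <- parameterSweep(corr,
                                  thresholds = config$sweep$thresholds,
                                  redundancies = config$sweep$redundancies,
                                  dmSizes = config$sweep$dmSizes,
                                  candidates = candidates)
            write.table(tab, out("sweep.tsv"), sep = "\t", quote = FALSE,
                        row.names = FALSE)
            outputs <<- c(outputs, out("sweep.tsv"))
            tab
        })
    }

    parts <- stage("split", function()
        trainTestSplit(filtered, config$trainFraction,
                       seed = config$seeds$split))

    models <- stage("train", function() {
        preds <- predictorSets(adj, selection)
        trainModels(minmaxScale(parts$train), preds,
                    seed = config$seeds$forest, nTrees = config$nTrees,
                    metadata = list(threshold = config$threshold,
                                    redundancy = config$redundancy))
    })

    predicted <- stage("predict", function() {
        p <- predictExpression(models, minmaxScale(parts$test))
        writeExpression(p, out("predicted.tsv"))
        outputs <<- c(outputs, out("predicted.tsv"))
        p
    })

    evaluation <- stage("evaluate", function() {
        ev <- evaluatePredictions(predicted, minmaxScale(parts$test),
                                  nBoot = config$nBoot,
                                  seed = config$seeds$bootstrap)
        jsonlite::write_json(.evalAsList(ev), out("evaluation.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        outputs <<- c(outputs, out("evaluation.json"))
        ev
    })

    manifest <- list(
        parameters = config[setdiff(names(config),
                                    c("verbose", "synthetic"))],
        synthetic = if (!is.null(config$synthetic))
            unclass(config$synthetic),
        seeds = config$seeds,
        versions = list(
            ggsel = as.character(utils::packageVersion("ggsel")),
            R = paste(R.version$major, R.version$minor, sep = ".")),
        stages_completed = stages,
        outputs = lapply(outputs, function(p)
            list(file = basename(p),
                 md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(selection = selection, models = models,
                   evaluation = evaluation, sweep = sweepTab,
                   manifest = manifest))
}
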