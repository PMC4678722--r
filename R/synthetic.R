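#' Specification for a planted-block synthetic expression matrix
#'
#' Describes a single-factor-per-block generative model: genes in a block
#' share a latent Gaussian factor, `x = loading * factor + noise`, so the
#' expected pairwise Pearson correlation within a block is
#' `loading^2 / (loading^2 + noiseSd^2)` and between blocks is 0. Blocks
#' become near-cliques in the thresholded co-expression graph, which makes
#' eligible and predictable gene counts analytically predictable (see
#' [plantedExpectations()]). Background genes are independent, and a
#' fraction of genes is planted below the expression cutoff so that
#' [quantileFilter()] has something to remove.
#'
#' Defaults (5 blocks of 10 genes, 500 samples, expected within-block
#' r = 0.8, 100 background genes) describe a compact, strongly separated
#' structure: the within-block correlation is well above any practical
#' threshold and the null correlation of background pairs at n = 500 is
#' far below it.
#'
#' @param nBlocks number of correlated blocks.
#' @param blockSize genes per block.
#' @param nSamples samples to draw.
#' @param withinLoading latent factor loading in (0, 1].
#' @param noiseSd residual standard deviation.
#' @param nBackground independent (uncorrelated) genes.
#' @param lowExpressionFraction fraction of all genes planted below the
#'   expression cutoff.
#' @param baseMean mean log-expression of expressed genes (default 8,
#'   comfortably above the default filter cutoff of 5).
#' @param lowMean mean log-expression of planted low genes (default 2).
#' @param seed integer RNG seed.
#' @return list of class `ggsel_synthetic_spec`; `$expectedR` holds the
#'   implied within-block correlation.
#' @export
syntheticSpec <- function(nBlocks = 5L, blockSize = 10L, nSamples = 500L,
                          withinLoading = 1, noiseSd = 0.5,
                          nBackground = 100L,
                          lowExpressionFraction = 0.2,
                          baseMean = 8, lowMean = 2, seed = 42L) {
    stopifnot(nBlocks >= 0, blockSize >= 0, nSamples >= 0,
              withinLoading > 0, withinLoading <= 1, noiseSd >= 0,
              nBackground >= 0, lowExpressionFraction >= 0,
              lowExpressionFraction < 1)
    spec <- list(nBlocks = as.integer(nBlocks),
                 blockSize = as.integer(blockSize),
                 nSamples = as.integer(nSamples),
                 withinLoading = withinLoading, noiseSd = noiseSd,
                 nBackground = as.integer(nBackground),
                 lowExpressionFraction = lowExpressionFraction,
                 baseMean = baseMean, lowMean = lowMean,
                 seed = as.integer(seed))
    spec$expectedR <- withinLoading^2 / (withinLoading^2 + noiseSd^2)
    class(spec) <- "ggsel_synthetic_spec"
    spec
}

#' Latent-factor loading that yields a target within-block correlation
#'
#' Inverts `r = loading^2 / (loading^2 + noiseSd^2)`.
#'
#' @param r target expected within-block Pearson correlation in (0, 1).
#' @param noiseSd residual standard deviation.
#' @return the loading.
#' @export
loadingForR <- function(r, noiseSd) {
    stopifnot(r > 0, r < 1, noiseSd > 0)
    noiseSd * sqrt(r / (1 - r))
}

.synthGeneNames <- function(spec) {
    nLow <- .nLowGenes(spec)
    c(if (spec$nBlocks * spec$blockSize)
          sprintf("BLK%02d_G%02d",
                  rep(seq_len(spec$nBlocks), each = spec$blockSize),
                  rep(seq_len(spec$blockSize), spec$nBlocks)),
      if (spec$nBackground) sprintf("BG_G%03d", seq_len(spec$nBackground)),
      if (nLow) sprintf("LOW_G%03d", seq_len(nLow)))
}

.nLowGenes <- function(spec) {
    nHigh <- spec$nBlocks * spec$blockSize + spec$nBackground
    f <- spec$lowExpressionFraction
    as.integer(round(nHigh * f / (1 - f)))
}

.simulate <- function(spec, nSamples, noiseSd, samplePrefix) {
    nBlockGenes <- spec$nBlocks * spec$blockSize
    nLow <- .nLowGenes(spec)
    genes <- .synthGeneNames(spec)
    samples <- sprintf("%s%04d", samplePrefix, seq_len(nSamples))
    vals <- matrix(0, length(genes), nSamples,
                   dimnames = list(genes, samples))
    blockOf <- c(rep(seq_len(spec$nBlocks), each = spec$blockSize),
                 rep(NA_integer_, spec$nBackground + nLow))
    for (b in seq_len(spec$nBlocks)) {
        f <- stats::rnorm(nSamples)
        rows <- which(blockOf == b)
        vals[rows, ] <- spec$withinLoading *
            matrix(f, length(rows), nSamples, byrow = TRUE) +
            matrix(stats::rnorm(length(rows) * nSamples, sd = noiseSd),
                   length(rows), nSamples) + spec$baseMean
    }
    if (spec$nBackground) {
        rows <- nBlockGenes + seq_len(spec$nBackground)
        vals[rows, ] <- matrix(stats::rnorm(spec$nBackground * nSamples,
                                            mean = spec$baseMean, sd = 1),
                               spec$nBackground, nSamples)
    }
    if (nLow) {
        rows <- nBlockGenes + spec$nBackground + seq_len(nLow)
        vals[rows, ] <- matrix(stats::rnorm(nLow * nSamples,
                                            mean = spec$lowMean, sd = 0.5),
                               nLow, nSamples)
    }
    blocks <- c(as.character(rep(seq_len(spec$nBlocks),
                                 each = spec$blockSize)),
                rep("background", spec$nBackground), rep("low", nLow))
    names(blocks) <- genes
    list(se = expressionMatrix(vals), blocks = blocks,
         expectedR = spec$expectedR)
}

#' Generate a block-correlated synthetic expression matrix
#'
#' Draws an expression matrix from the model described by
#' [syntheticSpec()]: block genes share a latent factor, background genes
#' are independent, and low-expression genes sit below the filter cutoff.
#' Deterministic given the spec's seed; the caller's RNG state is
#' untouched.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `se` (expression `SummarizedExperiment`), `blocks`
#'   (named character vector: block number, `"background"`, or `"low"`
#'   per gene), and `expectedR` (implied within-block correlation).
#' @export
generateBlockExpression <- function(spec) {
    stopifnot(inherits(spec, "ggsel_synthetic_spec"))
    withr::with_seed(spec$seed,
        .simulate(spec, spec$nSamples, spec$noiseSd, "S"))
}

#' Generate a paired validation cohort
#'
#' New samples from the same latent block structure, optionally with a
#' different noise level or size — a stand-in for an independent cohort
#' on another platform, used to exercise cross-dataset evaluation.
#'
#' @param spec a [syntheticSpec()].
#' @param nSamples cohort size (defaults to the spec's).
#' @param noiseSd residual noise (defaults to the spec's).
#' @param seed RNG seed for the cohort (defaults to spec seed + 1).
#' @return as [generateBlockExpression()].
#' @export
generateValidationCohort <- function(spec, nSamples = spec$nSamples,
                                     noiseSd = spec$noiseSd,
                                     seed = spec$seed + 1L) {
    stopifnot(inherits(spec, "ggsel_synthetic_spec"))
    withr::with_seed(as.integer(seed),
        .simulate(spec, as.integer(nSamples), noiseSd, "V"))
}

#' Expected selection outcomes on planted-block data
#'
#' Closed-form expectations assuming perfect edge recovery (within-block
#' correlation well above the threshold, background well below): every
#' block is a clique, so a block gene is eligible iff
#' `blockSize - 1 >= redundancy` and background/low genes never are.
#' Greedy selection takes DM genes round-robin across blocks (each pick
#' prunes within one block only), a block yields its remaining genes as
#' predictable once it holds `redundancy` DM genes, and a resolved block
#' accepts no further picks. With `dmSize = redundancy * nBlocks` this
#' gives `nBlocks * (blockSize - redundancy)` predictable genes.
#'
#' @param spec a [syntheticSpec()].
#' @param threshold edge threshold (must separate within-block from
#'   background correlation).
#' @param redundancy fold redundancy.
#' @param dmSize requested greedy DM set size.
#' @return list with `nEligible`, `nPredictable`, and `nDMUsable` (picks
#'   the greedy loop can actually make before exhaustion).
#' @export
plantedExpectations <- function(spec, threshold, redundancy, dmSize) {
    stopifnot(inherits(spec, "ggsel_synthetic_spec"),
              redundancy >= 1, dmSize >= 1)
    if (threshold >= spec$expectedR)
        warning("threshold is not below the expected within-block ",
                "correlation; perfect recovery is not guaranteed")
    eligiblePerBlock <- spec$blockSize - 1 >= redundancy
    nEligible <- if (eligiblePerBlock) spec$nBlocks * spec$blockSize else 0L
    if (!eligiblePerBlock)
        return(list(nEligible = 0L, nPredictable = 0L, nDMUsable = 0L))
    # distribute picks round-robin, at most `redundancy` per block
    picks <- integer(spec$nBlocks)
    left <- min(dmSize, redundancy * spec$nBlocks)
    while (left > 0) {
        take <- min(spec$nBlocks, left)
        picks[seq_len(take)] <- picks[seq_len(take)] + 1L
        left <- left - take
    }
    resolved <- picks >= redundancy
    list(nEligible = as.integer(nEligible),
         nPredictable = as.integer(sum(resolved) *
                                       (spec$blockSize - redundancy)),
         nDMUsable = as.integer(sum(picks)))
}
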