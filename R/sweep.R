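#' Parameter sweep over threshold, redundancy, and DM set size
#'
#' Runs selection for every combination of `|r_P|` threshold, redundancy,
#' and DM set size, and tabulates how many genes become predictable and
#' how many eligible genes are missed (neither measured nor predictable).
#' The default grids — thresholds 0.60/0.65/0.70, redundancy 1–3, and 16
#' DM sizes from 10 to 400 — give the familiar 144-run sweep.
#'
#' Greedy selection is nested: for a fixed threshold and redundancy the DM
#' list at size k is a prefix of the list at any larger size, so the sweep
#' performs one long run per (threshold, redundancy) pair and reads the
#' smaller sizes off its iteration log.
#'
#' @param corr gene-by-gene Pearson correlation matrix
#'   (from [geneCorrelation()]).
#' @param thresholds numeric vector of `|r_P|` cutoffs.
#' @param redundancies integer vector of fold-redundancy values.
#' @param dmSizes integer vector of DM set sizes.
#' @param candidates optional candidate gene vector seeded into every run.
#' @return data.frame with one row per combination: `threshold`,
#'   `redundancy`, `dmSize`, `nDM` (greedy genes actually selected; can
#'   fall short of `dmSize` on early exhaustion), `nPredictable`,
#'   `nEligible`, and `nMissed = nEligible - nEligibleDM - nPredictable`.
#' @export
parameterSweep <- function(corr,
                           thresholds = c(0.60, 0.65, 0.70),
                           redundancies = 1:3,
                           dmSizes = c(seq(10, 50, by = 5),
                                       seq(100, 400, by = 50)),
                           candidates = NULL) {
    stopifnot(length(thresholds) > 0, length(redundancies) > 0,
              length(dmSizes) > 0)
    dmSizes <- sort(unique(as.integer(dmSizes)))
    rows <- list()
    for (t in thresholds) {
        adj <- binarize(corr, t)
        for (r in redundancies) {
            elig <- eligibleGenes(adj, r)
            adjE <- restrictToEligible(adj, r)
            sel <- suppressWarnings(
                ggsSelect(adjE, dmSize = max(dmSizes), redundancy = r,
                          candidates = candidates))
            log <- iterationLog(sel)
            greedy <- log[log$phase == "greedy", , drop = FALSE]
            candPred <- sum(
                log$nNewPredictable[log$phase == "candidate"])
            candEligDM <- length(intersect(candidateGenes(sel), elig))
            for (k in dmSizes) {
                used <- min(k, nrow(greedy))
                nPred <- if (used == 0) candPred else
                    greedy$cumPredictable[used]
                dmElig <- candEligDM + used
                rows[[length(rows) + 1L]] <- data.frame(
                    threshold = t, redundancy = as.integer(r),
                    dmSize = k, nDM = as.integer(used),
                    nPredictable = as.integer(nPred),
                    nEligible = length(elig),
                    nMissed = as.integer(length(elig) - dmElig - nPred))
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
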