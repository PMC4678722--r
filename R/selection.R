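.radixSort <- function(x) sort(x, method = "radix")  # locale-independent

.emptyLog <- function() data.frame(
    phase = character(), iteration = integer(), gene = character(),
    prunedDegree = integer(), nNewPredictable = integer(),
    cumPredictable = integer(), newlyPredictable = character(),
    stringsAsFactors = FALSE)

.logRow <- function(phase, iteration, gene, degree, newPred, cumPred)
    data.frame(phase = phase, iteration = iteration, gene = gene,
               prunedDegree = degree, nNewPredictable = length(newPred),
               cumPredictable = cumPred,
               newlyPredictable = paste(newPred, collapse = ","),
               stringsAsFactors = FALSE)

#' Greedy gene set selection (GGS)
#'
#' Iteratively builds a set of genes to directly measure (DM set) and the
#' set of genes predictable from it, from a binary co-expression adjacency.
#' Each iteration (i) sorts genes by their degree in a working adjacency
#' from which used edges have been removed, (ii) adds the gene of maximum
#' degree to the DM set, (iii) moves any gene now correlated (in the
#' original adjacency) with at least `redundancy` DM genes into the
#' predictable set, and (iv) removes all edges incident to the new DM and
#' predictable genes from the working adjacency. Edge removal stops one
#' dense neighborhood from monopolizing the DM set.
#'
#' Degree sorting uses the pruned working adjacency, but the
#' predictability test of step (iii) counts DM neighbors in the
#' *original* adjacency (maintained as incremental counters): under
#' literal pruning a gene's edge to a DM gene disappears the moment the DM
#' gene is chosen, and redundancy >= 2 could never be satisfied. Set
#' `prunedPredictability = TRUE` to get the literal-pruning variant for
#' comparison.
#'
#' Candidate genes (e.g. a prognostic signature that must be assayed) are
#' all added to the DM set up front, predictability counters are updated
#' in bulk, and greedy selection proceeds as usual. Candidates absent from
#' the adjacency stay in the DM list (they are still measured) but
#' contribute no edges; a warning lists them. By default `dmSize` counts
#' greedy-selected genes in addition to the candidates; with
#' `candidatesCountTotal = TRUE` it caps the total DM size.
#'
#' Ties in degree are broken toward the lexicographically smallest gene id
#' (byte order), making runs reproducible across platforms. If no gene
#' with positive pruned degree remains before `dmSize` is reached, the run
#' stops early — isolated genes add no predictive value — and the
#' shortfall is recorded in the selection notes.
#'
#' @param adj a [CoexpressionAdjacency-class]; typically restricted to
#'   eligible genes via [restrictToEligible()].
#' @param dmSize number of genes to select greedily (integer >= 1).
#' @param redundancy minimum number of DM genes an unmeasured gene must be
#'   correlated with to count as predictable (integer >= 1).
#' @param candidates optional character vector of genes seeded into the DM
#'   set before greedy selection.
#' @param candidatesCountTotal if `TRUE`, `dmSize` caps the total DM set
#'   size including candidates.
#' @param prunedPredictability if `TRUE`, step (iii) counts DM neighbors
#'   in the pruned working adjacency instead of the original one.
#' @return a [GeneSelection-class].
#' @export
ggsSelect <- function(adj, dmSize, redundancy = 1L, candidates = NULL,
                      candidatesCountTotal = FALSE,
                      prunedPredictability = FALSE) {
    stopifnot(dmSize >= 1, redundancy >= 1)
    dmSize <- as.integer(dmSize)
    redundancy <- as.integer(redundancy)
    A <- edgeMatrix(adj) > 0L          # original adjacency, fixed
    W <- A                             # working adjacency, pruned
    genes <- rownames(A)
    n <- length(genes)
    notes <- character()
    log <- .emptyLog()

    status <- setNames(rep("open", n), genes)  # open | dm | predictable
    dmCount <- setNames(integer(n), genes)     # DM neighbors per open gene

    dmOrder <- character()
    candIn <- character()
    if (!is.null(candidates) && length(candidates)) {
        candidates <- unique(as.character(candidates))
        absent <- setdiff(candidates, genes)
        if (length(absent)) {
            warning("candidate gene(s) absent from the adjacency ",
                    "(kept in the DM set, no predictive edges): ",
                    paste(absent, collapse = ", "))
            notes <- c(notes, paste0("absent candidates: ",
                                     paste(absent, collapse = ",")))
        }
        candIn <- candidates
        present <- intersect(candidates, genes)
        status[present] <- "dm"
        dmOrder <- candidates
        # bulk counter update over all candidate edges, then one
        # predictability pass; the literal-pruning variant recounts from
        # the current working matrix instead of accumulating
        if (prunedPredictability) {
            cnt <- rowSums(W[, present, drop = FALSE])
        } else {
            for (g in present) {
                nb <- A[g, ]
                dmCount[nb] <- dmCount[nb] + 1L
            }
            cnt <- dmCount
        }
        newPred <- names(status)[status == "open" & cnt >= redundancy]
        status[newPred] <- "predictable"
        remove <- c(present, newPred)
        W[remove, ] <- FALSE
        W[, remove] <- FALSE
        for (g in present)
            log <- rbind(log, .logRow("candidate", 0L, g, NA_integer_,
                                      character(), length(newPred)))
        if (length(newPred))
            log <- rbind(log, .logRow("candidate", 0L, NA_character_,
                                      NA_integer_, newPred, length(newPred)))
    }

    nGreedy <- if (candidatesCountTotal)
        max(0L, dmSize - length(dmOrder)) else dmSize
    if (nGreedy > sum(status == "open")) {
        notes <- c(notes, sprintf(
            "requested %d greedy genes but only %d open genes in the graph",
            nGreedy, sum(status == "open")))
        warning(notes[length(notes)])
    }

    cumPred <- sum(status == "predictable")
    it <- 0L
    while (it < nGreedy) {
        deg <- rowSums(W)
        deg[status != "open"] <- -1
        maxDeg <- max(deg)
        if (maxDeg < 1) {  # nothing informative left
            notes <- c(notes, sprintf(
                "early exhaustion after %d of %d greedy iterations: no open gene with pruned degree >= 1",
                it, nGreedy))
            warning(notes[length(notes)])
            break
        }
        pick <- .radixSort(genes[deg == maxDeg])[1]
        it <- it + 1L
        status[pick] <- "dm"
        dmOrder <- c(dmOrder, pick)
        if (prunedPredictability) {
            dmPresent <- intersect(dmOrder, genes)
            cnt <- rowSums(W[, dmPresent, drop = FALSE])
        } else {
            nb <- A[pick, ]
            dmCount[nb] <- dmCount[nb] + 1L
            cnt <- dmCount
        }
        newPred <- names(status)[status == "open" & cnt >= redundancy]
        status[newPred] <- "predictable"
        remove <- c(pick, newPred)
        W[remove, ] <- FALSE
        W[, remove] <- FALSE
        cumPred <- cumPred + length(newPred)
        log <- rbind(log, .logRow("greedy", it, pick, as.integer(maxDeg),
                                  newPred, cumPred))
    }

    predictable <- names(status)[status == "predictable"]
    # redundancy guarantee against the original adjacency, every run
    if (length(predictable)) {
        dmPresent <- intersect(dmOrder, genes)
        cnt <- rowSums(A[predictable, dmPresent, drop = FALSE])
        if (!prunedPredictability && any(cnt < redundancy))
            stop("internal error: predictable gene below redundancy: ",
                 paste(predictable[cnt < redundancy], collapse = ", "))
    }
    res <- new("GeneSelection", method = "ggs", dmGenes = dmOrder,
               predictableGenes = predictable, candidateGenes = candIn,
               threshold = adj@threshold, redundancy = redundancy,
               dmSize = dmSize, iterationLog = log)
    attr(res@iterationLog, "notes") <- notes
    res
}

#' Ranked-degree gene selection (baseline)
#'
#' Control method: the DM set is simply the `dmSize` genes of highest
#' degree in the original adjacency (ties broken lexicographically, as in
#' [ggsSelect()]), with no edge removal. A non-DM gene is predictable when
#' it has at least `redundancy` DM neighbors. High-degree genes tend to be
#' mutually correlated, so this baseline wastes measurements on redundant
#' genes relative to GGS.
#'
#' @inheritParams ggsSelect
#' @return a [GeneSelection-class].
#' @export
rankedDegreeSelect <- function(adj, dmSize, redundancy = 1L) {
    stopifnot(dmSize >= 1, redundancy >= 1)
    dmSize <- as.integer(dmSize)
    redundancy <- as.integer(redundancy)
    A <- edgeMatrix(adj) > 0L
    genes <- rownames(A)
    deg <- rowSums(A)
    ord <- order(-deg, match(genes, .radixSort(genes)))
    dm <- genes[ord][seq_len(min(dmSize, length(genes)))]
    rest <- setdiff(genes, dm)
    cnt <- rowSums(A[rest, dm, drop = FALSE])
    predictable <- rest[cnt >= redundancy]
    log <- .emptyLog()
    for (i in seq_along(dm))
        log <- rbind(log, .logRow("ranked", i, dm[i],
                                  as.integer(deg[dm[i]]), character(), NA))
    new("GeneSelection", method = "ranked", dmGenes = dm,
        predictableGenes = predictable, candidateGenes = character(),
        threshold = adj@threshold, redundancy = redundancy,
        dmSize = dmSize, iterationLog = log)
}

#' Predictor genes for each predictable gene
#'
#' For every predictable gene, returns all DM genes adjacent to it in the
#' original (un-pruned) adjacency — exactly the genes correlated with it
#' beyond the threshold that will serve as regression predictors. By
#' construction each list has at least `redundancy` entries.
#'
#' @param adj the original [CoexpressionAdjacency-class] the selection ran
#'   on (not a pruned copy).
#' @param selection a [GeneSelection-class].
#' @return named list mapping each predictable gene to its character
#'   vector of DM predictor genes.
#' @export
predictorSets <- function(adj, selection) {
    A <- edgeMatrix(adj) > 0L
    dm <- intersect(dmGenes(selection), rownames(A))
    preds <- lapply(predictableGenes(selection), function(p) {
        dm[A[p, dm]]
    })
    names(preds) <- predictableGenes(selection)
    short <- lengths(preds) < selection@redundancy
    if (any(short))
        stop("internal inconsistency: predictable gene(s) with fewer than ",
             selection@redundancy, " DM neighbors: ",
             paste(names(preds)[short], collapse = ", "))
    preds
}
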