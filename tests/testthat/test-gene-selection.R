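starAdj <- function() mkAdj(list(c("A", "B"), c("A", "C"), c("A", "D")),
                            c("A", "B", "C", "D"))
twoTriangles <- function() mkAdj(
    list(c("A", "B"), c("B", "C"), c("A", "C"),
         c("D", "E"), c("E", "F"), c("D", "F")), LETTERS[1:6])
fourCycle <- function() mkAdj(
    list(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D")), LETTERS[1:4])

test_that("a single hub dominates a star", {
    sel <- ggsSelect(starAdj(), dmSize = 1, redundancy = 1)
    expect_identical(dmGenes(sel), "A")
    expect_setequal(predictableGenes(sel), c("B", "C", "D"))
})

test_that("edge removal spreads the DM set across disjoint triangles", {
    sel <- ggsSelect(twoTriangles(), dmSize = 2, redundancy = 1)
    expect_identical(dmGenes(sel), c("A", "D"))
    expect_setequal(predictableGenes(sel), c("B", "C", "E", "F"))
    # the ranked-degree control piles both picks into one triangle
    rk <- rankedDegreeSelect(twoTriangles(), dmSize = 2, redundancy = 1)
    expect_identical(dmGenes(rk), c("A", "B"))
    expect_identical(predictableGenes(rk), "C")
    expect_gte(length(predictableGenes(sel)),
               3 * length(predictableGenes(rk)))
})

test_that("predictability counts DM neighbors in the original adjacency", {
    # B's edge to A is pruned when A enters the DM set; only counting
    # neighbors in the original adjacency lets redundancy 2 be satisfied
    sel <- ggsSelect(fourCycle(), dmSize = 2, redundancy = 2)
    expect_identical(dmGenes(sel), c("A", "C"))
    expect_setequal(predictableGenes(sel), c("B", "D"))
    ps <- predictorSets(fourCycle(), sel)
    expect_identical(ps$B, c("A", "C"))
    expect_identical(ps$D, c("A", "C"))
    # under literal pruning nothing reaches redundancy 2
    selP <- suppressWarnings(
        ggsSelect(fourCycle(), dmSize = 2, redundancy = 2,
                  prunedPredictability = TRUE))
    expect_length(predictableGenes(selP), 0)
})

test_that("ranked-degree baseline picks top original degrees, no pruning", {
    rk <- rankedDegreeSelect(starAdj(), dmSize = 2, redundancy = 1)
    expect_identical(dmGenes(rk), c("A", "B"))
    expect_setequal(predictableGenes(rk), c("C", "D"))
    rkAll <- rankedDegreeSelect(twoTriangles(), dmSize = 6, redundancy = 1)
    expect_length(predictableGenes(rkAll), 0)  # everything measured
})

test_that("star predictor sets map every leaf to the hub", {
    sel <- ggsSelect(starAdj(), dmSize = 1, redundancy = 1)
    ps <- predictorSets(starAdj(), sel)
    expect_identical(unname(ps), list("A", "A", "A"))
})

test_that("candidate genes seed the DM set before greedy selection", {
    # seeding E into one triangle resolves it (D, F predictable through
    # E) and leaves the greedy pick free for the other triangle
    sel <- ggsSelect(twoTriangles(), dmSize = 1, redundancy = 1,
                     candidates = "E")
    expect_identical(dmGenes(sel), c("E", "A"))
    expect_setequal(predictableGenes(sel), c("B", "C", "D", "F"))
    expect_identical(candidateGenes(sel), "E")
    # dmSize counts additional greedy genes by default ...
    expect_identical(sum(iterationLog(sel)$phase == "greedy"), 1L)
    # ... but total-count semantics cap the whole DM set
    selTot <- ggsSelect(twoTriangles(), dmSize = 1, redundancy = 1,
                        candidates = "E", candidatesCountTotal = TRUE)
    expect_identical(dmGenes(selTot), "E")
    # seeding a star leaf makes the hub predictable and starves the
    # greedy loop: the leaf's only neighbor is the hub itself
    expect_warning(
        leaf <- ggsSelect(starAdj(), dmSize = 1, redundancy = 1,
                          candidates = "D"),
        "exhaustion")
    expect_identical(dmGenes(leaf), "D")
    expect_identical(predictableGenes(leaf), "A")
    # absent candidates warn and stay in the DM list without edges
    expect_warning(
        selAbs <- ggsSelect(starAdj(), dmSize = 1, redundancy = 1,
                            candidates = "ZZZ9"),
        "ZZZ9")
    expect_identical(dmGenes(selAbs), c("ZZZ9", "A"))
    expect_setequal(predictableGenes(selAbs), c("B", "C", "D"))
})

test_that("runs are deterministic and stop early when the graph is spent", {
    adj <- randomAdjacency(50, 0.08, 123)
    a <- ggsSelect(adj, dmSize = 10, redundancy = 2)
    b <- ggsSelect(adj, dmSize = 10, redundancy = 2)
    expect_identical(dmGenes(a), dmGenes(b))
    expect_identical(predictableGenes(a), predictableGenes(b))
    # exhaustion: demand more genes than informative picks exist
    expect_warning(big <- ggsSelect(twoTriangles(), dmSize = 5,
                                    redundancy = 1),
                   "exhaustion")
    expect_identical(dmGenes(big), c("A", "D"))
    expect_true(any(grepl("exhaustion",
                          attr(iterationLog(big), "notes"))))
})

test_that("greedy runs nest: smaller DM lists are prefixes of larger ones", {
    for (seed in 1:8) {
        adj <- randomAdjacency(60, 0.07, seed)
        long <- suppressWarnings(ggsSelect(adj, dmSize = 25,
                                           redundancy = 2))
        for (k in c(3, 10, 18)) {
            short <- suppressWarnings(ggsSelect(adj, dmSize = k,
                                                redundancy = 2))
            nShort <- length(dmGenes(short))
            expect_identical(dmGenes(short),
                             dmGenes(long)[seq_len(nShort)])
            expect_lte(length(predictableGenes(short)),
                       length(predictableGenes(long)))
        }
    }
})

test_that("every predictable gene keeps its redundancy guarantee", {
    for (seed in 1:10) {
        adj <- randomAdjacency(80, 0.05, seed)
        for (r in 1:3) {
            sel <- suppressWarnings(ggsSelect(adj, dmSize = 15,
                                              redundancy = r))
            ps <- predictorSets(adj, sel)
            if (length(ps))
                expect_true(all(lengths(ps) >= r))
            A <- edgeMatrix(adj)
            for (p in predictableGenes(sel))
                expect_gte(sum(A[p, dmGenes(sel)]), r)
        }
    }
})

test_that("greedy selection matches the naive re-scanning reference", {
    cases <- expand.grid(seed = 1:6, p = c(0.03, 0.1), r = 1:2)
    for (i in seq_len(nrow(cases))) {
        adj <- randomAdjacency(70, cases$p[i], cases$seed[i])
        sel <- suppressWarnings(ggsSelect(adj, dmSize = 12,
                                          redundancy = cases$r[i]))
        ref <- naiveGGS(adj, dmSize = 12, redundancy = cases$r[i])
        expect_identical(dmGenes(sel), ref$dm)
        expect_identical(sort(predictableGenes(sel)), ref$predictable)
    }
})

test_that("iteration count equals the DM size short of exhaustion", {
    adj <- randomAdjacency(100, 0.06, 5)
    sel <- ggsSelect(adj, dmSize = 10, redundancy = 1)
    log <- iterationLog(sel)
    expect_identical(sum(log$phase == "greedy"), 10L)
    expect_identical(log$iteration[log$phase == "greedy"], 1:10)
})

test_that("parameter sweep covers the grid and matches direct runs", {
    withr::local_seed(2)
    spec <- syntheticSpec(nBlocks = 4, blockSize = 8, nSamples = 120,
                          nBackground = 20, seed = 77)
    sim <- generateBlockExpression(spec)
    corr <- geneCorrelation(quantileFilter(sim$se))
    tab <- parameterSweep(corr)  # default 3 x 3 x 16 grid
    expect_identical(nrow(tab), 144L)
    expect_identical(anyDuplicated(tab[, c("threshold", "redundancy",
                                           "dmSize")]), 0L)
    # a sweep row reproduces a direct ggsSelect call
    one <- parameterSweep(corr, thresholds = 0.6, redundancies = 2,
                          dmSizes = 8)
    adjE <- restrictToEligible(binarize(corr, 0.6), 2)
    direct <- suppressWarnings(ggsSelect(adjE, dmSize = 8, redundancy = 2))
    expect_identical(one$nPredictable,
                     length(predictableGenes(direct)))
    expect_identical(one$nEligible,
                     length(eligibleGenes(binarize(corr, 0.6), 2)))
    expect_identical(one$nMissed,
                     one$nEligible - one$nDM - one$nPredictable)
    # predictable counts are non-decreasing in dmSize within a stratum
    for (s in split(tab, list(tab$threshold, tab$redundancy)))
        expect_false(is.unsorted(s$nPredictable[order(s$dmSize)]))
})

test_that("sweep with a planted block structure hits the closed form", {
    spec <- syntheticSpec()  # 5 blocks of 10, expected r = 0.8
    sim <- generateBlockExpression(spec)
    corr <- geneCorrelation(quantileFilter(sim$se))
    tab <- parameterSweep(corr, thresholds = 0.6, redundancies = c(1, 3),
                          dmSizes = c(5, 15))
    exp1 <- plantedExpectations(spec, 0.6, 1, 5)
    exp3 <- plantedExpectations(spec, 0.6, 3, 15)
    got <- function(r, k) tab$nPredictable[tab$redundancy == r &
                                               tab$dmSize == k]
    expect_identical(got(1, 5), exp1$nPredictable)
    expect_identical(got(3, 15), exp3$nPredictable)
})
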