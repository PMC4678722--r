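# Independent reference implementations used as test oracles. These are
# deliberately naive (full re-scans, explicit loops) and share no code
# with the package internals.

# adjacency from an edge list
mkAdj <- function(edges, genes) {
    e <- matrix(0L, length(genes), length(genes),
                dimnames = list(genes, genes))
    for (p in edges) {
        e[p[1], p[2]] <- 1L
        e[p[2], p[1]] <- 1L
    }
    coexpressionAdjacency(e)
}

# seeded Erdos-Renyi adjacency
randomAdjacency <- function(n, p, seed) {
    genes <- sprintf("g%03d", seq_len(n))
    e <- matrix(0L, n, n, dimnames = list(genes, genes))
    withr::with_seed(seed, {
        up <- which(upper.tri(e))
        e[up] <- as.integer(stats::runif(length(up)) < p)
    })
    e[lower.tri(e)] <- t(e)[lower.tri(e)]
    coexpressionAdjacency(e)
}

# naive greedy selection: re-sorts the full pruned matrix every iteration
# and re-counts DM neighbors in the original adjacency from scratch
naiveGGS <- function(adj, dmSize, redundancy) {
    A <- edgeMatrix(adj)
    W <- A
    genes <- rownames(A)
    dm <- character()
    predictable <- character()
    iters <- 0L
    while (iters < dmSize) {
        open <- setdiff(genes, c(dm, predictable))
        if (!length(open)) break
        deg <- vapply(open, function(g) sum(W[g, ]), numeric(1))
        if (max(deg) < 1) break
        pick <- sort(open[deg == max(deg)], method = "radix")[1]
        dm <- c(dm, pick)
        iters <- iters + 1L
        open <- setdiff(open, pick)
        cnt <- vapply(open, function(g) sum(A[g, dm]), numeric(1))
        newPred <- open[cnt >= redundancy]
        predictable <- c(predictable, newPred)
        for (g in c(pick, newPred)) {
            W[g, ] <- 0L
            W[, g] <- 0L
        }
    }
    list(dm = dm, predictable = sort(predictable))
}

# breadth-first-search connected component sizes (non-isolated vertices)
bfsComponents <- function(adj) {
    e <- edgeMatrix(adj)
    n <- nrow(e)
    seen <- rep(FALSE, n)
    sizes <- integer()
    for (s in seq_len(n)) {
        if (seen[s] || sum(e[s, ]) == 0) next
        queue <- s
        seen[s] <- TRUE
        size <- 0L
        while (length(queue)) {
            v <- queue[1]
            queue <- queue[-1]
            size <- size + 1L
            nb <- which(e[v, ] == 1L & !seen)
            seen[nb] <- TRUE
            queue <- c(queue, nb)
        }
        sizes <- c(sizes, size)
    }
    sort(sizes, decreasing = TRUE)
}

# textbook two-vector Pearson correlation
pearsonManual <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman via average ranks then the textbook Pearson formula
spearmanManual <- function(x, y) {
    pearsonManual(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
}

# small expression container
smallExpr <- function(values, genes = rownames(values),
                      samples = colnames(values)) {
    expressionMatrix(values, genes, samples)
}

exprValues <- function(se) SummarizedExperiment::assay(se, "exprs")
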