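test_that("TSV round-trip preserves values and identifier order", {
    m <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 3, byrow = TRUE,
                dimnames = list(c("TP53", "BRCA1", "EGFR"), c("s1", "s2")))
    se <- smallExpr(m)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpression(se, path)
    back <- readExpression(path)
    expect_identical(dim(back), c(3L, 2L))
    expect_identical(rownames(back), c("TP53", "BRCA1", "EGFR"))
    expect_identical(colnames(back), c("s1", "s2"))
    expect_equal(exprValues(back), m)
})

test_that("ingestion rejects duplicate gene ids, naming the offender", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2", "TP53\t1\t2", "TP53\t3\t4"), path)
    expect_error(readExpression(path), "TP53")
})

test_that("ingestion reports coordinates of bad cells", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2", "TP53\t1\t2", "EGFR\tabc\t4"), path)
    expect_error(readExpression(path), "EGFR.*s1")
    writeLines(c("gene\ts1\ts2", "TP53\t1\t2", "EGFR\t\t4"), path)
    expect_error(readExpression(path), "missing value.*EGFR")
})

test_that("GCT 1.2 and TSV dialects of one matrix read back identically", {
    withr::local_seed(7)
    m <- matrix(round(stats::rnorm(12, 8), 4), nrow = 4,
                dimnames = list(sprintf("G%d", 1:4), sprintf("s%d", 1:3)))
    se <- smallExpr(m)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    gct <- withr::local_tempfile(fileext = ".gct")
    writeExpression(se, tsv, "tsv")
    writeExpression(se, gct, "gct")
    expect_equal(exprValues(readExpression(gct, "gct")),
                 exprValues(readExpression(tsv, "tsv")))
    # mismatching dimension line is rejected
    lines <- readLines(gct)
    lines[2] <- "9\t9"
    writeLines(lines, gct)
    expect_error(readExpression(gct, "gct"), "dimension")
})

test_that("quantile filter keeps genes by their 90th-percentile expression", {
    m <- rbind(high = rep(6, 10), low = rep(1, 10), ramp = 1:10)
    colnames(m) <- sprintf("s%d", 1:10)
    se <- smallExpr(m)
    f <- quantileFilter(se, 0.90, 5)
    # type-7 quantile of 1..10 at 0.9 by hand: x[9] + 0.1*(x[10]-x[9]) = 9.1
    expect_identical(sort(rownames(f)), c("high", "ramp"))
    rep <- S4Vectors::metadata(f)$filterReport
    expect_equal(rep$exprQuantile[rep$gene == "ramp"], 9.1)
    expect_false(rep$retained[rep$gene == "low"])
    # idempotence: filtering a filtered matrix changes nothing
    f2 <- quantileFilter(f, 0.90, 5)
    expect_equal(exprValues(f2), exprValues(f))
    # everything removed -> actionable error
    expect_error(quantileFilter(se, 0.90, 100), "too strict")
})

test_that("min-max scaling maps each gene onto [0,1] preserving order", {
    m <- rbind(a = c(2, 4, 6), b = c(0, 0.25, 1))
    colnames(m) <- sprintf("s%d", 1:3)
    sc <- exprValues(minmaxScale(smallExpr(m)))
    expect_equal(sc["a", ], c(s1 = 0, s2 = 0.5, s3 = 1))
    expect_equal(sc["b", ], m["b", ])  # already spanning [0,1]
    withr::local_seed(11)
    for (i in 1:20) {
        x <- stats::rnorm(15)
        sc1 <- exprValues(minmaxScale(smallExpr(
            matrix(x, 1, dimnames = list("g", sprintf("s%d", 1:15))))))[1, ]
        expect_equal(min(sc1), 0)
        expect_equal(max(sc1), 1)
        expect_identical(order(sc1), order(x))
    }
    expect_error(minmaxScale(smallExpr(
        matrix(3, 1, 4, dimnames = list("flat", sprintf("s%d", 1:4))))),
        "flat")
})

test_that("log transform honors base and pseudocount and keeps monotonicity", {
    m <- rbind(zero = c(0, 0, 0), pow = c(0, 9, 99))
    colnames(m) <- sprintf("s%d", 1:3)
    lt <- exprValues(logTransform(smallExpr(m), base = 10, pseudocount = 1))
    expect_equal(unname(lt["zero", ]), c(0, 0, 0))
    expect_equal(unname(lt["pow", ]), c(0, 1, 2))
    withr::local_seed(3)
    x <- sort(stats::runif(10, 0, 100))
    lx <- exprValues(logTransform(smallExpr(
        matrix(x, 1, dimnames = list("g", sprintf("s%d", 1:10))))))[1, ]
    expect_false(is.unsorted(lx))
    expect_error(logTransform(smallExpr(
        matrix(-1, 1, 3, dimnames = list("g", sprintf("s%d", 1:3))))),
        "non-negative")
})

test_that("train/test split gives the documented sizes and a true partition", {
    mk <- function(n) smallExpr(matrix(stats::rnorm(2 * n), 2,
        dimnames = list(c("g1", "g2"), sprintf("s%04d", seq_len(n)))))
    withr::local_seed(1)
    big <- mk(549)
    parts <- trainTestSplit(big, 2 / 3, seed = 5)
    expect_identical(ncol(parts$train), 366L)
    expect_identical(ncol(parts$test), 183L)
    tiny <- mk(3)
    p3 <- trainTestSplit(tiny, 2 / 3, seed = 5)
    expect_identical(ncol(p3$train), 2L)
    expect_identical(ncol(p3$test), 1L)
    for (seed in 1:5) {
        p <- trainTestSplit(big, 2 / 3, seed = seed)
        expect_length(intersect(colnames(p$train), colnames(p$test)), 0)
        expect_setequal(c(colnames(p$train), colnames(p$test)),
                        colnames(big))
    }
    # deterministic given the seed; typically different across seeds
    pa <- trainTestSplit(big, 2 / 3, seed = 99)
    pb <- trainTestSplit(big, 2 / 3, seed = 99)
    expect_identical(colnames(pa$train), colnames(pb$train))
    pc <- trainTestSplit(big, 2 / 3, seed = 100)
    expect_false(identical(colnames(pa$train), colnames(pc$train)))
})

test_that("the expression container enforces its invariants", {
    m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s", "s")))
    expect_error(expressionMatrix(m), "duplicate sample")
    m2 <- matrix(c(1, NA, 3, 4), 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_error(expressionMatrix(m2), "missing value")
})
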