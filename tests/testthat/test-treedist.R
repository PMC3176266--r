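test_that("default cost model follows the weighted Shapiro rules", {
    co <- defaultCosts()
    expect_equal(co@relabel("S", 3L, "S", 5L), 2)
    expect_equal(co@relabel("H", 3L, "B", 3L), 6)
    expect_equal(co@relabel("H", 3L, "H", 3L), 0)
    expect_equal(co@indel("M", 0L), 0)
    expect_equal(co@indel("H", NA_integer_), 1)  # unweighted node
})

test_that("tree edit distance handles the elementary cases", {
    expect_equal(treeEditDistance("((H3)S3)R", "((H3)S3)R"), 0)
    expect_equal(treeEditDistance("((H3)S3)R", "((H4)S3)R"), 1)
    ## against a bare root every node must be deleted
    expect_equal(treeEditDistance("((H3)S3)R", "R"), 6)
    expect_equal(treeEditDistance("((((H3)S2)B1)S2)R", "R"), 8)
})

test_that("growing a hairpin weight by k moves the distance by exactly k", {
    base <- toShapiro("(((...)))")
    for (k in 1:5) {
        grown <- toShapiro(paste0("(((", strrep(".", 3 + k), ")))"))
        expect_equal(treeEditDistance(base, grown), k)
    }
})

test_that("keyroot DP equals the naive forest-distance oracle", {
    set.seed(23)
    for (i in 1:60) {
        a <- random_tree(sample.int(5L, 1), weighted = runif(1) < 0.7)
        b <- random_tree(sample.int(5L, 1), weighted = runif(1) < 0.7)
        expect_equal(treeEditDistance(a, b), oracle_tree_dist(a, b),
                     info = paste(shapiroToString(a), shapiroToString(b)))
    }
})

test_that("tree edit distance is symmetric and triangular", {
    set.seed(31)
    for (i in 1:40) {
        ts <- lapply(1:3, function(k) random_tree(sample.int(11L, 1)))
        d12 <- treeEditDistance(ts[[1]], ts[[2]])
        d13 <- treeEditDistance(ts[[1]], ts[[3]])
        d23 <- treeEditDistance(ts[[2]], ts[[3]])
        expect_identical(d12, treeEditDistance(ts[[2]], ts[[1]]))
        expect_gte(d12, 0)
        expect_lte(d13, d12 + d23)
        expect_equal(treeEditDistance(ts[[1]], ts[[1]]), 0)
    }
})

test_that("distances accept dot-bracket input directly", {
    expect_equal(treeEditDistance("(((...)))", "(((....)))"), 1)
})
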