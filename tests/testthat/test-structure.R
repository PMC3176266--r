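test_that("dot-bracket parsing produces the forced pair sets", {
    pt <- parseDotBracket("((...))")
    expect_s4_class(pt, "PairTable")
    expect_equal(bpLength(pt), 7L)
    expect_equal(basePairs(pt), cbind(i = c(0L, 1L), j = c(6L, 5L)))

    open <- parseDotBracket(".......")
    expect_equal(nrow(basePairs(open)), 0L)
    expect_equal(bpLength(open), 7L)
})

test_that("parse errors name the first offending position", {
    expect_error(parseDotBracket("(()"), "position 1")
    expect_error(parseDotBracket("())."), "position 3")
    expect_error(parseDotBracket("(.x..)"), "position 3")
    ## a pair closing fewer than 3 unpaired bases is a validation error
    expect_error(parseDotBracket("(..)"), "hairpin")
})

test_that("parse and render are mutually inverse", {
    expect_equal(renderDotBracket(parseDotBracket("((...))")), "((...))")
    expect_equal(renderDotBracket(new("PairTable", len = 3L,
                                      pairs = matrix(integer(0), ncol = 2))),
                 "...")
    expect_equal(renderDotBracket(new("PairTable", len = 5L,
                                      pairs = cbind(0L, 4L))), "(...)")
    set.seed(101)
    for (i in 1:20) {
        cls <- sample(c("hairpin", "bulged", "multiloop"), 1)
        pt <- genStructure(sample(20:70, 1), cls)
        expect_identical(parseDotBracket(renderDotBracket(pt)), pt)
    }
})

test_that("PairTable validity rejects malformed pair sets", {
    expect_error(new("PairTable", len = 10L, pairs = cbind(0L, 10L)),
                 "out of range")
    expect_error(new("PairTable", len = 12L, pairs = cbind(c(0L, 2L), c(6L, 8L))),
                 "pseudoknot")
    expect_error(new("PairTable", len = 12L, pairs = cbind(c(0L, 0L), c(6L, 8L))),
                 "more than one pair")
    expect_error(new("PairTable", len = 12L, pairs = cbind(0L, 3L)),
                 "hairpin")
})

test_that("base-pair distance counts the symmetric difference", {
    expect_equal(bpDistance("((...))", "((...))"), 0L)
    expect_equal(bpDistance("((...))", "(.....)"), 1L)
    expect_equal(bpDistance("((...))", "......."), 2L)
    expect_error(bpDistance("((...))", "...."), "length mismatch")
})

test_that("base-pair distance is a metric on equal-length structures", {
    set.seed(7)
    for (i in 1:60) {
        L <- 30L
        ss <- lapply(1:3, function(k)
            genStructure(L, sample(c("hairpin", "bulged", "multiloop"), 1)))
        d12 <- bpDistance(ss[[1]], ss[[2]])
        d21 <- bpDistance(ss[[2]], ss[[1]])
        d13 <- bpDistance(ss[[1]], ss[[3]])
        d23 <- bpDistance(ss[[2]], ss[[3]])
        expect_identical(d12, d21)
        expect_gte(d12, 0L)
        expect_lte(d13, d12 + d23)
        expect_equal(bpDistance(ss[[1]], ss[[1]]), 0L)
    }
})

test_that("sequence/structure compatibility follows the canonical pair set", {
    expect_true(isCompatible("GGGAAACCC", "(((...)))"))
    expect_false(isCompatible("AAAAAAAAA", "(((...)))"))
    expect_true(isCompatible("GAGAAAUUC", "(((...)))"))  # GC, AU, GU
    expect_error(isCompatible("GGGA", "(((...)))"), "length mismatch")
})

test_that("T in input sequences is converted to U with a warning", {
    expect_warning(f <- foldSequence("GGGGAAAATCCC"), "converted")
    expect_identical(dotBracket(f), dotBracket(foldSequence("GGGGAAAAUCCC")))
    expect_error(suppressWarnings(foldSequence("GGGGXAAACCCC")), "invalid residue")
})
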