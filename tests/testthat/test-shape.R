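test_that("coarse-grained decomposition matches the construction rules", {
    expect_equal(shapiroToString(toShapiro("(((...)))")), "((H3)S3)R")
    expect_equal(shapiroToString(toShapiro("((.((...))))")),
                 "((((H3)S2)B1)S2)R")
    expect_equal(shapiroToString(toShapiro("...")), "(E3)R")
    expect_equal(shapiroToString(toShapiro("(((...)))", weighted = FALSE)),
                 "((H)S)R")
})

## expected strings computed with ViennaRNA 2.7.2 b2shapiro (weighted
## Shapiro tree output, outermost parenthesis wrap stripped)
test_that("shapiro strings agree with the ViennaRNA b2shapiro dialect", {
    vienna <- c(
        "(((...)))" = "(((H3)S3)R)",
        "((.((...))))" = "(((((H3)S2)B1)S2)R)",
        "..." = "((E3)R)",
        ".((...))((....)).." = "((((H3)S2)((H4)S2)E3)R)",
        "((..((...))..))" = "(((((H3)S2)I4)S2)R)",
        "((((...))((...))))" = "(((((H3)S2)((H3)S2)M0)S2)R)",
        "..((...))" = "((((H3)S2)E2)R)",
        "((...)).." = "((((H3)S2)E2)R)",
        "(((..(((...)))...)))" = "(((((H3)S3)I5)S3)R)",
        "((..((...))((...))..))" = "(((((H3)S2)((H3)S2)M4)S2)R)",
        "(...)" = "(((H3)S1)R)",
        "((((....)))).((...))" = "((((H4)S4)((H3)S2)E1)R)",
        "..((.((...))((....))..((...)).))..." =
            "((((((H3)S2)((H4)S2)((H3)S2)M4)S2)E5)R)")
    for (db in names(vienna)) {
        stripped <- sub("\\)$", "", sub("^\\(", "", vienna[[db]]))
        expect_equal(shapiroToString(toShapiro(db)), stripped, info = db)
    }
})

test_that("structures differing only in motif sizes share the unweighted shape", {
    ## helix-bulge-helix-hairpin at different helix/loop sizes
    expect_equal(shapiroToString(toShapiro("((.((...))))", weighted = FALSE)),
                 shapiroToString(toShapiro("(((.(((....))))))", weighted = FALSE)))
    ## helix-interior-helix-hairpin
    expect_equal(shapiroToString(toShapiro("((..((...))..))", weighted = FALSE)),
                 shapiroToString(toShapiro("(((....((((......))))..)))",
                                           weighted = FALSE)))
})

test_that("weights account for every position exactly once", {
    acc <- function(db) RNAShapeDesign:::.tree_positions(toShapiro(db)@root)
    set.seed(11)
    for (i in 1:25) {
        pt <- genStructure(sample(20:70, 1),
                           sample(c("hairpin", "bulged", "multiloop"), 1))
        expect_equal(acc(renderDotBracket(pt)), bpLength(pt))
    }
    expect_equal(acc("..((.((...))((....))..((...)).))..."), 35L)
})

test_that("shapiro strings round-trip through the parser", {
    cases <- c("((H3)S3)R", "((((H3)S2)B1)S2)R", "(E3)R", "R",
               "(((H3)S2)((H4)S2)E3)R", "((((H3)S2)((H3)S2)M0)S2)R")
    for (s in cases)
        expect_equal(shapiroToString(parseShapiro(s)), s, info = s)
    set.seed(5)
    for (i in 1:20) {
        pt <- genStructure(sample(20:60, 1),
                           sample(c("hairpin", "bulged", "multiloop"), 1))
        s <- shapiroToString(toShapiro(pt))
        expect_equal(shapiroToString(parseShapiro(s)), s)
    }
})

test_that("unweighted parses default weights to one in the cost model", {
    t <- parseShapiro("((H)S)R")
    co <- defaultCosts()
    expect_equal(co@indel("H", t@root$children[[1]]$children[[1]]$weight), 1)
})

test_that("malformed shapiro strings fail with a position", {
    expect_error(parseShapiro("((H3S3)R"), "position")
    expect_error(parseShapiro("((H3)S3)Q"), "position")
    expect_error(parseShapiro("((H3)S3)RR"), "position")
})
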