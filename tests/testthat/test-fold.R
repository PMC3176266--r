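test_that("toy backend folds the canonical hairpin to its stacking optimum", {
    f <- foldSequence("GGGGAAAACCCC")
    expect_equal(dotBracket(f), "((((....))))")
    ## three GC/GC stacks, each -(3+3)
    expect_equal(freeEnergy(f), -18)
    expect_equal(freeEnergy(f), oracle_fold_min("GGGGAAAACCCC"))
})

test_that("sequences without stackable helices fold open at zero energy", {
    f <- foldSequence("AAAAAA")
    expect_equal(dotBracket(f), "......")
    expect_equal(freeEnergy(f), 0)
})

test_that("toy backend is optimal against exhaustive enumeration", {
    set.seed(13)
    for (i in 1:40) {
        s <- random_seq(sample(7:14, 1))
        f <- foldSequence(s)
        expect_equal(freeEnergy(f), oracle_fold_min(s), info = s)
        ## the returned structure's own toy energy equals the reported dG
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        expect_equal(oracle_energy(chars, basePairs(foldedStructure(f))),
                     freeEnergy(f), info = s)
    }
})

test_that("toy backend never returns isolated pairs", {
    set.seed(17)
    for (i in 1:30) {
        s <- random_seq(sample(10:40, 1))
        p <- basePairs(foldedStructure(foldSequence(s)))
        if (nrow(p) == 0L) next
        key <- paste(p[, 1], p[, 2])
        stacked <- vapply(seq_len(nrow(p)), function(r) {
            paste(p[r, 1] + 1L, p[r, 2] - 1L) %in% key ||
                paste(p[r, 1] - 1L, p[r, 2] + 1L) %in% key
        }, logical(1))
        expect_true(all(stacked), info = s)
    }
})

test_that("folding is deterministic and the cache transparent", {
    s <- "GCGCAAUACGCGAUUAGC"
    f1 <- foldSequence(s)
    f2 <- foldSequence(s)
    cache <- newFoldCache()
    f3 <- foldSequence(s, cache = cache)
    f4 <- foldSequence(s, cache = cache)
    expect_identical(dotBracket(f1), dotBracket(f2))
    expect_identical(dotBracket(f1), dotBracket(f3))
    expect_identical(freeEnergy(f3), freeEnergy(f4))
})

test_that("backend descriptors are stable strings", {
    expect_match(backendInfo("toy"), "toy-nussinov")
    expect_match(backendInfo("toy"), "min-hairpin=3")
})

test_that("the vienna adapter parses RNAfold output", {
    f <- foldSequence("GGGGAAAACCCC", backend = "vienna")
    expect_equal(dotBracket(f), "((((....))))")
    expect_equal(freeEnergy(f), -5.4, tolerance = 1e-6)
    expect_match(backendInfo("vienna"), "RNAfold")
})
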