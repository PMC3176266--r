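test_that("a sequence no single mutation can fold keeps neutrality one", {
    nv <- neutrality("AAAAAAAA")
    expect_equal(neutralityScore(nv), 1)
    expect_equal(mutantsEvaluated(nv), 24L)
})

test_that("neutrality lies in [0, 1] and counts 3L mutants", {
    set.seed(19)
    for (i in 1:10) {
        L <- sample(8:20, 1)
        nv <- neutrality(random_seq(L))
        expect_gte(neutralityScore(nv), 0)
        expect_lte(neutralityScore(nv), 1)
        expect_equal(mutantsEvaluated(nv), 3L * L)
    }
})

test_that("neutrality matches the exhaustive-enumeration oracle", {
    set.seed(29)
    checked <- 0L
    while (checked < 8L) {
        s <- random_seq(sample(8:12, 1))
        o <- oracle_neutrality(s)
        if (!o$unique_wt) next  # comparison only well defined for unique mfe
        checked <- checked + 1L
        v <- neutralityScore(neutrality(s))
        expect_gte(v, o$lo - 1e-9)
        expect_lte(v, o$hi + 1e-9)
        if (o$lo == o$hi) expect_equal(v, o$lo, info = s)
    }
    ## the worked example: all 36 mutants of the canonical hairpin
    o <- oracle_neutrality("GGGGAAAACCCC")
    v <- neutralityScore(neutrality("GGGGAAAACCCC"))
    expect_gte(v, o$lo - 1e-9)
    expect_lte(v, o$hi + 1e-9)
})

test_that("neutrality is invariant under mutant enumeration order", {
    s <- "GGGGAAAACCCC"
    o1 <- oracle_neutrality(s)
    set.seed(3)
    o2 <- oracle_neutrality(s, mutant_order = sample(36))
    expect_equal(o1$lo, o2$lo)
    expect_equal(o1$hi, o2$hi)
})
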