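test_that("reciprocal overlap handles identity, partial overlap and disjoint cases", {
    a <- gri("1", 1001, 2000)
    expect_equal(unname(reciprocalOverlap(a, a)[1, ]), c(1, 1))
    ## half-overlapping equal-length intervals
    b <- gri("1", 1501, 2500)
    expect_equal(unname(reciprocalOverlap(a, b)[1, ]), c(0.5, 0.5))
    ## different chromosome
    expect_equal(unname(reciprocalOverlap(gri("1", 1, 100),
                                          gri("2", 1, 100))[1, ]), c(0, 0))
    ## disjoint on same chromosome
    expect_equal(unname(reciprocalOverlap(gri("1", 1, 100),
                                          gri("1", 200, 300))[1, ]), c(0, 0))
})

test_that("reciprocal overlap is symmetric up to exchanging the pair", {
    set.seed(42)
    for (i in 1:50) {
        s1 <- sample(1e5, 1); s2 <- sample(1e5, 1)
        a <- gri("5", s1, s1 + sample(5e4, 1))
        b <- gri("5", s2, s2 + sample(5e4, 1))
        ab <- reciprocalOverlap(a, b)[1, ]
        ba <- reciprocalOverlap(b, a)[1, ]
        expect_equal(unname(ab), unname(rev(ba)))
        expect_true(all(ab >= 0 & ab <= 1))
    }
})

test_that("union coverage matches a per-base oracle and never double-counts", {
    tgt <- gri("1", 1, 100000)
    cov <- gri(c("1", "1"), c(1, 50001), c(30000, 90000))
    expect_equal(coverageFraction(tgt, cov), 0.7)
    expect_equal(coverageFraction(tgt, GRanges()), 0)
    expect_equal(coverageFraction(tgt, gri("1", 1, 2e6)), 1)
    ## property: permutation- and self-overlap-invariant, equals brute force
    set.seed(7)
    for (i in 1:25) {
        tgt <- gri("3", 1, 500)
        n <- sample(5, 1)
        st <- sample(600, n, replace = TRUE)
        cov <- gri("3", st, st + sample(200, n, replace = TRUE))
        frac <- coverageFraction(tgt, cov)
        expect_equal(frac, coverageOracle(tgt, cov))
        expect_equal(frac, coverageFraction(tgt, rev(cov)))
        expect_equal(frac, coverageFraction(tgt, c(cov, cov[1])))
    }
})

test_that("CNV identity requires matching dosage and 50% reciprocal overlap", {
    cfg <- filterConfig()
    del <- mkCall("1", 1e6 + 1, 2e6, "deletion")
    expect_true(isSameCnv(del, del, cfg))
    ## boundary: exactly 50/50 counts as identical (closed rule)
    half <- mkCall("1", 1.5e6 + 1, 2.5e6, "deletion")
    ro <- reciprocalOverlap(del, half)[1, ]
    expect_equal(unname(ro), c(0.5, 0.5))
    expect_true(isSameCnv(del, half, cfg))
    ## nested small call: min fraction 0.01
    nested <- mkCall("1", 1e6 + 1, 1e6 + 10000, "deletion")
    big <- mkCall("1", 1e6 + 1, 1e6 + 1000000, "deletion")
    expect_false(isSameCnv(nested, big, cfg))
    ## dosage mismatch blocks identity even at full overlap
    dup <- mkCall("1", 1e6, 2e6, "duplication")
    expect_false(isSameCnv(del, dup, cfg))
    expect_true(isSameCnv(dup, dup, cfg))
})

test_that("filter configuration validates its thresholds", {
    cfg <- filterConfig()
    expect_equal(cfg@minSizeBp, 50000)
    expect_equal(cfg@minMarkers, 20)
    expect_equal(cfg@controlPanelN, 1679)
    expect_error(filterConfig(reciprocalOverlap = 1.2), "fractions")
    expect_error(filterConfig(controlPanelN = 0), "positive")
})

test_that("call validation enforces chromosomes, copy states and sex baselines", {
    expect_error(cnvCalls("S1", "25", 1, 100, "deletion", 1, 1, 10),
                 "chromosome")
    expect_error(cnvCalls("S1", "1", 200, 100, "deletion", 1, 1, 10))
    expect_error(cnvCalls("S1", "1", 1, 100, "deletion", 2, 5, 10), "copy")
    ## autosomal deletion must drop below 2 copies
    expect_error(cnvCalls("S1", "1", 1, 100, "deletion", 2, 2, 10),
                 "baseline")
    ## mosaic loss x1-2 and mosaic gain x3-4 are valid autosomal states
    expect_s4_class(cnvCalls("S1", "18", 1, 1e6, "deletion", 1, 2, 50),
                    "GRanges")
    expect_s4_class(cnvCalls("S1", "9", 1, 1e6, "duplication", 3, 4, 50),
                    "GRanges")
    ## X duplication in a male sits on a 1-copy baseline: 2 copies is a gain
    sexes <- c(S1 = "male", S2 = "female")
    expect_s4_class(cnvCalls("S1", "X", 1, 1e6, "duplication", 2, 2, 50,
                             sexes = sexes), "GRanges")
    ## ...but 2 copies is not a gain for a female
    expect_error(cnvCalls("S2", "X", 1, 1e6, "duplication", 2, 2, 50,
                          sexes = sexes), "baseline")
    ## UPD events need a parent of origin
    expect_error(cnvCalls("S1", "15", 1, 1e6, "UPD"), "parent_of_origin")
})
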