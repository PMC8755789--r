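test_that("single-trio inheritance follows the matching rules", {
    cfg <- filterConfig()
    child <- mkCall("1", 10e6, 11e6, "deletion", subject = "S1")
    match <- mkCall("1", 10e6, 11e6, "deletion", subject = "F1")
    other <- mkCall("1", 40e6, 41e6, "deletion", subject = "F1")
    ## exact match in the father only
    expect_equal(determineInheritance(child, match, other, cfg)$status,
                 "paternal")
    expect_equal(determineInheritance(child, other, match, cfg)$status,
                 "maternal")
    expect_equal(determineInheritance(child, match, match, cfg)$status,
                 "biparental")
    ## both parents genotyped, neither carries it
    expect_equal(determineInheritance(child, other, other, cfg)$status,
                 "de_novo")
    ## empty parental call sets still mean the parent was genotyped
    empty <- match[integer()]
    expect_equal(determineInheritance(child, empty, empty, cfg)$status,
                 "de_novo")
    ## a missing parent blocks the de novo call
    expect_equal(determineInheritance(child, other, NULL, cfg)$status,
                 "unknown")
    expect_equal(determineInheritance(child, NULL, NULL, cfg)$status,
                 "unknown")
    ## ...but a genotyped carrier parent still resolves the variant
    expect_equal(determineInheritance(child, match, NULL, cfg)$status,
                 "paternal")
})

test_that("inheritance is invariant under permutation of parental call order", {
    cfg <- filterConfig()
    child <- mkCall("2", 5e6, 6e6, "duplication", subject = "S1")
    types <- c("deletion", "duplication", "duplication")
    father <- cnvCalls("F1", "2", c(1e6, 5e6, 30e6), c(2e6, 6e6, 31e6),
                       types, c(1, 3, 3), c(1, 3, 3), 50)
    for (perm in list(1:3, 3:1, c(2, 1, 3))) {
        expect_equal(determineInheritance(child, father[perm], NULL,
                                          cfg)$status, "paternal")
    }
})

test_that("cohort-level assignment partitions every stratum", {
    fx <- loadReferenceCohort()
    variants(fx) <- classifyVariants(variants(fx), knowledgeBase(fx))
    fx <- assignInheritance(fx)
    s <- inheritanceSummary(fx)
    tab <- s$variants
    ## partition: statuses sum to the variant total in every group
    expect_equal(sum(tab), length(variants(fx)))
    expect_equal(unname(colSums(tab)), c(32, 97))
    ## per-subject de novo flags never exceed subject counts
    expect_lte(sum(s$subjects$de_novo), nrow(subjects(fx)))
})

test_that("an empty cohort yields an all-zero inheritance table", {
    sub <- data.frame(subject_id = "S1", sex = "male", age_months = 10,
                      group = "ASD")
    co <- nddCohort(sub)
    co <- assignInheritance(co)
    s <- inheritanceSummary(co)
    expect_equal(sum(s$variants), 0)
    expect_false(any(s$subjects$de_novo))
})
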