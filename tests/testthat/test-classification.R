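test_that("syndrome matching needs dosage compatibility and 50% region coverage", {
    kb <- tinyKb()
    cfg <- filterConfig()
    ## full containment of an established region
    v <- mkCall("7", 71.9e6, 73.5e6, "deletion")
    m <- matchSyndrome(v, kb, cfg)
    expect_equal(m$name, "established_region_7q")
    expect_equal(m$covered, 1)
    ## duplication of the same span is dosage-incompatible
    d <- mkCall("7", 71.9e6, 73.5e6, "duplication")
    expect_true(is.na(matchSyndrome(d, kb, cfg)$name))
    ## covering 49% of the region is below the assignment threshold
    partial <- mkCall("7", 72e6, 72e6 + 0.49 * 1.4e6, "deletion")
    expect_true(is.na(matchSyndrome(partial, kb, cfg)$name))
    ## no overlap at all
    far <- mkCall("12", 1e6, 2e6, "deletion")
    expect_true(is.na(matchSyndrome(far, kb, cfg)$name))
})

test_that("ties break by covered fraction, then evidence, then name", {
    cfg <- filterConfig()
    kb <- tinyKb()
    ## deletion covering both 7q entries fully: evidence decides
    both <- mkCall("7", 70e6, 85e6, "deletion")
    expect_equal(matchSyndrome(both, kb, cfg)$name, "established_region_7q")
    ## two identical-evidence entries at equal coverage: lexicographic name
    kb2 <- c(kb[1], kb[1])
    mcols(kb2)$name <- c("zeta", "alpha")
    expect_equal(matchSyndrome(both, kb2, cfg)$name, "alpha")
})

test_that("the five-tier rules are total and reproduce the canonical examples", {
    kb <- loadReferenceCohort() |> knowledgeBase()
    cfg <- filterConfig()
    ## maternal UPD over an imprinted established region is pathogenic
    upd <- cnvCalls("S1", "15", 1e6, 80e6, "UPD",
                    parent_of_origin = "maternal")
    cl <- classifyVariants(upd, kb, cfg)
    expect_equal(mcols(cl)$tier, "pathogenic")
    expect_equal(mcols(cl)$rationale, "imprinted_established_upd")
    ## a paternal UPD of the same span hits the Angelman entry instead
    updP <- cnvCalls("S1", "15", 1e6, 80e6, "UPD",
                     parent_of_origin = "paternal")
    expect_equal(mcols(classifyVariants(updP, kb, cfg))$matched_entry,
                 "Angelman_UPD15")
    ## single-report region match gives likely pathogenic
    kbt <- tinyKb()
    lp <- mkCall("7", 79.9e6, 80.5e6, "deletion")
    expect_equal(mcols(classifyVariants(lp, kbt, cfg))$tier,
                 "likely_pathogenic")
    ## candidate gene without mechanism flag stays VUS
    vus <- mkCall("3", 49.9e6, 50.3e6, "deletion")
    expect_equal(mcols(classifyVariants(vus, kbt, cfg))$tier, "VUS")
    ## ...but the same candidate with a mechanism flag is likely pathogenic
    kbm <- kbt
    mcols(kbm)$mechanism[3] <- TRUE
    expect_equal(mcols(classifyVariants(vus, kbm, cfg))$tier,
                 "likely_pathogenic")
    ## rare call with no knowledge-base content is likely benign
    lb <- mkCall("13", 1e6, 2e6, "duplication")
    expect_equal(mcols(classifyVariants(lb, kbt, cfg))$tier, "likely_benign")
    ## non-rare call in annotate-all mode is benign
    common <- mkCall("13", 1e6, 2e6, "duplication")
    mcols(common)$rare <- FALSE
    expect_equal(mcols(classifyVariants(common, kbt, cfg))$tier, "benign")
})

test_that("every variant gets exactly one tier (totality property)", {
    set.seed(5)
    kb <- tinyKb()
    n <- 60
    chrom <- sample(c("3", "7", "13"), n, replace = TRUE)
    st <- round(stats::runif(n, 4e7, 9e7))
    types <- sample(c("deletion", "duplication"), n, TRUE)
    cp <- ifelse(types == "deletion", 1L, 3L)
    v <- cnvCalls(sprintf("S%02d", seq_len(n)), chrom, st,
                  st + round(stats::runif(n, 1e5, 3e7)), types, cp, cp, 50)
    cl <- classifyVariants(v, kb)
    expect_length(mcols(cl)$tier, n)
    expect_true(all(mcols(cl)$tier %in%
        c("pathogenic", "likely_pathogenic", "VUS", "likely_benign",
          "benign")))
})

test_that("enlarging a variant over an established region cannot lower its tier", {
    kb <- tinyKb()
    cfg <- filterConfig()
    base <- mkCall("7", 71.9e6, 73.5e6, "deletion")
    t0 <- mcols(classifyVariants(base, kb, cfg))$tier
    expect_equal(t0, "pathogenic")
    for (grow in c(1e6, 5e6, 2e7)) {
        big <- mkCall("7", max(1, 71.9e6 - grow), 73.5e6 + grow, "deletion")
        expect_equal(mcols(classifyVariants(big, kb, cfg))$tier, "pathogenic")
    }
})

test_that("subject summaries take the most severe tier and count subjects once", {
    sub <- data.frame(subject_id = c("S1", "S2", "S3", "S4"),
                      sex = c("male", "female", "male", "male"),
                      age_months = c(30, 40, 50, 60),
                      group = c("ASD", "ASD", "ID_DD", "ID_DD"))
    types <- c("deletion", "deletion", "deletion")
    v <- cnvCalls(c("S1", "S1", "S2"), "7",
                  c(72e6, 72e6, 50e6), c(73.4e6, 73.4e6, 51e6),
                  types, 1, 1, 100)
    mcols(v)$tier <- c("pathogenic", "pathogenic", "VUS")
    co <- nddCohort(sub, v,
                    aneuploidies = data.frame(subject_id = "S4",
                                              karyotype_label = "trisomy 21"))
    cls <- classifySubjects(co)
    ## S1: two pathogenic variants -> one diagnosed subject
    expect_true(cls$diagnosed_strict[cls$subject_id == "S1"])
    expect_equal(cls$n_variants[cls$subject_id == "S1"], 2L)
    ## S2: VUS only -> clinically relevant but not strict
    expect_true(cls$clinically_relevant[cls$subject_id == "S2"])
    expect_false(cls$diagnosed_strict[cls$subject_id == "S2"])
    ## S3: no variants
    expect_false(cls$clinically_relevant[cls$subject_id == "S3"])
    ## S4: aneuploidy alone diagnoses
    expect_true(cls$diagnosed_strict[cls$subject_id == "S4"])
})
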