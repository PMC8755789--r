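test_that("exact test matches closed-form enumerations", {
    ## two admissible tables, each probability 1/2
    expect_equal(fisherTwoSided(matrix(c(1, 0, 0, 1), 2)), 1)
    ## extreme diagonal: the two extreme tables each carry 1/choose(10,5)
    expect_equal(fisherTwoSided(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
    expect_error(fisherTwoSided(matrix(c(0, 0, 3, 4), 2)), "margins")
    expect_error(fisherTwoSided(matrix(c(-1, 2, 3, 4), 2)))
})

test_that("age bins are lower-closed at 12, 24 and 60 months", {
    expect_equal(as.character(ageBin(c(0, 11, 12, 23, 24, 59, 60, 120))),
                 c("<1", "<1", "1-2", "1-2", "2-5", "2-5", ">5", ">5"))
})

test_that("size summaries use the n-1 standard deviation and skip singleton sd", {
    sub <- data.frame(subject_id = c("S1", "S2", "S3"),
                      sex = "male", age_months = 30,
                      group = c("ASD", "ASD", "ID_DD"))
    v <- cnvCalls(c("S1", "S2", "S3"), "1", c(1e6, 1e6, 1e6),
                  c(2e6 - 1, 4e6 - 1, 3e6 - 1), "deletion", 1, 1, 100)
    co <- nddCohort(sub, v)
    sz <- sizeSummary(co, strata = "group")
    asd <- sz[sz$stratum == "ASD", ]
    ## 1 Mb and 3 Mb: mean 2 Mb, sd sqrt(2) Mb
    expect_equal(asd$mean_bp, 2e6)
    expect_equal(asd$sd_bp, sqrt((1e6^2 + 1e6^2) / 1), tolerance = 1e-12)
    expect_equal(asd$sd_bp, stats::sd(c(1e6, 3e6)))
    ## singleton stratum: mean defined, sd absent
    iddd <- sz[sz$stratum == "ID_DD", ]
    expect_equal(iddd$mean_bp, 2e6)
    expect_true(is.na(iddd$sd_bp))
})

test_that("size comparison runs Welch's test between the two groups", {
    fx <- loadReferenceCohort()
    variants(fx) <- classifyVariants(variants(fx), knowledgeBase(fx))
    sc <- sizeCompare(fx, by = "group")
    expect_named(sc$means, c("ASD", "ID_DD"))
    ## ID/DD variants are much larger on average than ASD variants
    expect_gt(sc$means[["ID_DD"]], sc$means[["ASD"]])
    expect_lt(sc$p_welch, 0.05)
    ## cross-check against a direct t.test on the same size vectors
    v <- variants(fx)
    v <- v[!as.logical(mcols(v)$size_interpolated)]
    g <- subjects(fx)$group[match(mcols(v)$subject_id,
                                  subjects(fx)$subject_id)]
    expect_equal(sc$p_welch,
                 stats::t.test(width(v)[g == "ASD"],
                               width(v)[g == "ID_DD"])$p.value)
})

test_that("yield tables are marginally additive over every stratification", {
    fx <- loadReferenceCohort()
    variants(fx) <- classifyVariants(variants(fx), knowledgeBase(fx))
    for (scope in c("strict", "broad")) {
        y <- diagnosticYield(fx, scope, strata = c("group", "sex", "age_bin"))
        cells <- y[y$group != "all" & y$sex != "all" & y$age_bin != "all", ]
        total <- y[y$group == "all" & y$sex == "all" & y$age_bin == "all", ]
        expect_equal(sum(cells$numerator), total$numerator)
        expect_equal(sum(cells$denominator), total$denominator)
        ## group margins equal sums of their cells
        for (g in c("ASD", "ID_DD")) {
            gm <- y[y$group == g & y$sex == "all" & y$age_bin == "all", ]
            expect_equal(sum(cells$numerator[cells$group == g]),
                         gm$numerator)
        }
        expect_true(all(y$numerator <= y$denominator))
        expect_equal(y$fraction, y$numerator / y$denominator)
    }
})

test_that("contrast tables assemble from subject flags and test both ways", {
    fx <- loadReferenceCohort()
    variants(fx) <- classifyVariants(variants(fx), knowledgeBase(fx))
    fx <- assignInheritance(fx)
    sexC <- compareGroups(fx, "sex_by_strict")
    expect_equal(unname(sexC$table),
                 matrix(c(40, 88, 44, 230), 2, byrow = TRUE))
    expect_equal(sexC$p_fisher, fisherOracle(sexC$table))
    dnC <- compareGroups(fx, "group_by_denovo")
    expect_equal(unname(dnC$table),
                 matrix(c(55, 196, 5, 146), 2, byrow = TRUE))
    ## degenerate custom contrast with a zero margin errors
    n <- nrow(subjects(fx)) - nrow(aneuploidies(fx))
    expect_error(compareGroups(fx, "custom",
                               rowFlag = rep(TRUE, n),
                               colFlag = rep(c(TRUE, FALSE), length.out = n)),
                 "margins")
})
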