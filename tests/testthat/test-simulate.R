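test_that("simulation is byte-identical under the same seed", {
    p <- simulationParams(nSubjects = 60, seed = 123)
    s1 <- simulateCohort(p)
    s2 <- simulateCohort(p)
    f1 <- tempfile(); f2 <- tempfile()
    writeSimulation(s1, f1)
    writeSimulation(s2, f2)
    for (f in list.files(f1)) {
        expect_identical(readLines(file.path(f1, f)),
                         readLines(file.path(f2, f)), info = f)
    }
})

test_that("per-subject substreams keep early subjects stable as n grows", {
    pSmall <- simulationParams(nSubjects = 30, seed = 5)
    pBig <- simulationParams(nSubjects = 60, seed = 5)
    vSmall <- variants(simulateCohort(pSmall)$cohort)
    vBig <- variants(simulateCohort(pBig)$cohort)
    ids <- subjects(simulateCohort(pSmall)$cohort)$subject_id
    keep <- mcols(vBig)$subject_id %in% ids
    key <- function(v) paste(mcols(v)$subject_id, seqnames(v), start(v),
                             end(v), mcols(v)$type)
    expect_equal(key(vBig[keep]), key(vSmall))
})

test_that("simulated files parse back through the readers without warnings", {
    sim <- simulateCohort(simulationParams(nSubjects = 40, seed = 9))
    d <- tempfile()
    writeSimulation(sim, d)
    expect_no_warning({
        segs <- readSegmentTable(file.path(d, "segments.tsv"))
        readSegmentTable(file.path(d, "parents.tsv"))
        readSegmentTable(file.path(d, "panel.tsv"))
        readPedigree(file.path(d, "trios.ped"))
        readKnowledgeBase(file.path(d, "kb.tsv"))
    })
    expect_equal(length(segs), length(variants(sim$cohort)))
})

test_that("a null cohort with no syndromic events has zero strict yield", {
    zero <- matrix(0, 2, 2, dimnames = list(c("ASD", "ID_DD"),
                                            c("male", "female")))
    p <- simulationParams(nSubjects = 300, syndromicEventProb = zero,
                          updProb = c(ASD = 0, ID_DD = 0),
                          aneuploidyProb = 0, seed = 21)
    rec <- recoverParameters(simulateCohort(p))
    expect_equal(rec$strict_yield, 0)
})

test_that("a missing mother forces paternal or unknown, never de novo", {
    p <- simulationParams(nSubjects = 150, missingMotherProb = 1,
                          missingFatherProb = 0, seed = 33)
    rec <- recoverParameters(simulateCohort(p))
    v <- variants(rec$cohort)
    expect_true(all(mcols(v)$inheritance[mcols(v)$type != "UPD"] %in%
                    c("paternal", "unknown")))
})

test_that("noiseless tier recovery is perfect at moderate n", {
    rec <- recoverParameters(simulateCohort(
        simulationParams(nSubjects = 400, seed = 2)))
    expect_equal(rec$tier_recovery, 1)
    expect_equal(rec$inheritance_recovery, 1)
})

test_that("parameter validation rejects impossible settings", {
    expect_error(simulationParams(nSubjects = 10), "seed")
    expect_error(simulationParams(fractionASD = 1.4, seed = 1), "\\[0, 1\\]")
    expect_error(simulationParams(benignRate = -1, seed = 1), "non-negative")
})
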