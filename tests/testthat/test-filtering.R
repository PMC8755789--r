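test_that("reporting threshold is inclusive on both size and marker count", {
    cfg <- filterConfig()
    calls <- cnvCalls(c("S1", "S2", "S3", "S4"), "1",
                      c(1, 1, 1, 1) * 1e6,
                      1e6 + c(50000, 49999, 60000, 60000) - 1,
                      "deletion", 1, 1, c(20L, 100L, 19L, 20L))
    kept <- qcFilter(calls, cfg)
    expect_equal(mcols(kept)$subject_id, c("S1", "S4"))
    ## UPD events pass through untouched
    upd <- cnvCalls("S9", "15", 1, 30000, "UPD",
                    parent_of_origin = "maternal")
    expect_length(qcFilter(upd, cfg), 1)
})

test_that("control frequency uses carrier-subject counting at the 1% boundary", {
    cfg <- filterConfig()
    call <- mkCall("2", 10e6, 11e6, "deletion")
    mkPanel <- function(nCarriers) {
        ids <- sprintf("C%03d", seq_len(nCarriers))
        cnvCalls(ids, "2", 10e6, 11e6, "deletion", 1, 1, 50)
    }
    ## 16/1679 = 0.953% passes, 17/1679 = 1.01% fails ("more than 1%")
    a16 <- annotateFrequency(call, mkPanel(16), 1679, cfg = cfg)
    expect_equal(mcols(a16)$control_carriers, 16L)
    expect_true(mcols(a16)$rare)
    a17 <- annotateFrequency(call, mkPanel(17), 1679, cfg = cfg)
    expect_false(mcols(a17)$rare)
    ## a control subject with two matching calls counts once
    twice <- cnvCalls(rep("C001", 2), "2", c(10e6, 10.1e6), c(11e6, 11.1e6),
                      "deletion", 1, 1, 50)
    a1 <- annotateFrequency(call, twice, 1679, cfg = cfg)
    expect_equal(mcols(a1)$control_carriers, 1L)
    expect_equal(mcols(a1)$control_carriers, carrierOracle(call, twice))
    ## no match anywhere
    a0 <- annotateFrequency(call, mkPanel(0), 1679, cfg = cfg)
    expect_equal(mcols(a0)$control_carriers, 0L)
    expect_true(mcols(a0)$rare)
    expect_error(annotateFrequency(call, mkPanel(1), 0), "positive")
})

test_that("carrier counting agrees with a brute-force pairwise oracle", {
    set.seed(11)
    cfg <- filterConfig()
    for (rep in 1:5) {
        q <- mkCall("4", 5e6, 5e6 + 4e5, sample(c("deletion", "duplication"), 1))
        n <- 40
        st <- round(stats::runif(n, 4.5e6, 5.5e6))
        types <- sample(c("deletion", "duplication"), n, TRUE)
        panel <- cnvCalls(sprintf("C%02d", sample(20, n, replace = TRUE)),
                          "4", st, st + round(stats::runif(n, 2e5, 6e5)),
                          types, ifelse(types == "deletion", 1L, 3L),
                          ifelse(types == "deletion", 1L, 3L), 50)
        ann <- annotateFrequency(q, panel, 1679, cfg = cfg)
        expect_equal(mcols(ann)$control_carriers, carrierOracle(q, panel, cfg))
    }
})

test_that("segmental-duplication masking is strict at 70%", {
    cfg <- filterConfig()
    call <- mkCall("1", 1, 100000, "deletion")
    sd699 <- gri("1", 1, 69900)
    sd700 <- gri("1", 1, 70000)
    expect_true(segdupMask(call, sd699, cfg)$keep)
    expect_false(segdupMask(call, sd700, cfg)$keep)
    expect_equal(segdupMask(call, GRanges(), cfg)$fraction, 0)
    expect_true(segdupMask(call, GRanges(), cfg)$keep)
})

test_that("the rarity funnel is idempotent, monotone and keeps UPDs", {
    cfg <- filterConfig()
    set.seed(3)
    n <- 30
    st <- round(stats::runif(n, 1e6, 50e6))
    types <- sample(c("deletion", "duplication"), n, TRUE)
    cp <- ifelse(types == "deletion", 1L, 3L)
    calls <- cnvCalls(sprintf("S%02d", seq_len(n)), "6", st,
                      st + round(stats::runif(n, 4e4, 2e6)),
                      types, cp, cp, sample(10:200, n, TRUE))
    ptype <- rep(types[1:3], each = 100)
    pcp <- rep(cp[1:3], each = 100)
    panel <- cnvCalls(sprintf("C%03d", rep(1:100, 3)), "6",
                      rep(st[1:3], each = 100),
                      rep(st[1:3], each = 100) +
                          rep(width(calls)[1:3] - 1, each = 100),
                      ptype, pcp, pcp, 50)
    rare <- selectRare(calls, panel, 1679, cfg = cfg)
    ## the three panel-common calls are gone
    expect_false(any(mcols(rare)$subject_id %in% c("S01", "S02", "S03")))
    ## idempotence
    again <- selectRare(rare, panel, 1679, cfg = cfg)
    expect_equal(mcols(again)$subject_id, mcols(rare)$subject_id)
    ## monotonicity: raising the frequency ceiling never removes a call
    loose <- selectRare(calls, panel, 1679,
                        cfg = filterConfig(controlFreqMax = 0.2))
    expect_true(all(mcols(rare)$subject_id %in% mcols(loose)$subject_id))
    ## a lone 1 Mb de novo call absent from the panel survives everything
    solo <- mkCall("6", 90e6, 91e6, "deletion", subject = "S99")
    expect_length(selectRare(solo, panel, 1679, cfg = cfg), 1)
})
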