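## shared fixtures and independent oracles for the suite

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## single CNV call with sensible defaults
mkCall <- function(chrom = "1", start = 1e6, end = 2e6, type = "deletion",
                   subject = "S1", markers = 100L, copy = NULL,
                   poo = NA_character_) {
    if (is.null(copy)) copy <- if (type == "deletion") 1L else 3L
    if (type == "UPD") copy <- NA_integer_
    cnvCalls(subject, chrom, start, end, type, copy, copy, markers, poo)
}

gri <- function(chrom, start, end) GRanges(chrom, IRanges(start, end))

## brute-force per-base union coverage on small intervals
coverageOracle <- function(target, cover) {
    pos <- seq(start(target), end(target))
    covered <- rep(FALSE, length(pos))
    for (i in seq_along(cover)) {
        same <- as.character(seqnames(cover))[i] ==
            as.character(seqnames(target))
        if (!same) next
        covered <- covered | (pos >= start(cover)[i] & pos <= end(cover)[i])
    }
    mean(covered)
}

## hypergeometric enumeration oracle for the two-sided exact test
## (probability-mass rule: sum of table probabilities <= observed)
fisherOracle <- function(tab) {
    a <- tab[1, 1]
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - r2):min(k, r1)
    probs <- stats::dhyper(support, r1, r2, k)
    p0 <- stats::dhyper(a, r1, r2, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
}

## brute-force carrier counting for the frequency filter
carrierOracle <- function(call, panel, cfg = filterConfig()) {
    subs <- unique(mcols(panel)$subject_id)
    sum(vapply(subs, function(s) {
        ps <- panel[mcols(panel)$subject_id == s]
        any(vapply(seq_along(ps), function(j)
            isSameCnv(call, ps[j], cfg), logical(1)))
    }, logical(1)))
}

## tiny two-entry knowledge base used across classification tests
tinyKb <- function() {
    kb <- GRanges(c("7", "7", "3"),
                  IRanges(c(72e6, 80e6, 50e6), c(73.4e6, 80.4e6, 50.2e6)))
    mcols(kb)$name <- c("established_region_7q", "single_report_7q",
                        "candidate_gene_3p")
    mcols(kb)$expected_dosage <- c("loss", "loss", "either")
    mcols(kb)$evidence <- c("established_multi_report", "single_report",
                            "candidate_gene")
    mcols(kb)$mechanism <- c(FALSE, FALSE, FALSE)
    mcols(kb)$syndrome <- c(TRUE, FALSE, FALSE)
    mcols(kb)$genes <- c("ELN", "", "CADM2")
    kb
}
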