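#' Reporting-threshold filter on segment calls
#'
#' Retains CNV calls with size >= the reporting threshold (50 kb by default)
#' and marker support >= the minimum probe count (20 by default); both
#' boundaries are inclusive. UPD events pass through untouched. Order is
#' preserved.
#'
#' @param calls a GRanges of calls (see [cnvCalls()])
#' @param cfg a \linkS4class{FilterConfig}
#' @return the retained calls
#' @export
qcFilter <- function(calls, cfg = filterConfig()) {
    if (!length(calls)) return(calls)
    mc <- mcols(calls)
    keep <- mc$type == "UPD" |
        (width(calls) >= cfg@minSizeBp & !is.na(mc$marker_count) &
         mc$marker_count >= cfg@minMarkers)
    calls[keep]
}

#' Annotate one or more calls with control/reference frequency and
#' segmental-duplication coverage
#'
#' Control frequency is carrier-subject counting: a control subject with at
#' least one call deemed identical (dosage-matched reciprocal overlap at the
#' configured threshold) counts once, however many matching calls it has.
#' Reference frequencies are supplied precomputed per reference entry (the
#' maximum frequency over matching entries is taken). A call is rare when
#' its control frequency and reference frequency are both at most 1\% and
#' less than 70\% of its length is segmental duplication.
#'
#' @param calls GRanges of query CNV calls (UPD rows are annotated rare with
#'   zero frequencies)
#' @param panel GRanges of control-panel calls with subject_id
#' @param panelN number of subjects in the panel (>= number of distinct
#'   panel subjects; must be positive)
#' @param reference GRanges of reference CNV entries with a numeric
#'   \code{freq} metadata column, or NULL
#' @param segdups GRanges of segmental-duplication/mask intervals, or NULL
#' @param cfg a \linkS4class{FilterConfig}
#' @return \code{calls} with metadata columns control_carriers,
#'   control_freq, reference_freq, segdup_fraction, rare
#' @export
annotateFrequency <- function(calls, panel, panelN = filterConfig()@controlPanelN,
                              reference = NULL, segdups = NULL,
                              cfg = filterConfig()) {
    if (is.null(panelN) || panelN <= 0)
        stop("panelN must be a positive number of control subjects")
    if (length(panel) && panelN < length(unique(mcols(panel)$subject_id)))
        stop("panelN smaller than the number of distinct panel subjects")
    n <- length(calls)
    carriers <- integer(n); reffreq <- numeric(n); sdfrac <- numeric(n)
    cnv <- mcols(calls)$type != "UPD"
    hits <- .sameCnvHits(calls, panel, cfg)
    if (nrow(hits)) {
        ps <- mcols(panel)$subject_id[hits$p]
        tab <- tapply(ps, hits$q, function(x) length(unique(x)))
        carriers[as.integer(names(tab))] <- as.integer(tab)
    }
    if (!is.null(reference) && length(reference)) {
        rh <- .sameCnvHits(calls, reference, cfg)
        if (nrow(rh)) {
            fr <- mcols(reference)$freq[rh$p]
            tab <- tapply(fr, rh$q, max)
            reffreq[as.integer(names(tab))] <- as.numeric(tab)
        }
    }
    if (!is.null(segdups) && length(segdups)) {
        sd <- reduce(granges(segdups))
        for (i in which(cnv))
            sdfrac[i] <- coverageFraction(calls[i], sd)
    }
    carriers[!cnv] <- 0L; reffreq[!cnv] <- 0; sdfrac[!cnv] <- 0
    mcols(calls)$control_carriers <- carriers
    mcols(calls)$control_freq <- carriers / panelN
    mcols(calls)$reference_freq <- reffreq
    mcols(calls)$segdup_fraction <- sdfrac
    mcols(calls)$rare <- mcols(calls)$control_freq <= cfg@controlFreqMax &
        reffreq <= cfg@referenceFreqMax & sdfrac < cfg@segdupFractionMax
    calls
}

#' Segmental-duplication mask for a single call
#'
#' @param call a single CNV call
#' @param segdups GRanges of mask intervals
#' @param cfg a \linkS4class{FilterConfig}
#' @return list(fraction, keep): keep is TRUE when strictly less than the
#'   configured fraction (70\%) of the call is masked
#' @export
segdupMask <- function(call, segdups, cfg = filterConfig()) {
    frac <- if (length(segdups)) coverageFraction(call, segdups) else 0
    list(fraction = frac, keep = frac < cfg@segdupFractionMax)
}

#' Select rare calls: the full rarity funnel
#'
#' Composition of [qcFilter()] (reporting threshold), [annotateFrequency()]
#' (control and reference rarity) and the segmental-duplication mask. The
#' result carries the full frequency annotation; the funnel is deterministic
#' and idempotent.
#'
#' @inheritParams annotateFrequency
#' @return the annotated rare calls (UPD events always retained)
#' @export
selectRare <- function(calls, panel = GRanges(), panelN = filterConfig()@controlPanelN,
                       reference = NULL, segdups = NULL,
                       cfg = filterConfig()) {
    kept <- qcFilter(calls, cfg)
    kept <- annotateFrequency(kept, panel, panelN, reference, segdups, cfg)
    kept[mcols(kept)$rare | mcols(kept)$type == "UPD"]
}
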