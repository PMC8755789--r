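#' Build a validated GRanges of CNV/UPD segment calls
#'
#' Coordinates are 1-based inclusive (the convention of clinical array
#' reports and of GRanges); a call's size in bp is its width. Copy states
#' are carried as a low/high pair so mosaic states such as x3-4 are
#' representable; non-mosaic calls have low = high.
#'
#' @param subject_id character vector of subject identifiers
#' @param chrom chromosome labels among 1..22, X, Y ("chr" prefixes are
#'   stripped)
#' @param start,end 1-based inclusive coordinates, start <= end
#' @param type one of "deletion", "duplication", "UPD"
#' @param copy_low,copy_high integer copy states in 0..4 (NA for UPD)
#' @param marker_count supporting probe count (NA for UPD)
#' @param parent_of_origin "maternal"/"paternal" for UPD events, else NA
#' @param sexes optional named vector of subject sexes used to validate
#'   sex-chromosome copy-state baselines (X/Y baseline 1 in males, X
#'   baseline 2 in females)
#' @return a GRanges with the call-level metadata columns
#' @examples
#' cnvCalls("S1", "7", 1e6, 2e6, "deletion", 1, 1, 200)
#' @export
cnvCalls <- function(subject_id, chrom, start, end, type,
                     copy_low = NA_integer_, copy_high = NA_integer_,
                     marker_count = NA_integer_,
                     parent_of_origin = NA_character_, sexes = NULL) {
    chrom <- sub("^chr", "", as.character(chrom))
    lens <- c(length(subject_id), length(chrom), length(start),
              length(end), length(type))
    n <- if (any(lens == 0)) 0L else max(lens)
    gr <- GRanges(rep_len(chrom, n),
                  IRanges(rep_len(as.numeric(start), n),
                          rep_len(as.numeric(end), n)))
    mcols(gr)$subject_id <- rep_len(as.character(subject_id), n)
    mcols(gr)$type <- rep_len(as.character(type), n)
    mcols(gr)$copy_low <- rep_len(as.integer(copy_low), n)
    mcols(gr)$copy_high <- rep_len(as.integer(copy_high), n)
    mcols(gr)$marker_count <- rep_len(as.integer(marker_count), n)
    mcols(gr)$parent_of_origin <- rep_len(as.character(parent_of_origin), n)
    bad <- .validateCnvCalls(gr, sexes)
    if (length(bad))
        stop("invalid CNV calls: ", paste(bad, collapse = "; "))
    gr
}

## Validation shared by constructors and NddCohort validity. Returns a
## character vector of problems (empty when valid).
.validateCnvCalls <- function(gr, sexes = NULL) {
    msg <- character()
    chr <- as.character(seqnames(gr))
    if (!all(chr %in% .CHROMS))
        msg <- c(msg, paste("chromosome labels outside 1..22/X/Y:",
                            paste(unique(setdiff(chr, .CHROMS)), collapse = ",")))
    if (any(width(gr) <= 0))
        msg <- c(msg, "intervals must have positive length")
    mc <- mcols(gr)
    need <- c("subject_id", "type", "copy_low", "copy_high", "marker_count")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(c(msg, paste("missing metadata columns:",
                            paste(miss, collapse = ", "))))
    if (!all(mc$type %in% c("deletion", "duplication", "UPD")))
        msg <- c(msg, "type must be deletion, duplication or UPD")
    cnv <- mc$type != "UPD"
    cl <- mc$copy_low[cnv]; ch <- mc$copy_high[cnv]
    if (any(is.na(cl) | is.na(ch)))
        msg <- c(msg, "CNV calls need copy states")
    else {
        if (any(cl < 0 | ch > 4 | cl > ch))
            msg <- c(msg, "copy states must satisfy 0 <= low <= high <= 4")
        ## mosaic states may reach the baseline on one side (e.g. x1-2 loss,
        ## x3-4 gain) but the aberrant side must cross it
        base <- .copyBaseline(chr[cnv], mc$subject_id[cnv], sexes)
        del <- mc$type[cnv] == "deletion"
        if (any(del & !is.na(base) & !(cl < base & ch <= base)))
            msg <- c(msg, "deletions must have copy_low below the dosage baseline")
        if (any(!del & !is.na(base) & !(ch > base & cl >= base)))
            msg <- c(msg, "duplications must have copy_high above the dosage baseline")
    }
    upd <- mc$type == "UPD"
    if (any(upd) && !all(mc$parent_of_origin[upd] %in% c("maternal", "paternal")))
        msg <- c(msg, "UPD events need parent_of_origin maternal/paternal")
    if (any(!is.na(mc$marker_count) & mc$marker_count < 0))
        msg <- c(msg, "marker_count must be >= 0")
    msg
}

## Expected diploid/haploid copy baseline per call; NA when the sex needed
## for an X/Y baseline is unknown (those calls are then not dosage-checked).
.copyBaseline <- function(chrom, subject_id, sexes = NULL) {
    base <- rep(2, length(chrom))
    sexchr <- chrom %in% c("X", "Y")
    if (!any(sexchr)) return(base)
    if (is.null(sexes)) {
        base[sexchr] <- NA
        return(base)
    }
    sex <- unname(sexes[subject_id])
    base[chrom == "Y"] <- ifelse(sex[chrom == "Y"] == "male", 1, NA)
    base[chrom == "X"] <- ifelse(is.na(sex[chrom == "X"]), NA,
                                 ifelse(sex[chrom == "X"] == "male", 1, 2))
    base
}

## dosage of a call set: loss/gain/NA(UPD)
.dosage <- function(gr) {
    type <- mcols(gr)$type
    ifelse(type == "deletion", "loss",
           ifelse(type == "duplication", "gain", NA_character_))
}

#' Reciprocal overlap of two genomic intervals
#'
#' For intervals a and b returns the pair (overlap/length(a),
#' overlap/length(b)). Both fractions are 0 when the intervals sit on
#' different chromosomes or do not intersect. Two CNVs are deemed identical
#' when the smaller of the two fractions reaches the configured threshold
#' (50\% reciprocal overlap by default).
#'
#' @param a,b GRanges of equal length (recycled if one has length 1)
#' @return a two-column matrix with columns \code{frac_a}, \code{frac_b}
#' @examples
#' a <- GenomicRanges::GRanges("1", IRanges::IRanges(1001, 2000))
#' b <- GenomicRanges::GRanges("1", IRanges::IRanges(1501, 2500))
#' reciprocalOverlap(a, b)   # 0.5 / 0.5
#' @export
reciprocalOverlap <- function(a, b) {
    n <- max(length(a), length(b))
    if (length(a) == 1) a <- rep(a, n)
    if (length(b) == 1) b <- rep(b, n)
    stopifnot(length(a) == length(b))
    if (any(width(a) <= 0) || any(width(b) <= 0))
        stop("invalid interval: length must be positive")
    ov <- rep(0, n)
    same <- as.character(seqnames(a)) == as.character(seqnames(b))
    lo <- pmax(start(a), start(b))
    hi <- pmin(end(a), end(b))
    hit <- same & lo <= hi
    ov[hit] <- hi[hit] - lo[hit] + 1
    cbind(frac_a = ov / width(a), frac_b = ov / width(b))
}

#' Fraction of a target interval covered by the union of a set of intervals
#'
#' Overlaps within the cover set are merged before measuring, so
#' self-overlapping cover sets never double-count.
#'
#' @param target a single-interval GRanges
#' @param cover a GRanges of covering intervals (may be empty, may overlap)
#' @return the covered fraction of the target length, in [0, 1]
#' @examples
#' tgt <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 100000))
#' cov <- GenomicRanges::GRanges(c("1", "1"),
#'     IRanges::IRanges(c(1, 50001), c(30000, 90000)))
#' coverageFraction(tgt, cov)   # 0.7
#' @export
coverageFraction <- function(target, cover) {
    stopifnot(length(target) == 1)
    if (length(cover) == 0) return(0)
    tgt <- granges(target)
    cover <- reduce(granges(cover))
    sl <- union(seqlevels(tgt), seqlevels(cover))
    seqlevels(tgt) <- sl; seqlevels(cover) <- sl
    hits <- findOverlaps(tgt, cover)
    if (!length(hits)) return(0)
    inter <- pintersect(rep(tgt, length(hits)),
                        cover[S4Vectors::subjectHits(hits)])
    sum(width(inter)) / width(target)
}

#' Are two CNV calls the same variant?
#'
#' Identity rule used for control-frequency matching and trio inheritance:
#' dosage (loss vs gain) must match and the smaller reciprocal-overlap
#' fraction must reach the configured threshold. The boundary counts as
#' identical (a closed rule; ties are measure-zero in real data). Copy state
#' is deliberately not compared, so an x3 and an x4 duplication of the same
#' segment match.
#'
#' @param a,b single CNV calls (GRanges rows from [cnvCalls()])
#' @param cfg a \linkS4class{FilterConfig}
#' @return logical
#' @export
isSameCnv <- function(a, b, cfg = filterConfig()) {
    if (.dosage(a) %in% NA || .dosage(b) %in% NA)
        stop("isSameCnv applies to CNV calls, not UPD events")
    if (!identical(.dosage(a), .dosage(b))) return(FALSE)
    ro <- reciprocalOverlap(a, b)
    min(ro) >= cfg@reciprocalOverlap
}

## Vectorized identity matching: for each query call, the subject ids of
## panel calls deemed identical. Returns a Hits-like data.frame.
.sameCnvHits <- function(query, panel, cfg) {
    if (!length(query) || !length(panel))
        return(data.frame(q = integer(), p = integer()))
    gq <- granges(query); gp <- granges(panel)
    sl <- union(seqlevels(gq), seqlevels(gp))
    seqlevels(gq) <- sl; seqlevels(gp) <- sl
    hits <- findOverlaps(gq, gp)
    if (!length(hits)) return(data.frame(q = integer(), p = integer()))
    q <- S4Vectors::queryHits(hits); p <- S4Vectors::subjectHits(hits)
    inter <- width(pintersect(gq[q], gp[p]))
    keep <- inter / width(query)[q] >= cfg@reciprocalOverlap &
        inter / width(panel)[p] >= cfg@reciprocalOverlap &
        .dosage(query)[q] == .dosage(panel)[p]
    keep[is.na(keep)] <- FALSE
    data.frame(q = q[keep], p = p[keep])
}
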