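#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect reduce granges
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
NULL

## findOverlaps on objects whose chromosome sets may differ: put both on the
## union of seqlevels first so GenomicRanges does not warn
.ovl <- function(a, b) {
    sl <- union(seqlevels(a), seqlevels(b))
    seqlevels(a) <- sl
    seqlevels(b) <- sl
    findOverlaps(a, b)
}

.CHROMS <- c(as.character(1:22), "X", "Y")

.TIERS <- c("pathogenic", "likely_pathogenic", "VUS", "likely_benign", "benign")

.EVIDENCE <- c("established_multi_report", "single_report", "candidate_gene")

.DOSAGES <- c("loss", "gain", "either", "upd_maternal", "upd_paternal")

#' FilterConfig: every numeric threshold of the triage funnel in one place
#'
#' Holds the reporting threshold (minimum segment size and probe support), the
#' rarity thresholds against the control panel and the reference frequency
#' set, the reciprocal-overlap identity threshold, the segmental-duplication
#' masking fraction, the syndrome-assignment coverage minimum and the
#' significance level. Defaults are the values used for clinical triage of
#' array calls in NDD cohorts: 50 kb / 20 markers reporting threshold,
#' CNVs identical at >= 50\% reciprocal overlap, rare when present in at most
#' 1\% of the 1679-subject control panel and at most 1\% of the reference set,
#' masked when 70\% or more of their length is segmental duplication.
#'
#' @slot minSizeBp minimum reported segment size in bp (default 50000)
#' @slot minMarkers minimum supporting marker (probe) count (default 20)
#' @slot reciprocalOverlap reciprocal-overlap identity threshold (default 0.5)
#' @slot controlFreqMax maximum control carrier frequency for a rare call
#' @slot referenceFreqMax maximum reference-set frequency for a rare call
#' @slot segdupFractionMax calls with segdup coverage at or above this
#'   fraction are dropped (strict bound, default 0.70)
#' @slot controlPanelN number of subjects in the control panel (default 1679)
#' @slot syndromeCoverageMin minimum fraction of a knowledge-base critical
#'   region a variant must cover to be assigned that entry (default 0.50)
#' @slot alpha significance level for cohort contrasts (default 0.05)
#' @export
setClass("FilterConfig", representation(
    minSizeBp = "numeric",
    minMarkers = "numeric",
    reciprocalOverlap = "numeric",
    controlFreqMax = "numeric",
    referenceFreqMax = "numeric",
    segdupFractionMax = "numeric",
    controlPanelN = "numeric",
    syndromeCoverageMin = "numeric",
    alpha = "numeric"
))

setValidity("FilterConfig", function(object) {
    msg <- character()
    fr <- c(reciprocalOverlap = object@reciprocalOverlap,
            controlFreqMax = object@controlFreqMax,
            referenceFreqMax = object@referenceFreqMax,
            segdupFractionMax = object@segdupFractionMax,
            syndromeCoverageMin = object@syndromeCoverageMin,
            alpha = object@alpha)
    bad <- fr < 0 | fr > 1 | is.na(fr)
    if (any(bad))
        msg <- c(msg, paste0("fractions must lie in [0, 1]: ",
                             paste(names(fr)[bad], collapse = ", ")))
    cnt <- c(minSizeBp = object@minSizeBp, minMarkers = object@minMarkers,
             controlPanelN = object@controlPanelN)
    if (any(cnt <= 0 | is.na(cnt)))
        msg <- c(msg, "minSizeBp, minMarkers and controlPanelN must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a FilterConfig
#'
#' @param minSizeBp,minMarkers reporting threshold (size in bp, marker count)
#' @param reciprocalOverlap reciprocal-overlap identity threshold
#' @param controlFreqMax,referenceFreqMax rarity thresholds
#' @param segdupFractionMax segmental-duplication masking fraction (strict)
#' @param controlPanelN control panel size in subjects
#' @param syndromeCoverageMin knowledge-base assignment coverage minimum
#' @param alpha significance level
#' @return a \linkS4class{FilterConfig} object
#' @examples
#' cfg <- filterConfig()
#' cfg
#' @export
filterConfig <- function(minSizeBp = 50000, minMarkers = 20,
                         reciprocalOverlap = 0.50,
                         controlFreqMax = 0.01, referenceFreqMax = 0.01,
                         segdupFractionMax = 0.70, controlPanelN = 1679,
                         syndromeCoverageMin = 0.50, alpha = 0.05) {
    new("FilterConfig", minSizeBp = minSizeBp, minMarkers = minMarkers,
        reciprocalOverlap = reciprocalOverlap, controlFreqMax = controlFreqMax,
        referenceFreqMax = referenceFreqMax,
        segdupFractionMax = segdupFractionMax, controlPanelN = controlPanelN,
        syndromeCoverageMin = syndromeCoverageMin, alpha = alpha)
}

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig\n")
    cat(sprintf("  reporting threshold : >= %s bp, >= %d markers\n",
                format(object@minSizeBp, big.mark = ","),
                as.integer(object@minMarkers)))
    cat(sprintf("  identity rule       : reciprocal overlap >= %.2f, dosage-matched\n",
                object@reciprocalOverlap))
    cat(sprintf("  rarity              : <= %.1f%% of %d controls and <= %.1f%% reference\n",
                100 * object@controlFreqMax, as.integer(object@controlPanelN),
                100 * object@referenceFreqMax))
    cat(sprintf("  segdup mask         : drop at >= %.0f%% coverage\n",
                100 * object@segdupFractionMax))
    cat(sprintf("  syndrome assignment : >= %.0f%% of critical region covered\n",
                100 * object@syndromeCoverageMin))
    cat(sprintf("  alpha               : %.2f\n", object@alpha))
})

#' NddCohort: subjects, variants and aneuploidies of one cohort
#'
#' The central container tying a subject table (sex, age, diagnosis group,
#' parental availability, karyotype), a set of segment-level variants
#' (CNV and UPD calls as a GRanges), whole-chromosome aneuploidy events, a
#' pedigree and optional parental segment calls together. Variant-level
#' annotation added by the pipeline (frequency, tier, inheritance) lives in
#' the metadata columns of \code{variants(x)}.
#'
#' @slot subjects DataFrame with columns subject_id, sex, age_months, group,
#'   father_id, mother_id, karyotype
#' @slot variants GRanges with columns subject_id, type, copy_low, copy_high,
#'   marker_count, parent_of_origin and any pipeline annotation
#' @slot aneuploidies DataFrame with columns subject_id, karyotype_label
#' @slot parentCalls GRanges of parental segment calls (same schema as
#'   variants, subject_id = parent id); may be empty
#' @slot knowledgeBase GRanges knowledge base (may be empty)
#' @export
setClass("NddCohort", representation(
    subjects = "DataFrame",
    variants = "GRanges",
    aneuploidies = "DataFrame",
    parentCalls = "GRanges",
    knowledgeBase = "GRanges"
))

setValidity("NddCohort", function(object) {
    msg <- character()
    sub <- object@subjects
    need <- c("subject_id", "sex", "age_months", "group")
    miss <- setdiff(need, colnames(sub))
    if (length(miss))
        return(paste("subjects lacks columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(sub$subject_id))
        msg <- c(msg, "subject ids must be unique within the cohort")
    if (!all(sub$sex %in% c("male", "female")))
        msg <- c(msg, "sex must be male or female")
    if (!all(sub$group %in% c("ASD", "ID_DD")))
        msg <- c(msg, "group must be ASD or ID_DD")
    if (any(sub$age_months < 0, na.rm = TRUE))
        msg <- c(msg, "age_months must be >= 0")
    vs <- object@variants
    if (length(vs)) {
        bad <- .validateCnvCalls(vs, sexOf(object))
        if (length(bad)) msg <- c(msg, bad)
        if (!all(mcols(vs)$subject_id %in% sub$subject_id))
            msg <- c(msg, "variants refer to unknown subject ids")
    }
    an <- object@aneuploidies
    if (nrow(an)) {
        if (!all(c("subject_id", "karyotype_label") %in% colnames(an)))
            msg <- c(msg, "aneuploidies needs subject_id, karyotype_label")
        else if (any(!nzchar(an$karyotype_label)))
            msg <- c(msg, "aneuploidy karyotype labels must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "NddCohort", function(object) {
    sub <- object@subjects
    cat("NddCohort with", nrow(sub), "subjects (",
        sum(sub$group == "ASD"), "ASD /", sum(sub$group == "ID_DD"), "ID_DD )\n")
    cat("  variants     :", length(object@variants), "segment calls\n")
    cat("  aneuploidies :", nrow(object@aneuploidies), "subjects\n")
    cat("  parent calls :", length(object@parentCalls), "\n")
    cat("  knowledge base:", length(object@knowledgeBase), "entries\n")
})

#' Accessors for NddCohort
#'
#' @param x an \linkS4class{NddCohort}
#' @return \code{subjects}: the subject DataFrame; \code{variants}: the
#'   variant GRanges; \code{aneuploidies}: the aneuploidy DataFrame;
#'   \code{parentCalls}: parental segment calls; \code{knowledgeBase}: the
#'   knowledge-base GRanges; \code{sexOf}: named character vector of subject
#'   sexes.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
subjects <- function(x) x@subjects

#' @rdname cohort-accessors
#' @export
variants <- function(x) x@variants

#' @rdname cohort-accessors
#' @export
aneuploidies <- function(x) x@aneuploidies

#' @rdname cohort-accessors
#' @export
parentCalls <- function(x) x@parentCalls

#' @rdname cohort-accessors
#' @export
knowledgeBase <- function(x) x@knowledgeBase

#' @rdname cohort-accessors
#' @export
sexOf <- function(x) {
    sub <- x@subjects
    stats::setNames(as.character(sub$sex), sub$subject_id)
}

#' Replace the variants of a cohort
#'
#' @param x an NddCohort
#' @param value a GRanges in the variant schema
#' @export
`variants<-` <- function(x, value) {
    x@variants <- value
    validObject(x)
    x
}

#' Construct an NddCohort
#'
#' @param subjects data.frame/DataFrame of subjects
#' @param variants GRanges of CNV/UPD calls (may be empty)
#' @param aneuploidies data.frame of aneuploidy events
#' @param parentCalls GRanges of parental calls
#' @param knowledgeBase GRanges knowledge base
#' @return an \linkS4class{NddCohort}
#' @export
nddCohort <- function(subjects, variants = GRanges(),
                      aneuploidies = data.frame(subject_id = character(),
                                                karyotype_label = character()),
                      parentCalls = GRanges(), knowledgeBase = GRanges()) {
    sub <- DataFrame(subjects)
    if (is.null(sub$father_id)) sub$father_id <- NA_character_
    if (is.null(sub$mother_id)) sub$mother_id <- NA_character_
    if (is.null(sub$karyotype)) sub$karyotype <- "normal"
    new("NddCohort", subjects = sub, variants = variants,
        aneuploidies = DataFrame(aneuploidies), parentCalls = parentCalls,
        knowledgeBase = knowledgeBase)
}
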