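#' Trio inheritance for a single child call
#'
#' A child CNV is \emph{paternal} when it is deemed identical
#' (dosage-matched reciprocal overlap) to at least one call of the father
#' and to none of the mother, \emph{maternal} symmetrically,
#' \emph{biparental} when both parents carry it, \emph{de novo} when both
#' parents were genotyped and neither carries it, and \emph{unknown} when a
#' parent is missing and no genotyped parent carries it. De novo therefore
#' requires both parents. UPD events keep their annotated parent of origin
#' and are not re-evaluated here.
#'
#' @param childCall a single CNV call
#' @param fatherCalls GRanges of the father's post-QC calls, or NULL when
#'   the father was unavailable
#' @param motherCalls GRanges of the mother's calls, or NULL when missing
#' @param cfg a \linkS4class{FilterConfig}
#' @return list(status, evidence): status in de_novo / paternal / maternal /
#'   biparental / unknown; evidence holds indices of matching parental calls
#' @export
determineInheritance <- function(childCall, fatherCalls, motherCalls,
                                 cfg = filterConfig()) {
    stopifnot(length(childCall) == 1)
    matchIn <- function(calls) {
        if (is.null(calls) || !length(calls)) return(integer())
        .sameCnvHits(childCall, calls, cfg)$p
    }
    fHit <- matchIn(fatherCalls); mHit <- matchIn(motherCalls)
    status <- if (length(fHit) && length(mHit)) "biparental"
        else if (length(fHit)) "paternal"
        else if (length(mHit)) "maternal"
        else if (!is.null(fatherCalls) && !is.null(motherCalls)) "de_novo"
        else "unknown"
    list(status = status,
         evidence = list(father = fHit, mother = mHit))
}

#' Assign inheritance to every variant of a cohort
#'
#' Applies [determineInheritance()] per child CNV against the cohort's
#' parental calls, using the pedigree in the subject table (an absent
#' father_id/mother_id means that parent was unavailable). UPD events carry
#' their input parent-of-origin annotation through unchanged.
#'
#' @param cohort an \linkS4class{NddCohort}
#' @param cfg a \linkS4class{FilterConfig}
#' @return the cohort with an \code{inheritance} metadata column on its
#'   variants
#' @export
assignInheritance <- function(cohort, cfg = filterConfig()) {
    v <- variants(cohort)
    if (!length(v)) return(cohort)
    sub <- subjects(cohort)
    pc <- parentCalls(cohort)
    m <- match(mcols(v)$subject_id, sub$subject_id)
    fid <- as.character(sub$father_id)[m]
    mid <- as.character(sub$mother_id)[m]
    ## one overlap join against all parental calls, then split by parent
    fMatch <- mMatch <- rep(FALSE, length(v))
    if (length(pc)) {
        hits <- .sameCnvHits(v, pc, cfg)
        if (nrow(hits)) {
            pid <- mcols(pc)$subject_id[hits$p]
            fh <- hits$q[!is.na(fid[hits$q]) & pid == fid[hits$q]]
            mh <- hits$q[!is.na(mid[hits$q]) & pid == mid[hits$q]]
            fMatch[unique(fh)] <- TRUE
            mMatch[unique(mh)] <- TRUE
        }
    }
    inh <- ifelse(fMatch & mMatch, "biparental",
           ifelse(fMatch, "paternal",
           ifelse(mMatch, "maternal",
           ifelse(!is.na(fid) & !is.na(mid), "de_novo", "unknown"))))
    upd <- mcols(v)$type == "UPD"
    inh[upd] <- mcols(v)$parent_of_origin[upd]
    mcols(v)$inheritance <- inh
    cohort@variants <- v
    cohort
}

#' Cohort inheritance summary
#'
#' Per-variant and per-subject tallies of inheritance status by diagnosis
#' group. A subject's de novo flag is set when it carries at least one
#' de novo variant. The per-variant statuses always partition the variants:
#' de_novo + paternal + maternal + biparental + unknown = total, in every
#' stratum.
#'
#' @param cohort an \linkS4class{NddCohort} with assigned inheritance
#' @param tiers restrict to variants in these tiers (default: the
#'   clinically relevant tiers) when a tier column is present
#' @return list(variants = status x group table, subjects = data.frame of
#'   per-subject de novo flags with group)
#' @export
inheritanceSummary <- function(cohort,
                               tiers = c("pathogenic", "likely_pathogenic",
                                         "VUS")) {
    v <- variants(cohort)
    if (length(v) && is.null(mcols(v)$inheritance))
        stop("variants carry no inheritance; run assignInheritance() first")
    sub <- subjects(cohort)
    statuses <- c("de_novo", "paternal", "maternal", "biparental", "unknown")
    if (length(v) && !is.null(mcols(v)$tier))
        v <- v[mcols(v)$tier %in% tiers]
    grp <- sub$group[match(mcols(v)$subject_id, sub$subject_id)]
    st <- mcols(v)$inheritance
    tab <- table(factor(st, levels = statuses),
                 factor(grp, levels = c("ASD", "ID_DD")))
    denovoIds <- unique(mcols(v)$subject_id[st == "de_novo"])
    subjFlags <- data.frame(subject_id = sub$subject_id, group = sub$group,
                            sex = sub$sex,
                            de_novo = sub$subject_id %in% denovoIds,
                            stringsAsFactors = FALSE)
    list(variants = tab, subjects = subjFlags)
}
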