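.EVIDENCE_RANK <- c(established_multi_report = 3, single_report = 2,
                    candidate_gene = 1)

## dosage compatibility between a variant row and KB entries
.dosageCompatible <- function(type, poo, expected) {
    switch(type,
           deletion = expected %in% c("loss", "either"),
           duplication = expected %in% c("gain", "either"),
           UPD = (expected == "upd_maternal" & poo %in% "maternal") |
                 (expected == "upd_paternal" & poo %in% "paternal"))
}

#' Best-matching knowledge-base entry for each variant
#'
#' An entry matches when its expected dosage is compatible with the variant
#' and the variant covers at least the configured fraction (50\% by default)
#' of the entry's critical region. Among matches the entry with the largest
#' covered fraction wins; ties break by evidence strength
#' (established > single report > candidate gene), then by name, so
#' assignment is deterministic.
#'
#' @param v GRanges of variants (post-filter CNVs, UPDs)
#' @param kb knowledge-base GRanges from [readKnowledgeBase()]
#' @param cfg a \linkS4class{FilterConfig}
#' @return a DataFrame (one row per variant) with \code{entry} (index into
#'   kb or NA), \code{name}, \code{evidence}, \code{mechanism},
#'   \code{covered}
#' @export
matchSyndrome <- function(v, kb, cfg = filterConfig()) {
    n <- length(v)
    out <- DataFrame(entry = rep(NA_integer_, n), name = NA_character_,
                     evidence = NA_character_, mechanism = NA,
                     covered = NA_real_)
    if (!n || !length(kb)) return(out)
    gv <- granges(v); gk <- granges(kb)
    sl <- union(seqlevels(gv), seqlevels(gk))
    seqlevels(gv) <- sl; seqlevels(gk) <- sl
    hits <- findOverlaps(gv, gk)
    if (!length(hits)) return(out)
    q <- S4Vectors::queryHits(hits); e <- S4Vectors::subjectHits(hits)
    inter <- width(pintersect(gv[q], gk[e]))
    covered <- inter / width(kb)[e]
    type <- mcols(v)$type[q]; poo <- mcols(v)$parent_of_origin[q]
    compat <- vapply(seq_along(q), function(i)
        .dosageCompatible(type[i], poo[i], mcols(kb)$expected_dosage[e[i]]),
        logical(1))
    keep <- compat & covered >= cfg@syndromeCoverageMin
    q <- q[keep]; e <- e[keep]; covered <- covered[keep]
    if (!length(q)) return(out)
    rank <- .EVIDENCE_RANK[mcols(kb)$evidence[e]]
    ord <- order(q, -covered, -rank, mcols(kb)$name[e])
    first <- ord[!duplicated(q[ord])]
    out$entry[q[first]] <- e[first]
    out$name[q[first]] <- mcols(kb)$name[e[first]]
    out$evidence[q[first]] <- mcols(kb)$evidence[e[first]]
    out$mechanism[q[first]] <- mcols(kb)$mechanism[e[first]]
    out$covered[q[first]] <- covered[first]
    out
}

#' Five-tier clinical classification of rare variants
#'
#' Operationalizes the ACMG-style rules used for clinical array reporting:
#' \itemize{
#'   \item \strong{pathogenic} — the variant matches an established,
#'     multiply-reported syndrome/critical region (including a UPD of an
#'     imprinted established region);
#'   \item \strong{likely_pathogenic} — the best match is a single-report
#'     region, or the variant disrupts a candidate-gene entry flagged with a
#'     compelling NDD-specific dosage mechanism;
#'   \item \strong{VUS} — rare and overlapping gene-bearing knowledge-base
#'     content, but neither rule above fires;
#'   \item \strong{likely_benign} — rare with no knowledge-base overlap;
#'   \item \strong{benign} — not rare (only reachable in annotate-all mode,
#'     i.e. when a \code{rare} column marks common calls).
#' }
#' Every variant receives exactly one tier.
#'
#' @param v GRanges of variants; a logical \code{rare} metadata column is
#'   honoured if present (absent means all calls already passed the funnel)
#' @param kb knowledge-base GRanges
#' @param cfg a \linkS4class{FilterConfig}
#' @return \code{v} with metadata columns \code{tier},
#'   \code{matched_entry}, \code{rationale}
#' @export
classifyVariants <- function(v, kb, cfg = filterConfig()) {
    n <- length(v)
    if (!n) {
        mcols(v)$tier <- character(); mcols(v)$matched_entry <- character()
        mcols(v)$rationale <- character()
        return(v)
    }
    ## tolerate "TRUE"/"FALSE" strings from round-tripped annotated tables
    rare <- if (is.null(mcols(v)$rare)) rep(TRUE, n) else
        as.logical(mcols(v)$rare)
    m <- matchSyndrome(v, kb, cfg)
    overlapsKb <- rep(FALSE, n)
    if (length(kb)) {
        hits <- .ovl(granges(v), granges(kb))
        overlapsKb[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    tier <- character(n); rationale <- character(n)
    for (i in seq_len(n)) {
        if (!rare[i]) {
            tier[i] <- "benign"; rationale[i] <- "common_variant"
        } else if (!is.na(m$evidence[i]) &&
                   m$evidence[i] == "established_multi_report") {
            tier[i] <- "pathogenic"
            rationale[i] <- if (mcols(v)$type[i] == "UPD")
                "imprinted_established_upd" else "established_region"
        } else if (!is.na(m$evidence[i]) && m$evidence[i] == "single_report") {
            tier[i] <- "likely_pathogenic"; rationale[i] <- "single_report_region"
        } else if (!is.na(m$evidence[i]) && m$evidence[i] == "candidate_gene" &&
                   isTRUE(m$mechanism[i])) {
            tier[i] <- "likely_pathogenic"; rationale[i] <- "candidate_mechanism"
        } else if (overlapsKb[i]) {
            tier[i] <- "VUS"; rationale[i] <- "uncertain_gene_overlap"
        } else {
            tier[i] <- "likely_benign"; rationale[i] <- "no_gene_content"
        }
    }
    mcols(v)$tier <- tier
    mcols(v)$matched_entry <- m$name
    mcols(v)$rationale <- rationale
    v
}

#' Subject-level classification summary
#'
#' Collapses classified variants to one row per subject: the most severe
#' tier carried (severity pathogenic > likely_pathogenic > VUS >
#' likely_benign > benign), whether the subject is clinically relevant
#' (carries at least one pathogenic / likely pathogenic / VUS variant) and
#' whether the subject counts toward the strict diagnostic yield (at least
#' one pathogenic or likely pathogenic variant, or an aneuploidy). A subject
#' with several qualifying variants counts once.
#'
#' @param cohort an \linkS4class{NddCohort} whose variants carry a
#'   \code{tier} column (see [classifyVariants()])
#' @return a DataFrame with one row per subject: subject_id, group, sex,
#'   age_months, aneuploid, top_tier, clinically_relevant, diagnosed_strict,
#'   n_variants
#' @export
classifySubjects <- function(cohort) {
    sub <- subjects(cohort)
    v <- variants(cohort)
    if (length(v) && is.null(mcols(v)$tier))
        stop("variants are not classified; run classifyVariants() first")
    an <- aneuploidies(cohort)
    out <- DataFrame(subject_id = sub$subject_id, group = sub$group,
                     sex = sub$sex, age_months = sub$age_months,
                     aneuploid = sub$subject_id %in% an$subject_id,
                     top_tier = NA_character_,
                     clinically_relevant = FALSE,
                     diagnosed_strict = FALSE,
                     n_variants = 0L)
    if (length(v)) {
        sev <- match(mcols(v)$tier, .TIERS)   # 1 = most severe
        byId <- split(sev, mcols(v)$subject_id)
        m <- match(names(byId), out$subject_id)
        out$top_tier[m] <- .TIERS[vapply(byId, min, 0)]
        out$n_variants[m] <- lengths(byId)
        out$clinically_relevant[m] <- vapply(byId, min, 0) <= 3
        out$diagnosed_strict[m] <- vapply(byId, min, 0) <= 2
    }
    out$diagnosed_strict <- out$diagnosed_strict | out$aneuploid
    out$clinically_relevant <- out$clinically_relevant | out$aneuploid
    out
}
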