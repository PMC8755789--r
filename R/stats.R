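.AGE_BINS <- c("<1", "1-2", "2-5", ">5")

## report-style rounding: halves away from zero (39/128 -> 31.3%), unlike
## round()'s round-half-even
.roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Age bin from age in months
#'
#' Clinical reporting bins: under 1 year, 1 to 2, 2 to 5, over 5. Bins are
#' lower-closed: exactly 24 months falls in the 2-5 bin.
#'
#' @param ageMonths integer vector of ages in months
#' @return factor with levels <1, 1-2, 2-5, >5
#' @export
ageBin <- function(ageMonths) {
    cut(ageMonths, breaks = c(-Inf, 12, 24, 60, Inf), right = FALSE,
        labels = .AGE_BINS)
}

#' Diagnostic-yield table with optional stratification
#'
#' The strict yield counts subjects carrying at least one pathogenic or
#' likely pathogenic variant (or an aneuploidy when those subjects are
#' included); the broad yield counts clinically relevant subjects
#' (pathogenic, likely pathogenic or VUS). Aneuploid subjects are excluded
#' from numerator and denominator unless \code{includeAneuploidy}, in which
#' case they enter both. Rows are emitted for every stratum combination
#' plus marginal totals; a stratum with an empty denominator is flagged.
#'
#' @param cohort an \linkS4class{NddCohort} with classified variants
#' @param scope "strict" or "broad"
#' @param includeAneuploidy logical
#' @param strata character subset of c("group", "sex", "age_bin"); NULL for
#'   the overall yield only
#' @return a data.frame with stratum columns, numerator, denominator,
#'   fraction and percent
#' @examples
#' fx <- loadReferenceCohort()
#' diagnosticYield(fx, "strict")                       # 84 / 402
#' diagnosticYield(fx, "strict", strata = "group")     # 5/151, 79/251
#' @export
diagnosticYield <- function(cohort, scope = c("strict", "broad"),
                            includeAneuploidy = FALSE, strata = NULL) {
    scope <- match.arg(scope)
    cls <- classifySubjects(cohort)
    if (!includeAneuploidy) cls <- cls[!cls$aneuploid, ]
    flag <- if (scope == "strict") cls$diagnosed_strict else
        cls$clinically_relevant
    df <- data.frame(group = cls$group, sex = cls$sex,
                     age_bin = as.character(ageBin(cls$age_months)),
                     flag = flag, stringsAsFactors = FALSE)
    allowed <- c("group", "sex", "age_bin")
    if (!is.null(strata) && length(setdiff(strata, allowed)))
        stop("strata must be among ", paste(allowed, collapse = ", "))
    ## all marginal combinations of the requested strata, plus the overall row
    combos <- list(character())
    if (!is.null(strata) && length(strata)) {
        idx <- unlist(lapply(seq_along(strata), function(k)
            utils::combn(seq_along(strata), k, simplify = FALSE)),
            recursive = FALSE)
        combos <- c(lapply(idx, function(i) strata[i]), list(character()))
    }
    rows <- list()
    for (by in combos) {
        if (!length(by)) {
            rows[[length(rows) + 1L]] <-
                data.frame(group = "all", sex = "all", age_bin = "all",
                           numerator = sum(df$flag), denominator = nrow(df),
                           stringsAsFactors = FALSE)
        } else {
            agg <- stats::aggregate(df$flag, by = df[by], FUN = function(x)
                c(num = sum(x), den = length(x)))
            out <- data.frame(group = "all", sex = "all", age_bin = "all",
                              numerator = agg$x[, "num"],
                              denominator = agg$x[, "den"],
                              stringsAsFactors = FALSE)
            for (col in by) out[[col]] <- as.character(agg[[col]])
            rows[[length(rows) + 1L]] <- out
        }
    }
    res <- do.call(rbind, rows)
    res <- res[!duplicated(res[c("group", "sex", "age_bin")]), ]
    res$fraction <- ifelse(res$denominator > 0,
                           res$numerator / res$denominator, NA_real_)
    res$percent <- .roundHalfUp(100 * res$fraction, 1)
    res$empty_stratum <- res$denominator == 0
    res$scope <- scope
    res$include_aneuploidy <- includeAneuploidy
    rownames(res) <- NULL
    res
}

## convenience: pull one yield cell as "num/den"
.yieldCell <- function(yld, group = "all", sex = "all", age_bin = "all") {
    r <- yld[yld$group == group & yld$sex == sex & yld$age_bin == age_bin, ]
    if (nrow(r) != 1) stop("no unique yield cell for the requested stratum")
    c(num = r$numerator, den = r$denominator)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value under the probability-mass two-sided rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. All
#' margins must be positive.
#'
#' @param tab a 2x2 matrix of non-negative counts
#' @return the p-value in (0, 1]
#' @examples
#' fisherTwoSided(matrix(c(5, 0, 0, 5), 2))   # 2/252
#' @export
fisherTwoSided <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
        stop("need a 2x2 table of non-negative integer counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all margins of the 2x2 table must be positive")
    stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Asymptotic chi-square p-value for a 2x2 table (no continuity correction)
#'
#' Reported alongside the exact test because legacy statistical software
#' defaults differ and reported p-values for cohort contrasts are often
#' asymptotic; see the package vignette.
#'
#' @param tab a 2x2 matrix
#' @return p-value
#' @export
chisqTwoSided <- function(tab) {
    suppressWarnings(stats::chisq.test(as.matrix(tab), correct = FALSE)$p.value)
}

#' Size summaries of variants per stratum
#'
#' Mean, sample standard deviation (n - 1), minimum and maximum of variant
#' sizes in bp. Fixture rows whose sizes were interpolated inside a
#' published group range (\code{size_interpolated}) are excluded. Singleton
#' strata report an NA standard deviation; empty strata are absent.
#'
#' @param cohort an \linkS4class{NddCohort}
#' @param strata subject columns to stratify by (e.g. "group", "sex"), or
#'   NULL for the whole cohort
#' @param tiers restrict to these tiers when variants are classified
#' @return data.frame with stratum columns, n, mean_bp, sd_bp, min_bp,
#'   max_bp
#' @export
sizeSummary <- function(cohort, strata = NULL,
                        tiers = c("pathogenic", "likely_pathogenic", "VUS")) {
    v <- variants(cohort)
    if (!is.null(mcols(v)$tier)) v <- v[mcols(v)$tier %in% tiers]
    if (!is.null(mcols(v)$size_interpolated))
        v <- v[!mcols(v)$size_interpolated]
    if (!length(v))
        return(data.frame(n = integer(), mean_bp = numeric(),
                          sd_bp = numeric(), min_bp = numeric(),
                          max_bp = numeric()))
    sub <- subjects(cohort)
    m <- match(mcols(v)$subject_id, sub$subject_id)
    df <- data.frame(size = width(v))
    key <- rep("all", length(v))
    if (!is.null(strata) && length(strata)) {
        parts <- lapply(strata, function(s) as.character(sub[[s]])[m])
        key <- do.call(paste, c(parts, sep = "/"))
    }
    agg <- lapply(split(df$size, key), function(x)
        data.frame(n = length(x), mean_bp = mean(x),
                   sd_bp = if (length(x) > 1) stats::sd(x) else NA_real_,
                   min_bp = min(x), max_bp = max(x)))
    out <- do.call(rbind, agg)
    out <- cbind(stratum = names(agg), out)
    rownames(out) <- NULL
    out
}

#' Two-sample comparison of variant sizes between strata
#'
#' Welch's unequal-variance t test on variant sizes (bp) between the two
#' levels of a subject stratum, excluding interpolated fixture sizes. The
#' choice of test for size differences is a reporting convention, not part
#' of the count-based yield machinery; treat the p-value as descriptive.
#'
#' @param cohort an \linkS4class{NddCohort}
#' @param by subject column with exactly two levels among the variant
#'   carriers (default "group")
#' @param tiers tiers to include
#' @return list(means, p_welch)
#' @export
sizeCompare <- function(cohort, by = "group",
                        tiers = c("pathogenic", "likely_pathogenic", "VUS")) {
    v <- variants(cohort)
    if (!is.null(mcols(v)$tier)) v <- v[mcols(v)$tier %in% tiers]
    if (!is.null(mcols(v)$size_interpolated))
        v <- v[!as.logical(mcols(v)$size_interpolated)]
    sub <- subjects(cohort)
    g <- as.character(sub[[by]])[match(mcols(v)$subject_id,
                                       sub$subject_id)]
    lv <- sort(unique(g))
    if (length(lv) != 2)
        stop("sizeCompare needs exactly two strata with variants")
    t <- stats::t.test(width(v)[g == lv[1]], width(v)[g == lv[2]])
    list(means = stats::setNames(c(mean(width(v)[g == lv[1]]),
                                   mean(width(v)[g == lv[2]])), lv),
         p_welch = t$p.value)
}

#' Cohort contrasts as 2x2 tables with exact and asymptotic p-values
#'
#' Builds the 2x2 table from per-subject flags and tests it. Available
#' contrasts: \code{sex_by_strict} (sex vs strict diagnosis, aneuploid
#' subjects excluded), \code{group_by_denovo} (diagnosis group vs carrying a
#' de novo variant), or \code{custom} with caller-supplied logical vectors.
#'
#' @param cohort an \linkS4class{NddCohort} with classification and
#'   inheritance assigned
#' @param contrast one of "sex_by_strict", "group_by_denovo", "custom"
#' @param rowFlag,colFlag logical vectors over subjects for "custom"
#' @return list(table, p_fisher, p_chisq)
#' @export
compareGroups <- function(cohort, contrast = c("sex_by_strict",
                                               "group_by_denovo", "custom"),
                          rowFlag = NULL, colFlag = NULL) {
    contrast <- match.arg(contrast)
    cls <- classifySubjects(cohort)
    cls <- cls[!cls$aneuploid, ]
    if (contrast == "sex_by_strict") {
        rows <- cls$sex == "female"
        cols <- cls$diagnosed_strict
        dn <- c("female", "male"); cn <- c("diagnosed", "not")
    } else if (contrast == "group_by_denovo") {
        inh <- inheritanceSummary(cohort)$subjects
        inh <- inh[match(cls$subject_id, inh$subject_id), ]
        rows <- cls$group == "ID_DD"
        cols <- inh$de_novo
        dn <- c("ID_DD", "ASD"); cn <- c("de_novo", "not")
    } else {
        if (is.null(rowFlag) || is.null(colFlag))
            stop("custom contrast needs rowFlag and colFlag")
        rows <- rowFlag; cols <- colFlag
        dn <- c("TRUE", "FALSE"); cn <- c("TRUE", "FALSE")
    }
    tab <- matrix(c(sum(rows & cols), sum(rows & !cols),
                    sum(!rows & cols), sum(!rows & !cols)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(dn, cn))
    list(table = tab,
         p_fisher = fisherTwoSided(tab),
         p_chisq = chisqTwoSided(tab))
}
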