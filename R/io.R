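#' Read a tab-delimited segment-call table
#'
#' The segment table is the package's minimal array-export-like exchange
#' format (one row per called segment): columns \code{subject_id},
#' \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#' \code{type} (deletion / duplication / UPD), \code{copy_state}
#' (e.g. "1", "3", "3-4" for mosaics; empty for UPD), \code{marker_count}
#' and optionally \code{parent_of_origin} (UPD rows only). Extra columns are
#' carried through as metadata columns, which is how annotated tables
#' written by the pipeline round-trip.
#'
#' @param path path to a TSV file with a header line
#' @param sexes optional named sex vector for copy-state baseline validation
#' @return a GRanges of calls (see [cnvCalls()]); row order preserved
#' @export
readSegmentTable <- function(path, sexes = NULL) {
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE)
    need <- c("subject_id", "chrom", "start", "end", "type", "copy_state",
              "marker_count")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("segment table lacks columns: ", paste(miss, collapse = ", "))
    if (!nrow(df)) return(cnvCalls(character(), character(), numeric(),
                                   numeric(), character()))
    line <- seq_len(nrow(df)) + 1L   # 1-based file line, after header
    start <- suppressWarnings(as.numeric(gsub(",", "", df$start)))
    end <- suppressWarnings(as.numeric(gsub(",", "", df$end)))
    bad <- which(is.na(start) | is.na(end) | start > end | start < 1)
    if (length(bad))
        stop("malformed coordinates in segment table at line ",
             paste(line[bad], collapse = ", "))
    bad <- which(!df$type %in% c("deletion", "duplication", "UPD"))
    if (length(bad))
        stop("unknown dosage/type '", df$type[bad[1]],
             "' in segment table at line ", paste(line[bad], collapse = ", "))
    cs <- .parseCopyState(df$copy_state, df$type, line)
    poo <- if ("parent_of_origin" %in% colnames(df)) {
        ifelse(nzchar(df$parent_of_origin), df$parent_of_origin, NA_character_)
    } else NA_character_
    gr <- cnvCalls(df$subject_id, df$chrom, start, end, df$type,
                   cs$low, cs$high,
                   ifelse(nzchar(df$marker_count),
                          suppressWarnings(as.integer(df$marker_count)),
                          NA_integer_),
                   poo, sexes = sexes)
    extra <- setdiff(colnames(df), c(need, "parent_of_origin"))
    for (col in extra) mcols(gr)[[col]] <- df[[col]]
    gr
}

## "3-4" -> (3,4); "3" -> (3,3); "" -> NA (UPD rows only)
.parseCopyState <- function(x, type, line) {
    x <- gsub("–", "-", trimws(x))    # tolerate en-dash from reports
    low <- high <- rep(NA_integer_, length(x))
    cnv <- type != "UPD"
    parts <- strsplit(x, "-", fixed = TRUE)
    for (i in which(cnv)) {
        p <- suppressWarnings(as.integer(parts[[i]]))
        if (!length(p) || anyNA(p) || length(p) > 2)
            stop("malformed copy_state '", x[i],
                 "' in segment table at line ", line[i])
        low[i] <- p[1]; high[i] <- p[length(p)]
    }
    list(low = low, high = high)
}

#' Write a segment-call table
#'
#' Inverse of [readSegmentTable()]: writing then reading a well-formed table
#' reproduces it, with a byte-stable column order.
#'
#' @param gr a GRanges of calls
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeSegmentTable <- function(gr, path) {
    mc <- mcols(gr)
    cs <- ifelse(mc$type == "UPD", "",
                 ifelse(mc$copy_low == mc$copy_high,
                        as.character(mc$copy_low),
                        paste0(mc$copy_low, "-", mc$copy_high)))
    df <- data.frame(subject_id = mc$subject_id,
                     chrom = as.character(seqnames(gr)),
                     start = format(start(gr), scientific = FALSE, trim = TRUE),
                     end = format(end(gr), scientific = FALSE, trim = TRUE),
                     type = mc$type, copy_state = cs,
                     marker_count = ifelse(is.na(mc$marker_count), "",
                                           mc$marker_count),
                     parent_of_origin = ifelse(is.na(mc$parent_of_origin), "",
                                               mc$parent_of_origin),
                     stringsAsFactors = FALSE)
    extra <- setdiff(colnames(mc),
                     c("subject_id", "type", "copy_low", "copy_high",
                       "marker_count", "parent_of_origin"))
    for (col in extra) df[[col]] <- as.character(mc[[col]])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a BED file of mask intervals (e.g. segmental duplications)
#'
#' Standard BED: 0-based half-open on disk, converted to 1-based inclusive
#' GRanges on read. Track definition and comment lines are skipped.
#'
#' @param path path to a BED file (3+ columns)
#' @return a GRanges
#' @export
readBed <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(#|track|browser)", lines)]
    if (!length(lines)) return(GRanges())
    f <- strsplit(lines, "[ \t]+")
    if (any(lengths(f) < 3))
        stop("BED line with fewer than 3 fields")
    chrom <- sub("^chr", "", vapply(f, `[`, "", 1))
    s <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
    e <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
    if (anyNA(s) || anyNA(e) || any(s < 0) || any(s >= e))
        stop("malformed BED interval (need 0 <= start < end)")
    GRanges(chrom, IRanges(s + 1, e))
}

#' Read a PED-style pedigree
#'
#' Whitespace-delimited columns family, individual, father, mother, sex
#' (1 = male, 2 = female), phenotype; "0" denotes a missing parent. Sexes
#' are cross-checked against a subject table when one is supplied.
#'
#' @param path path to the pedigree file
#' @param subjects optional subject data.frame with subject_id and sex
#' @return a DataFrame with subject_id, father_id, mother_id, sex
#' @export
readPedigree <- function(path, subjects = NULL) {
    df <- utils::read.table(path, colClasses = "character",
                            col.names = c("family", "subject_id", "father_id",
                                          "mother_id", "sex", "phenotype"))
    if (anyDuplicated(df$subject_id))
        stop("duplicated subject id in pedigree: ",
             df$subject_id[duplicated(df$subject_id)][1])
    out <- DataFrame(subject_id = df$subject_id,
                     father_id = ifelse(df$father_id == "0", NA_character_,
                                        df$father_id),
                     mother_id = ifelse(df$mother_id == "0", NA_character_,
                                        df$mother_id),
                     sex = c(`1` = "male", `2` = "female")[df$sex])
    if (!is.null(subjects)) {
        m <- match(out$subject_id, subjects$subject_id)
        known <- !is.na(m)
        if (any(known & !is.na(out$sex) &
                out$sex != subjects$sex[m], na.rm = TRUE))
            stop("pedigree sex codes conflict with the subject table")
    }
    out
}

#' Read a syndrome/candidate-region knowledge base
#'
#' Tab-delimited with columns \code{name}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive), \code{expected_dosage} (loss / gain /
#' either / upd_maternal / upd_paternal), \code{evidence}
#' (established_multi_report / single_report / candidate_gene),
#' \code{mechanism} (TRUE when a candidate gene carries a compelling
#' NDD-specific dosage mechanism), \code{syndrome} (TRUE for named
#' syndrome regions) and \code{genes} (comma-separated symbols). Entries may
#' overlap each other.
#'
#' @param path path to the TSV file
#' @return a GRanges with entry metadata, sorted as read
#' @export
readKnowledgeBase <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!nrow(df)) {
        warning("knowledge base is empty")
        return(GRanges())
    }
    need <- c("name", "chrom", "start", "end", "expected_dosage", "evidence")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("knowledge base lacks columns: ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(df$evidence), .EVIDENCE)
    if (length(bad))
        stop("unknown evidence level in knowledge base: ",
             paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$expected_dosage), .DOSAGES)
    if (length(bad))
        stop("unknown expected_dosage in knowledge base: ",
             paste(bad, collapse = ", "))
    gr <- GRanges(sub("^chr", "", df$chrom),
                  IRanges(as.numeric(df$start), as.numeric(df$end)))
    mcols(gr)$name <- df$name
    mcols(gr)$expected_dosage <- df$expected_dosage
    mcols(gr)$evidence <- df$evidence
    mcols(gr)$mechanism <- if (is.null(df$mechanism)) FALSE else
        as.logical(df$mechanism)
    mcols(gr)$syndrome <- if (is.null(df$syndrome)) FALSE else
        as.logical(df$syndrome)
    mcols(gr)$genes <- if (is.null(df$genes)) "" else df$genes
    gr
}

#' Load the packaged reference cohort
#'
#' A subject- and variant-level encoding of a clinical chromosomal-microarray reference cohort
#' of 410 NDD probands (151 ASD, 259 ID/DD of whom 8 are aneuploid), with
#' 129 clinically relevant CNVs/UPDs, the knowledge base they were
#' classified against, a pedigree and the parental calls supporting the
#' inherited variants. Genomic coordinates in the fixture are synthetic
#' placeholders laid out so that sizes match the reference values exactly;
#' variants whose individual sizes are known only as a group size range are
#' flagged \code{size_interpolated} and excluded from size statistics.
#'
#' Marginal counts are re-checked at every load; a failure signals fixture
#' corruption.
#'
#' @return an \linkS4class{NddCohort} with classification (\code{tier}),
#'   inheritance annotation and provenance on its variants
#' @examples
#' fx <- loadReferenceCohort()
#' fx
#' @export
loadReferenceCohort <- function() {
    dir <- system.file("extdata", package = "CNVtriage", mustWork = TRUE)
    subj <- utils::read.delim(file.path(dir, "fixture_subjects.tsv"),
                              stringsAsFactors = FALSE)
    vars <- readSegmentTable(file.path(dir, "fixture_variants.tsv"),
                             sexes = stats::setNames(subj$sex, subj$subject_id))
    an <- utils::read.delim(file.path(dir, "fixture_aneuploidies.tsv"),
                            stringsAsFactors = FALSE)
    kb <- readKnowledgeBase(file.path(dir, "fixture_kb.tsv"))
    ped <- readPedigree(file.path(dir, "fixture_pedigree.ped"),
                        subjects = subj)
    parents <- readSegmentTable(file.path(dir, "fixture_parent_calls.tsv"))
    m <- match(subj$subject_id, ped$subject_id)
    subj$father_id <- ped$father_id[m]
    subj$mother_id <- ped$mother_id[m]
    mcols(vars)$size_interpolated <-
        as.logical(mcols(vars)$size_interpolated)
    cohort <- nddCohort(subj, vars,
                        aneuploidies = an, parentCalls = parents,
                        knowledgeBase = kb)
    .checkFixtureInvariants(cohort)
    cohort
}

.checkFixtureInvariants <- function(cohort) {
    sub <- subjects(cohort)
    an <- aneuploidies(cohort)
    ok <- nrow(sub) == 410 &&
        nrow(an) == 8 &&
        sum(sub$group == "ASD") == 151 &&
        sum(sub$group == "ID_DD") == 259 &&
        sum(!sub$subject_id %in% an$subject_id) == 402 &&
        sum(sub$group == "ID_DD" & !sub$subject_id %in% an$subject_id) == 251 &&
        length(variants(cohort)) == 129
    if (!ok)
        stop("fixture corruption: packaged cohort fails its marginal-count ",
             "invariants (410 subjects = 151 ASD + 259 ID/DD, 8 aneuploid, ",
             "129 clinically relevant variants)")
    invisible(TRUE)
}
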