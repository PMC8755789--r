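#' Run the full triage pipeline
#'
#' Chains the stages in fixed order — load, rarity filter, classification,
#' trio inheritance, cohort statistics — and returns the cohort statistics
#' together with a run manifest (configuration snapshot, input digests,
#' package version, per-stage record counts). A failure in any stage aborts
#' with an error naming the stage. With \code{fixture = TRUE} the packaged
#' reference cohort replaces the file inputs (its variants are already
#' post-filter, so the rarity stage sees an empty panel).
#'
#' @param config named list (or path to a YAML file) with entries
#'   \code{segments}, \code{subjects}, \code{ped}, \code{parents},
#'   \code{panel}, \code{panel_n}, \code{reference}, \code{segdups},
#'   \code{kb} (file paths), \code{scope} ("strict"/"broad"),
#'   \code{include_aneuploidy}, \code{strata} (character vector), and
#'   optional FilterConfig overrides under \code{thresholds}
#' @param fixture use the packaged cohort instead of file inputs
#' @param out optional path for the JSON report; the manifest is written
#'   alongside as \code{<out>.manifest.json}
#' @return list(report, manifest, cohort) invisibly; report is also
#'   written when \code{out} is given
#' @export
runPipeline <- function(config = list(), fixture = FALSE, out = NULL) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    thr <- config$thresholds
    cfg <- do.call(filterConfig, if (is.null(thr)) list() else thr)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    digests <- list()
    if (fixture) {
        cohort <- stage("load", loadReferenceCohort())
        panel <- GRanges(); panelN <- cfg@controlPanelN
        reference <- NULL; segdups <- NULL
    } else {
        need <- c("segments", "subjects")
        miss <- setdiff(need, names(config))
        if (length(miss))
            stop("pipeline config lacks inputs: ",
                 paste(miss, collapse = ", "))
        for (f in intersect(names(config),
                            c("segments", "subjects", "ped", "parents",
                              "panel", "reference", "segdups", "kb"))) {
            if (!file.exists(config[[f]]))
                stop("input file for '", f, "' not found: ", config[[f]])
            digests[[f]] <- unname(tools::md5sum(config[[f]]))
        }
        cohort <- stage("load", {
            subj <- utils::read.delim(config$subjects,
                                      stringsAsFactors = FALSE)
            if (!is.null(config$ped)) {
                ped <- readPedigree(config$ped, subjects = subj)
                m <- match(subj$subject_id, ped$subject_id)
                subj$father_id <- ped$father_id[m]
                subj$mother_id <- ped$mother_id[m]
            }
            sexes <- stats::setNames(subj$sex, subj$subject_id)
            vars <- readSegmentTable(config$segments, sexes = sexes)
            an <- if (!is.null(subj$karyotype))
                data.frame(subject_id =
                               subj$subject_id[subj$karyotype != "normal"],
                           karyotype_label =
                               subj$karyotype[subj$karyotype != "normal"])
            else data.frame(subject_id = character(),
                            karyotype_label = character())
            nddCohort(subj, vars, aneuploidies = an,
                      parentCalls = if (!is.null(config$parents))
                          readSegmentTable(config$parents) else GRanges(),
                      knowledgeBase = if (!is.null(config$kb))
                          readKnowledgeBase(config$kb) else GRanges())
        })
        panel <- if (!is.null(config$panel))
            readSegmentTable(config$panel) else GRanges()
        panelN <- if (!is.null(config$panel_n)) config$panel_n
            else cfg@controlPanelN
        reference <- if (!is.null(config$reference)) {
            rf <- utils::read.delim(config$reference,
                                    stringsAsFactors = FALSE)
            cp <- ifelse(rf$type == "deletion", 1L, 3L)
            gr <- cnvCalls(rf$name, rf$chrom, rf$start, rf$end, rf$type,
                           cp, cp)
            mcols(gr)$freq <- rf$freq
            gr
        } else NULL
        segdups <- if (!is.null(config$segdups) &&
                       file.size(config$segdups) > 0)
            readBed(config$segdups) else NULL
    }
    counts <- list(input = length(variants(cohort)))
    rare <- stage("filter", selectRare(variants(cohort), panel, panelN,
                                       reference, segdups, cfg))
    counts$rare <- length(rare)
    rare <- stage("classify",
                  classifyVariants(rare, knowledgeBase(cohort), cfg))
    counts$classified <- length(rare)
    cohort@variants <- rare
    cohort <- stage("inherit", assignInheritance(cohort, cfg))
    counts$inherited <- length(variants(cohort))
    scope <- if (is.null(config$scope)) "strict" else config$scope
    strata <- config$strata
    incAn <- isTRUE(config$include_aneuploidy)
    report <- stage("stats", {
        list(yield = diagnosticYield(cohort, scope, incAn, strata),
             inheritance = {
                 s <- inheritanceSummary(cohort)
                 list(variants = as.data.frame(s$variants),
                      de_novo_subjects = sum(s$subjects$de_novo))
             },
             sizes = sizeSummary(cohort, strata = "group"))
    })
    manifest <- list(tool = "CNVtriage",
                     version = as.character(utils::packageVersion("CNVtriage")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     fixture = fixture,
                     config = config,
                     thresholds = list(min_size_bp = cfg@minSizeBp,
                                       min_markers = cfg@minMarkers,
                                       reciprocal_overlap = cfg@reciprocalOverlap,
                                       control_freq_max = cfg@controlFreqMax,
                                       reference_freq_max = cfg@referenceFreqMax,
                                       segdup_fraction_max = cfg@segdupFractionMax,
                                       control_panel_n = panelN,
                                       syndrome_coverage_min =
                                           cfg@syndromeCoverageMin,
                                       alpha = cfg@alpha),
                     input_digests = digests,
                     record_counts = counts)
    if (!is.null(out)) {
        jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE)
        jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(report = report, manifest = manifest, cohort = cohort))
}
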