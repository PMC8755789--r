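#' Parameters for the synthetic trio-cohort generator
#'
#' Defaults reproduce the structure of a clinical CMA cohort of 410 NDD
#' probands: 36.8\% ASD with a strong male excess (male fraction 0.841 in
#' ASD, 0.599 in ID/DD), about 1.45 background CNV calls per subject with
#' log-normal sizes (median 150 kb, sigma 1 on the log scale), a 1679-subject
#' control panel drawn from the same background model, group- and
#' sex-specific syndromic-event probabilities matching the observed strict
#' yields, group-specific de novo fractions, 2\% aneuploidy, rare UPDs in
#' ID/DD, and parental availability of 90.2\% (fathers) / 94.1\% (mothers).
#'
#' @param nSubjects cohort size
#' @param fractionASD fraction of subjects in the ASD group
#' @param maleFracASD,maleFracIDDD male fraction per group
#' @param benignRate expected background CNV calls per subject
#' @param benignSizeMedianBp,benignSizeSigma log-normal size model of
#'   background CNVs
#' @param nBenignLoci number of polymorphic background loci in the pool
#' @param panelN control-panel size in subjects
#' @param syndromicEventProb 2x2 matrix (rows ASD/ID_DD, cols male/female)
#'   of per-subject probabilities of carrying one established syndromic
#'   event
#' @param deNovoFraction named vector (ASD, ID_DD): probability that a
#'   simulated event is de novo rather than transmitted from a parent
#' @param vusEventProb named vector: per-subject probability of a
#'   candidate-gene (VUS) event
#' @param updProb named vector: per-subject probability of a UPD event
#' @param mosaicProb probability a syndromic CNV is mosaic
#' @param aneuploidyProb probability of whole-chromosome aneuploidy
#' @param missingFatherProb,missingMotherProb parental unavailability
#' @param seed mandatory integer master seed
#' @return a validated list of class \code{SimulationParams}
#' @export
simulationParams <- function(nSubjects = 410,
                             fractionASD = 151 / 410,
                             maleFracASD = 127 / 151,
                             maleFracIDDD = 155 / 259,
                             benignRate = 1.45,
                             benignSizeMedianBp = 150000,
                             benignSizeSigma = 1.0,
                             nBenignLoci = 200,
                             panelN = 1679,
                             syndromicEventProb =
                                 matrix(c(0.031, 0.042, 0.272, 0.375), 2,
                                        byrow = TRUE,
                                        dimnames = list(c("ASD", "ID_DD"),
                                                        c("male", "female"))),
                             deNovoFraction = c(ASD = 5 / 32, ID_DD = 65 / 97),
                             vusEventProb = c(ASD = 0.17, ID_DD = 0.012),
                             updProb = c(ASD = 0, ID_DD = 0.019),
                             mosaicProb = 0.03,
                             aneuploidyProb = 0.02,
                             missingFatherProb = 40 / 410,
                             missingMotherProb = 24 / 410,
                             seed = NULL) {
    if (is.null(seed))
        stop("a seed is mandatory for simulateCohort()")
    p <- list(nSubjects = nSubjects, fractionASD = fractionASD,
              maleFracASD = maleFracASD, maleFracIDDD = maleFracIDDD,
              benignRate = benignRate,
              benignSizeMedianBp = benignSizeMedianBp,
              benignSizeSigma = benignSizeSigma,
              nBenignLoci = nBenignLoci, panelN = panelN,
              syndromicEventProb = syndromicEventProb,
              deNovoFraction = deNovoFraction, vusEventProb = vusEventProb,
              updProb = updProb, mosaicProb = mosaicProb,
              aneuploidyProb = aneuploidyProb,
              missingFatherProb = missingFatherProb,
              missingMotherProb = missingMotherProb,
              seed = as.integer(seed))
    probs <- c(fractionASD, maleFracASD, maleFracIDDD,
               as.vector(syndromicEventProb), deNovoFraction, vusEventProb,
               updProb, mosaicProb, aneuploidyProb, missingFatherProb,
               missingMotherProb)
    if (any(probs < 0 | probs > 1) || anyNA(probs))
        stop("simulation probabilities must lie in [0, 1]")
    if (benignRate < 0 || nSubjects < 1 || panelN < 1)
        stop("rates and sizes must be non-negative / positive")
    class(p) <- "SimulationParams"
    p
}

## stable 31-bit string hash for per-subject RNG substreams: reproducible
## across sessions and independent of the number of subjects generated
.stableHash <- function(id, seed) {
    h <- as.double(seed %% 2147483647L)
    for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 2147483647
    as.integer(h)
}

## benign polymorphic locus pool shared by cohort and control panel;
## placed in a coordinate band (>= 200 Mb) disjoint from knowledge-base loci
.benignLoci <- function(p) {
    n <- p$nBenignLoci
    chrom <- sample(as.character(1:22), n, replace = TRUE)
    size <- round(stats::rlnorm(n, log(p$benignSizeMedianBp),
                                p$benignSizeSigma))
    start <- round(stats::runif(n, 4.0e8, 5.0e8))
    freq <- exp(stats::runif(n, log(0.002), log(0.20)))
    freq <- freq * p$benignRate / sum(freq)   # per-subject call rate
    data.frame(locus = paste0("bg", seq_len(n)), chrom = chrom,
               start = start, end = start + size - 1,
               type = sample(c("deletion", "duplication"), n, replace = TRUE),
               freq = pmin(freq, 0.5), stringsAsFactors = FALSE)
}

.drawBenign <- function(loci, id) {
    hit <- stats::runif(nrow(loci)) < loci$freq
    if (!any(hit)) return(NULL)
    l <- loci[hit, ]
    data.frame(subject_id = id, chrom = l$chrom, start = l$start,
               end = l$end, type = l$type,
               copy = ifelse(l$type == "deletion", 1L, 3L),
               locus = l$locus, stringsAsFactors = FALSE)
}

#' Simulate a trio cohort with truth labels
#'
#' Generates subjects, their CNV/UPD calls, parental calls, a control panel
#' and a reference-frequency set, all deterministic given
#' \code{params$seed}. Background CNVs come from a shared polymorphic locus
#' pool (so they are common in the panel and removed by the rarity filter);
#' syndromic, candidate-gene and UPD events are drawn from the supplied
#' knowledge base with dosage respected, and are absent from the panel.
#' Events are de novo with the group's de novo fraction, otherwise copied
#' into one parent; calls whose carrier parent is unavailable are labelled
#' with intended inheritance "unknown".
#'
#' @param params a \code{SimulationParams} list (see [simulationParams()])
#' @param kb knowledge base GRanges; defaults to the packaged reference KB
#' @return list with elements \code{cohort} (an \linkS4class{NddCohort}),
#'   \code{panel} (GRanges), \code{panelN}, \code{reference} (GRanges with
#'   \code{freq}), \code{truth} (DataFrame of intended tier and inheritance
#'   per simulated clinically relevant event) and \code{params}
#' @examples
#' sim <- simulateCohort(simulationParams(nSubjects = 50, seed = 1))
#' sim$cohort
#' @export
simulateCohort <- function(params, kb = NULL) {
    stopifnot(inherits(params, "SimulationParams"))
    if (is.null(kb))
        kb <- readKnowledgeBase(system.file("extdata", "fixture_kb.tsv",
                                            package = "CNVtriage",
                                            mustWork = TRUE))
    p <- params
    set.seed(p$seed)
    loci <- .benignLoci(p)
    est <- kb[mcols(kb)$evidence == "established_multi_report" &
              mcols(kb)$expected_dosage %in% c("loss", "gain")]
    cand <- kb[mcols(kb)$evidence == "candidate_gene" & !mcols(kb)$mechanism]
    updEntries <- kb[mcols(kb)$expected_dosage %in%
                     c("upd_maternal", "upd_paternal")]
    ids <- sprintf("SIM%05d", seq_len(p$nSubjects))
    subjRows <- vector("list", p$nSubjects)
    callRows <- list(); parentRows <- list(); truthRows <- list()
    anRows <- list()
    mkEvent <- function(id, entry, type, sex, mosaic = FALSE) {
        pad <- round(0.1 * width(entry)) + 10000
        st <- max(1, start(entry) - pad)
        en <- end(entry) + pad
        copyLow <- copyHigh <- NA_integer_
        poo <- NA_character_
        base <- if (as.character(seqnames(entry)) %in% c("X", "Y") &&
                    sex == "male") 1L else 2L
        if (type == "deletion") {
            copyLow <- base - 1L; copyHigh <- base - 1L + mosaic
        }
        if (type == "duplication") {
            copyLow <- base + 1L; copyHigh <- base + 1L + mosaic
        }
        if (type == "UPD")
            poo <- if (mcols(entry)$expected_dosage == "upd_maternal")
                "maternal" else "paternal"
        data.frame(subject_id = id, chrom = as.character(seqnames(entry)),
                   start = st, end = en, type = type,
                   copy_low = copyLow, copy_high = copyHigh,
                   parent_of_origin = poo,
                   source_entry = mcols(entry)$name, stringsAsFactors = FALSE)
    }
    for (i in seq_len(p$nSubjects)) {
        id <- ids[i]
        set.seed(.stableHash(id, p$seed))
        grp <- if (stats::runif(1) < p$fractionASD) "ASD" else "ID_DD"
        maleFrac <- if (grp == "ASD") p$maleFracASD else p$maleFracIDDD
        sex <- if (stats::runif(1) < maleFrac) "male" else "female"
        age <- if (grp == "ASD") round(stats::runif(1, 22, 98)) else
            round(stats::runif(1, 0, 123))
        fatherAway <- stats::runif(1) < p$missingFatherProb
        motherAway <- stats::runif(1) < p$missingMotherProb
        fid <- if (fatherAway) NA_character_ else paste0(id, "_F")
        mid <- if (motherAway) NA_character_ else paste0(id, "_M")
        aneu <- stats::runif(1) < p$aneuploidyProb
        kary <- "normal"
        if (aneu) {
            kary <- if (sex == "male" && stats::runif(1) < 0.25)
                sample(c("47,XXY", "47,XYY"), 1) else "trisomy 21"
            anRows[[length(anRows) + 1L]] <-
                data.frame(subject_id = id, karyotype_label = kary,
                           stringsAsFactors = FALSE)
        }
        subjRows[[i]] <- data.frame(subject_id = id, sex = sex,
                                    age_months = age, group = grp,
                                    father_id = fid, mother_id = mid,
                                    karyotype = kary, stringsAsFactors = FALSE)
        if (aneu) next
        addEvent <- function(ev, deNovo) {
            intended <- "de_novo"
            if (ev$type == "UPD") {
                ## parent of origin is an input annotation, nothing to copy
                callRows[[length(callRows) + 1L]] <<- ev
                return(ev$parent_of_origin)
            }
            if (!deNovo) {
                toFather <- stats::runif(1) < 0.5
                pid <- if (toFather) fid else mid
                intended <- if (toFather) "paternal" else "maternal"
                if (is.na(pid)) intended <- "unknown"
                else {
                    pr <- ev; pr$subject_id <- pid
                    parentRows[[length(parentRows) + 1L]] <<- pr
                }
            } else if (fatherAway || motherAway) intended <- "unknown"
            callRows[[length(callRows) + 1L]] <<- ev
            intended
        }
        ## background CNVs (common; expected to be filtered out)
        bg <- .drawBenign(loci, id)
        if (!is.null(bg)) {
            for (k in seq_len(nrow(bg))) {
                ev <- data.frame(subject_id = id, chrom = bg$chrom[k],
                                 start = bg$start[k], end = bg$end[k],
                                 type = bg$type[k], copy_low = bg$copy[k],
                                 copy_high = bg$copy[k],
                                 parent_of_origin = NA_character_,
                                 source_entry = bg$locus[k],
                                 stringsAsFactors = FALSE)
                addEvent(ev, deNovo = stats::runif(1) <
                             p$deNovoFraction[[grp]])
            }
        }
        ## syndromic event
        if (length(est) && stats::runif(1) < p$syndromicEventProb[grp, sex]) {
            entry <- est[sample(length(est), 1)]
            type <- if (mcols(entry)$expected_dosage == "loss") "deletion"
                else "duplication"
            ev <- mkEvent(id, entry, type, sex,
                          mosaic = stats::runif(1) < p$mosaicProb)
            intended <- addEvent(ev, deNovo = stats::runif(1) <
                                     p$deNovoFraction[[grp]])
            truthRows[[length(truthRows) + 1L]] <-
                data.frame(subject_id = id, source_entry = ev$source_entry,
                           intended_tier = "pathogenic",
                           intended_inheritance = intended,
                           stringsAsFactors = FALSE)
        }
        ## candidate-gene (VUS) event
        if (length(cand) && stats::runif(1) < p$vusEventProb[[grp]]) {
            entry <- cand[sample(length(cand), 1)]
            type <- switch(mcols(entry)$expected_dosage,
                           loss = "deletion", gain = "duplication",
                           sample(c("deletion", "duplication"), 1))
            ev <- mkEvent(id, entry, type, sex)
            intended <- addEvent(ev, deNovo = stats::runif(1) <
                                     p$deNovoFraction[[grp]])
            truthRows[[length(truthRows) + 1L]] <-
                data.frame(subject_id = id, source_entry = ev$source_entry,
                           intended_tier = "VUS",
                           intended_inheritance = intended,
                           stringsAsFactors = FALSE)
        }
        ## UPD event
        if (length(updEntries) && stats::runif(1) < p$updProb[[grp]]) {
            entry <- updEntries[sample(length(updEntries), 1)]
            ev <- mkEvent(id, entry, "UPD", sex)
            intended <- addEvent(ev, deNovo = FALSE)
            truthRows[[length(truthRows) + 1L]] <-
                data.frame(subject_id = id, source_entry = ev$source_entry,
                           intended_tier = "pathogenic",
                           intended_inheritance = ev$parent_of_origin,
                           stringsAsFactors = FALSE)
        }
    }
    ## control panel: same background pool, no syndromic events
    set.seed(.stableHash("control_panel", p$seed))
    panelRows <- list()
    for (j in seq_len(p$panelN)) {
        bg <- .drawBenign(loci, sprintf("CTRL%05d", j))
        if (!is.null(bg)) panelRows[[length(panelRows) + 1L]] <- bg
    }
    toCalls <- function(rows, withCopy = TRUE) {
        if (!length(rows)) return(cnvCalls(character(), character(),
                                           numeric(), numeric(), character()))
        df <- do.call(rbind, rows)
        cl <- if (withCopy) df$copy_low else df$copy
        ch <- if (withCopy) df$copy_high else df$copy
        gr <- cnvCalls(df$subject_id, df$chrom, df$start, df$end, df$type,
                       cl, ch,
                       marker_count = pmax(20L, as.integer(
                           (df$end - df$start + 1) %/% 2000)),
                       parent_of_origin = if (withCopy) df$parent_of_origin
                           else NA_character_)
        if (!is.null(df$source_entry))
            mcols(gr)$source_entry <- df$source_entry
        gr
    }
    subj <- do.call(rbind, subjRows)
    cohort <- nddCohort(subj, toCalls(callRows),
                        aneuploidies = if (length(anRows))
                            do.call(rbind, anRows) else
                            data.frame(subject_id = character(),
                                       karyotype_label = character()),
                        parentCalls = toCalls(parentRows),
                        knowledgeBase = kb)
    reference <- GRanges(loci$chrom, IRanges(loci$start, loci$end))
    mcols(reference)$subject_id <- loci$locus
    mcols(reference)$type <- loci$type
    mcols(reference)$freq <- loci$freq
    list(cohort = cohort, panel = toCalls(panelRows, withCopy = FALSE),
         panelN = p$panelN, reference = reference,
         truth = if (length(truthRows)) DataFrame(do.call(rbind, truthRows))
             else DataFrame(subject_id = character(),
                            source_entry = character(),
                            intended_tier = character(),
                            intended_inheritance = character()),
         params = p)
}

#' Write a simulated cohort to the pipeline's file formats
#'
#' Emits segments.tsv, parents.tsv, panel.tsv, reference.tsv, subjects.tsv,
#' trios.ped, kb.tsv and segdups.bed in a directory so a simulated run can
#' be consumed by the file-based pipeline entry points.
#'
#' @param sim result of [simulateCohort()]
#' @param dir output directory (created if needed)
#' @return dir, invisibly
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cohort <- sim$cohort
    writeSegmentTable(variants(cohort), file.path(dir, "segments.tsv"))
    writeSegmentTable(parentCalls(cohort), file.path(dir, "parents.tsv"))
    writeSegmentTable(sim$panel, file.path(dir, "panel.tsv"))
    ref <- sim$reference
    utils::write.table(
        data.frame(name = mcols(ref)$subject_id,
                   chrom = as.character(seqnames(ref)),
                   start = start(ref), end = end(ref),
                   type = mcols(ref)$type, freq = mcols(ref)$freq),
        file.path(dir, "reference.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    sub <- as.data.frame(subjects(cohort))
    utils::write.table(sub[c("subject_id", "sex", "age_months", "group",
                             "karyotype")],
                       file.path(dir, "subjects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ped <- data.frame(family = sub$subject_id, id = sub$subject_id,
                      father = ifelse(is.na(sub$father_id), "0",
                                      sub$father_id),
                      mother = ifelse(is.na(sub$mother_id), "0",
                                      sub$mother_id),
                      sex = ifelse(sub$sex == "male", 1, 2), phenotype = 2)
    utils::write.table(ped, file.path(dir, "trios.ped"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    kb <- knowledgeBase(cohort)
    utils::write.table(
        data.frame(name = mcols(kb)$name, chrom = as.character(seqnames(kb)),
                   start = start(kb), end = end(kb),
                   expected_dosage = mcols(kb)$expected_dosage,
                   evidence = mcols(kb)$evidence,
                   mechanism = mcols(kb)$mechanism,
                   syndrome = mcols(kb)$syndrome, genes = mcols(kb)$genes),
        file.path(dir, "kb.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeLines(character(), file.path(dir, "segdups.bed"))
    invisible(dir)
}

#' Run the pipeline on a simulated cohort and compare against truth
#'
#' Executes the full funnel (rarity filter against the simulated panel and
#' reference set, classification against the knowledge base, trio
#' inheritance) and reports a confusion matrix of intended vs assigned tier
#' for the truth-labelled events, the tier and inheritance recovery rates,
#' and the pipeline-estimated strict diagnostic yield and de novo fraction
#' among pathogenic/likely pathogenic variants.
#'
#' @param sim result of [simulateCohort()]
#' @param cfg a \linkS4class{FilterConfig}
#' @return list(confusion, tier_recovery, inheritance_recovery,
#'   strict_yield, de_novo_fraction, cohort)
#' @export
recoverParameters <- function(sim, cfg = filterConfig()) {
    cohort <- sim$cohort
    rare <- selectRare(variants(cohort), sim$panel, sim$panelN,
                       sim$reference, segdups = NULL, cfg = cfg)
    rare <- classifyVariants(rare, knowledgeBase(cohort), cfg)
    cohort@variants <- rare
    cohort <- assignInheritance(cohort, cfg)
    v <- variants(cohort)
    truth <- sim$truth
    key <- paste(mcols(v)$subject_id, mcols(v)$source_entry)
    tkey <- paste(truth$subject_id, truth$source_entry)
    m <- match(tkey, key)
    assignedTier <- ifelse(is.na(m), "filtered", mcols(v)$tier[m])
    assignedInh <- ifelse(is.na(m), NA, mcols(v)$inheritance[m])
    confusion <- table(intended = truth$intended_tier,
                       assigned = assignedTier)
    tierRec <- if (nrow(truth)) mean(assignedTier == truth$intended_tier)
        else NA_real_
    inhRec <- if (nrow(truth)) mean(assignedInh == truth$intended_inheritance,
                                    na.rm = TRUE) else NA_real_
    cls <- classifySubjects(cohort)
    cls <- cls[!cls$aneuploid, ]
    strictYield <- mean(cls$diagnosed_strict)
    ## de novo fraction estimated on complete trios only: with a missing
    ## parent the pipeline can never return de_novo, so incomplete trios
    ## would bias the estimate downward
    sub <- subjects(cohort)
    complete <- sub$subject_id[!is.na(sub$father_id) & !is.na(sub$mother_id)]
    plp <- v[mcols(v)$tier %in% c("pathogenic", "likely_pathogenic") &
             mcols(v)$type != "UPD" & mcols(v)$subject_id %in% complete]
    dnFrac <- if (length(plp))
        mean(mcols(plp)$inheritance == "de_novo") else NA_real_
    list(confusion = confusion, tier_recovery = tierRec,
         inheritance_recovery = inhRec, strict_yield = strictYield,
         n_subjects = nrow(cls), de_novo_fraction = dnFrac,
         n_plp_complete_trios = length(plp), cohort = cohort)
}
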