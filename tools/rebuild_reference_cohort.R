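#!/usr/bin/env Rscript
## Deterministic builder for the packaged reference-cohort files
## (inst/extdata/fixture_*). Pure base R; run from the repo root:
##   Rscript tools/rebuild_reference_cohort.R
## Encodes the published subject/variant-level cohort structure with
## synthetic placeholder coordinates (sizes exact). Heavily asserted.

stopifnot(file.exists("DESCRIPTION"))
outdir <- "inst/extdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
A <- function(cond, what) if (!isTRUE(cond)) stop("ASSERT FAILED: ", what)

## ---------------------------------------------------------------- KB loci
## locus registry: key, chrom, expected_dosage, evidence, mechanism,
## syndrome flag, optional manual entry coords
L <- list()
reg <- function(key, chrom, dosage, evidence = "established_multi_report",
                mech = FALSE, synd = TRUE, genes = "",
                mstart = NA, mend = NA) {
    L[[key]] <<- list(key = key, chrom = chrom, dosage = dosage,
                      evidence = evidence, mech = mech, synd = synd,
                      genes = genes, mstart = mstart, mend = mend)
}

## ID/DD syndrome critical regions
reg("1p36_deletion", "1", "loss")
reg("1q21.1_microduplication", "1", "gain")
reg("2q37_microdeletion", "2", "loss")
reg("Wolf-Hirschhorn", "4", "loss")
reg("Cri-du-chat", "5", "loss")
reg("5q_trisomy", "5", "gain")
reg("Sotos", "5", "loss")
reg("Silver-Russell_UPD7", "7", "upd_maternal", mstart = 1.5e6, mend = 3e6)
reg("Williams-Beuren", "7", "loss", genes = "ELN")
reg("Waardenburg_8p23", "8", "loss")
reg("Branchio-Otorenal", "8", "loss")
reg("9p_partial_monosomy", "9", "loss")
reg("9p_partial_trisomy", "9", "gain", mstart = 5e6, mend = 15e6)
reg("10p_partial_deletion", "10", "loss")
reg("10p15.3_deletion", "10", "loss")
reg("Distal_trisomy_10q", "10", "gain")
reg("10qter_deletion", "10", "loss")
reg("15q11q13_deletion_PWS_AS", "15", "loss", genes = "SNRPN,UBE3A",
    mstart = 24.0e6, mend = 28.8e6)
reg("Prader-Willi_UPD15", "15", "upd_maternal", mstart = 24.0e6, mend = 26e6)
reg("Angelman_UPD15", "15", "upd_paternal", mstart = 24.0e6, mend = 26e6)
reg("15q11q13_duplication", "15", "gain", mstart = 24.0e6, mend = 28.8e6)
reg("15q13.3_duplication", "15", "gain", mstart = 31.2e6, mend = 31.9e6)
reg("15q26_deletion", "15", "loss")
reg("16p11.2_microduplication", "16", "gain")
reg("16_partial_trisomy", "16", "gain")
reg("17_partial_trisomy", "17", "gain")
reg("18q_deletion", "18", "loss")
reg("18q_duplication", "18", "gain")
reg("22q11.2_duplication_proximal", "22", "gain",
    mstart = 17.5e6, mend = 19.3e6)
reg("22q11.2_duplication_distal", "22", "gain", mstart = 20e6, mend = 21e6)
reg("22q11.2_deletion", "22", "loss", genes = "TBX1",
    mstart = 17.5e6, mend = 19.3e6)
reg("MECP2_duplication", "X", "gain", genes = "MECP2",
    mstart = 153.2e6, mend = 153.5e6)
reg("Temple_UPD14", "14", "upd_maternal")
## ASD syndrome regions
reg("AUTS2_syndrome", "7", "loss", genes = "AUTS2")
reg("Kleefstra", "9", "loss", genes = "EHMT1")
reg("15q24_microdeletion", "15", "loss")
## other established (non-named-syndrome) regions
oth <- list(c("1q25.1q31.1_del", "1", "loss"), c("2p16.1p12_del", "2", "loss"),
    c("2p21p13.2_dup", "2", "gain"), c("2p25.3p25.2_dup", "2", "gain"),
    c("3p14.1p11.1_dup", "3", "gain"), c("4p16.3p16.1_dup", "4", "gain"),
    c("4p16.3_del", "4", "loss"), c("4q31.3q35.2_dup", "4", "gain"),
    c("4q34.14q35.2_dup", "4", "gain"), c("6q23.3q24.2_del", "6", "loss"),
    c("8p23.3p22_del", "8", "loss"), c("13q21.1q32.2_del", "13", "loss"),
    c("14q11.2q21.2_dup", "14", "gain"), c("14q32.12p32.33_dup", "14", "gain"),
    c("15q26.2q26.3_del", "15", "loss"), c("16q24.2q24.3_dup", "16", "gain"),
    c("18p11.32p11.31_del", "18", "loss"), c("18p11.32p11.21_del", "18", "loss"),
    c("18q21.32q23_dup", "18", "gain"), c("19p13.3p13.2_dup", "19", "gain"),
    c("20p13p12.3_del", "20", "loss"), c("21q22.11q22.3_del", "21", "loss"),
    c("22q13.31q13.33_dup", "22", "gain"), c("Xq22.3q27.1_dup", "X", "gain"))
for (o in oth) reg(o[1], o[2], o[3], synd = FALSE)
## three of the "other" established regions correspond to named
## chromosomal syndromes (15q26 deletion, 18p deletion, 18q duplication
## spectra): flagged so the de novo syndromic tally closes at 53/70
for (k in c("15q26.2q26.3_del", "18p11.32p11.31_del", "18q21.32q23_dup"))
    L[[k]]$synd <- TRUE
## single-report regions (likely pathogenic)
reg("CADM2_3p12.2p11.1_del", "3", "loss", "single_report", synd = FALSE,
    genes = "CADM2,CHMP2B,POU1F1,CGGBP1")
reg("2q13_del", "2", "loss", "single_report", synd = FALSE)
reg("7q11.22q21.11_del", "7", "loss", "single_report", synd = FALSE)
reg("19p13.2_del", "19", "loss", "single_report", synd = FALSE)
reg("20p13_del", "20", "loss", "single_report", synd = FALSE)
## candidate-gene entries (ASD VUS genes + ID/DD VUS regions)
cand <- list(c("CTNNA2", "2"), c("DPP10", "2"), c("CNTNAP5", "2"),
    c("TRIP12", "2"), c("GRM7", "3"), c("RSRC1", "3"), c("PIGG", "4"),
    c("ARHGEF38", "4"), c("KHDRBS2", "6"), c("AHI1", "6"), c("PARK2", "6"),
    c("SDK1", "7"), c("GRM8", "7"), c("CTNNA3", "10"), c("LRRC4C", "11"),
    c("APBA2", "15"), c("CHRNA7", "15"), c("RBFOX1", "16"), c("GRIN2A", "16"),
    c("LAMA1", "18"), c("MIB1", "18"), c("PTPRT", "20"), c("AIFM3", "22"),
    c("IGBP1", "X"), c("SMS", "X"))
for (cg in cand) reg(cg[1], cg[2], "either", "candidate_gene", synd = FALSE,
                     genes = cg[1])
reg("16p13.11_microduplication", "16", "gain", "candidate_gene", synd = FALSE)
reg("4p16.2p16.1_dup_VUS", "4", "gain", "candidate_gene", synd = FALSE)
reg("21q22.3_dup_VUS", "21", "gain", "candidate_gene", synd = FALSE)

## ------------------------------------------------------------- variants
## vid, locus, type, copy, size_kb (NA when real coords), start, end, inh,
## tier, interp, prov; subject assignment comes later
vr <- list()
addv <- function(vid, locus, type, copy, size_kb, inh, tier, prov,
                 interp = FALSE, start = NA, end = NA) {
    vr[[vid]] <<- data.frame(vid = vid, locus = locus, type = type,
                             copy = copy, size_kb = size_kb, start = start,
                             end = end, inh = inh, tier = tier,
                             interp = interp, prov = prov,
                             stringsAsFactors = FALSE)
}
P <- "pathogenic"; LP <- "likely_pathogenic"; VU <- "VUS"
DN <- "de_novo"; MA <- "maternal"; PA <- "paternal"; UN <- "unknown"

## --- ID/DD variants at named syndrome regions
addv("r01", "1p36_deletion", "deletion", "1", 4515, DN, P, "iddd:1p36")
addv("r02", "1p36_deletion", "deletion", "1", 7908, DN, P, "iddd:1p36")
addv("r03", "1q21.1_microduplication", "duplication", "3", 1626, MA, P, "iddd:1q21.1dup")
addv("r04", "2q37_microdeletion", "deletion", "1", 3656, DN, P, "iddd:2q37")
addv("r05", "2q37_microdeletion", "deletion", "1", 3973, DN, P, "iddd:2q37")
addv("r06", "Wolf-Hirschhorn", "deletion", "1", 5868, DN, P, "iddd:WHS")
addv("r07", "Cri-du-chat", "deletion", "1", 7595, DN, P, "iddd:CdC")
addv("r08", "Cri-du-chat", "deletion", "1", 16576, DN, P, "iddd:CdC")
addv("r09", "5q_trisomy", "duplication", "3", 15248, DN, P, "iddd:5qtri")
addv("r10", "Sotos", "deletion", "1", 1911, DN, P, "iddd:Sotos")
addv("r11", "Silver-Russell_UPD7", "UPD", "", 95119, MA, P, "iddd:SRS-UPD")
wbs_sizes <- round(seq(1424, 1570, length.out = 11))
for (i in 1:11)
    addv(sprintf("r%02d", 11 + i), "Williams-Beuren", "deletion", "1",
         wbs_sizes[i], DN, P, "iddd:WBS", interp = i %in% 2:10)
addv("r23", "Waardenburg_8p23", "deletion", "1", 9905, DN, P, "iddd:Waardenburg")
addv("r24", "Waardenburg_8p23", "deletion", "1", 6841, UN, P, "iddd:Waardenburg")
addv("r25", "Waardenburg_8p23", "deletion", "1", 8373, UN, P,
     "iddd:Waardenburg", interp = TRUE)
addv("r26", "Branchio-Otorenal", "deletion", "1", 10009, DN, P, "iddd:BOR")
addv("r27", "9p_partial_monosomy", "deletion", "1", 10487, DN, P, "iddd:9pmono")
tri9 <- round(seq(29995, 74596, length.out = 4))
addv("r28", "9p_partial_trisomy", "duplication", "3", tri9[1], DN, P, "iddd:9ptri")
addv("r29", "9p_partial_trisomy", "duplication", "3", tri9[2], DN, P,
     "iddd:9ptri", interp = TRUE)
addv("r30", "9p_partial_trisomy", "duplication", "3", tri9[3], DN, P,
     "iddd:9ptri", interp = TRUE)
addv("r31", "9p_partial_trisomy", "duplication", "3", tri9[4], DN, P, "iddd:9ptri")
addv("r32", "9p_partial_trisomy", "duplication", "3-4", NA, DN, P,
     "iddd:9ptri-footnote-a", start = 203861, end = 38787479)
addv("r33", "10p_partial_deletion", "deletion", "1", 11049, DN, P, "iddd:10p")
addv("r34", "10p15.3_deletion", "deletion", "1", 3472, DN, P, "iddd:10p15.3")
addv("r35", "Distal_trisomy_10q", "duplication", "3", 35938, DN, P, "iddd:10qtri")
addv("r36", "10qter_deletion", "deletion", "1", 5640, DN, P, "iddd:10qter")
addv("r37", "15q11q13_deletion_PWS_AS", "deletion", "1", 5259, PA, P, "iddd:PWSdel")
addv("r38", "15q11q13_deletion_PWS_AS", "deletion", "1", 6261, PA, P, "iddd:PWSdel")
addv("r39", "Prader-Willi_UPD15", "UPD", "", 79659, MA, P, "iddd:PWS-UPD")
addv("r40", "Prader-Willi_UPD15", "UPD", "", 79677, MA, P, "iddd:PWS-UPD")
addv("r41", "15q11q13_deletion_PWS_AS", "deletion", "1", 5239, MA, P, "iddd:ASdel")
addv("r42", "Angelman_UPD15", "UPD", "", 25942, PA, P, "iddd:AS-UPD")
addv("r43", "15q11q13_duplication", "duplication", "3", 4929, DN, P, "iddd:15qdup")
addv("r44", "15q11q13_duplication", "duplication", "3", 7302, DN, P,
     "iddd:15qdup", interp = TRUE)
addv("r45", "15q11q13_duplication", "duplication", "4", 9674, DN, P, "iddd:15qdup")
addv("r46", "15q11q13_duplication", "duplication", "4", NA, UN, P,
     "iddd:15qdup-footnote-b", start = 22770421, end = 31073668)
addv("r47", "15q13.3_duplication", "duplication", "3", NA, UN, P,
     "iddd:15qdup-footnote-b", start = 31073668, end = 32011459)
addv("r48", "15q26_deletion", "deletion", "1", 3134, UN, P, "iddd:15q26del")
addv("r49", "16p13.11_microduplication", "duplication", "3", 1429, MA, VU,
     "iddd:16p13.11dup")
addv("r50", "16p11.2_microduplication", "duplication", "3", 586, DN, P,
     "iddd:16p11.2dup")
addv("r51", "16p11.2_microduplication", "duplication", "3", 826, UN, P,
     "iddd:16p11.2dup")
addv("r52", "16_partial_trisomy", "duplication", "3", 19668, DN, P, "iddd:16tri")
addv("r53", "17_partial_trisomy", "duplication", "3", 5701, DN, P, "iddd:17tri")
del18 <- round(seq(3042, 77943, length.out = 4))
addv("r54", "18q_deletion", "deletion", "1", del18[1], DN, P, "iddd:18qdel")
addv("r55", "18q_deletion", "deletion", "1-2", del18[2], DN, P,
     "iddd:18qdel-mosaic", interp = TRUE)
addv("r56", "18q_deletion", "deletion", "1", del18[3], DN, P,
     "iddd:18qdel", interp = TRUE)
addv("r57", "18q_deletion", "deletion", "1", del18[4], UN, P, "iddd:18qdel")
addv("r58", "18q_duplication", "duplication", "3", 77943, DN, P, "iddd:18qdup")
addv("r59", "22q11.2_duplication_proximal", "duplication", "4", NA, DN, P,
     "iddd:22q11dup-footnote-c", start = 16888899, end = 19781868)
addv("r60", "22q11.2_duplication_distal", "duplication", "3", NA, DN, P,
     "iddd:22q11dup-footnote-c", start = 19783504, end = 21465659)
del22 <- c(2549, 2716, 2884)
addv("r61", "22q11.2_deletion", "deletion", "1", del22[1], DN, P, "iddd:22q11del")
addv("r62", "22q11.2_deletion", "deletion", "1", del22[2], DN, P,
     "iddd:22q11del", interp = TRUE)
addv("r63", "22q11.2_deletion", "deletion", "1", del22[3], DN, P, "iddd:22q11del")
addv("r64", "MECP2_duplication", "duplication", "2", 377, MA, P, "iddd:MECP2dup")
addv("r65", "MECP2_duplication", "duplication", "3", 424, PA, P, "iddd:MECP2dup")
## --- ID/DD variants at other clinically relevant loci
addv("r66", "1q25.1q31.1_del", "deletion", "1", 12292, DN, P, "iddd:other")
addv("r67", "2p16.1p12_del", "deletion", "1", 16664, UN, P, "iddd:other")
addv("r68", "2p21p13.2_dup", "duplication", "3", 28560, DN, P, "iddd:other")
addv("r69", "2p25.3p25.2_dup", "duplication", "3", 6544, UN, P, "iddd:other")
addv("r70", "2q13_del", "deletion", "1", 1734, DN, LP, "iddd:other")
addv("r71", "3p14.1p11.1_dup", "duplication", "3", 21577, DN, P, "iddd:other")
addv("r72", "4p16.3p16.1_dup", "duplication", "3", 9452, UN, P, "iddd:other")
addv("r73", "4p16.3_del", "deletion", "1", 1195, UN, P, "iddd:other")
addv("r74", "4p16.2p16.1_dup_VUS", "duplication", "3", 493, DN, VU, "iddd:other")
addv("r75", "4q31.3q35.2_dup", "duplication", "3", 38587, UN, P, "iddd:other")
addv("r76", "4q34.14q35.2_dup", "duplication", "3", 18897, DN, P, "iddd:other")
addv("r77", "6q23.3q24.2_del", "deletion", "1", 7405, UN, P, "iddd:other")
addv("r78", "7q11.22q21.11_del", "deletion", "1", 17988, DN, LP, "iddd:other")
addv("r79", "8p23.3p22_del", "deletion", "1", 17300, DN, P, "iddd:other")
addv("r80", "13q21.1q32.2_del", "deletion", "1", 39073, DN, P, "iddd:other")
addv("r81", "14q11.2q21.2_dup", "duplication", "3", 23595, UN, P, "iddd:other")
addv("r82", "Temple_UPD14", "UPD", "", 86774, MA, P, "iddd:14qUPD")
addv("r83", "14q32.12p32.33_dup", "duplication", "3", 11616, UN, P, "iddd:other")
addv("r84", "15q26.2q26.3_del", "deletion", "1", 3006, DN, P, "iddd:other")
addv("r85", "16q24.2q24.3_dup", "duplication", "3", 2671, UN, P, "iddd:other")
addv("r86", "18p11.32p11.31_del", "deletion", "1", 5987, DN, P, "iddd:other")
addv("r87", "18p11.32p11.21_del", "deletion", "1", 13649, DN, P, "iddd:other")
addv("r88", "18q21.32q23_dup", "duplication", "3", 19416, DN, P, "iddd:other")
addv("r89", "19p13.2_del", "deletion", "1", 2260, DN, LP, "iddd:other")
addv("r90", "19p13.3p13.2_dup", "duplication", "3", 7327, DN, P, "iddd:other")
addv("r91", "20p13_del", "deletion", "1", 978, DN, LP, "iddd:other")
addv("r92", "20p13p12.3_del", "deletion", "1", 9844, UN, P, "iddd:other")
addv("r93", "21q22.11q22.3_del", "deletion", "1", 13055, DN, P, "iddd:other")
addv("r94", "21q22.3_dup_VUS", "duplication", "3", 2858, DN, VU, "iddd:other")
addv("r95", "22q13.31q13.33_dup", "duplication", "3", 5648, UN, P, "iddd:other")
addv("r96", "22q13.31q13.33_dup", "duplication", "3", 5648, UN, P, "iddd:other")
addv("r97", "Xq22.3q27.1_dup", "duplication", "3", 32324, UN, P, "iddd:other")

## --- ASD variants
addv("a01", "CADM2_3p12.2p11.1_del", "deletion", "1", 8418, DN, LP, "asd:CADM2")
addv("a02", "AUTS2_syndrome", "deletion", "1", 830, DN, P, "asd:AUTS2")
addv("a03", "Kleefstra", "deletion", "1", 801, DN, P, "asd:EHMT1")
addv("a04", "15q24_microdeletion", "deletion", "1", 2581, DN, P, "asd:15q24")
addv("a05", "MECP2_duplication", "duplication", "2", 408, MA, P, "asd:MECP2")
asd_vus <- list(
    c("a06", "CTNNA2", "duplication", 1197, PA), c("a07", "DPP10", "duplication", 141, PA),
    c("a08", "CNTNAP5", "duplication", 477, MA), c("a09", "TRIP12", "duplication", 115, MA),
    c("a10", "GRM7", "deletion", 303, DN), c("a11", "GRM7", "deletion", 1174, MA),
    c("a12", "RSRC1", "deletion", 435, PA), c("a13", "PIGG", "deletion", 159, PA),
    c("a14", "ARHGEF38", "duplication", 162, PA), c("a15", "KHDRBS2", "duplication", 699, PA),
    c("a16", "AHI1", "duplication", 103, PA), c("a17", "PARK2", "deletion", 76, PA),
    c("a18", "PARK2", "deletion", 174, PA), c("a19", "SDK1", "duplication", 119, UN),
    c("a20", "GRM8", "duplication", 56, PA), c("a21", "CTNNA3", "deletion", 74, MA),
    c("a22", "LRRC4C", "duplication", 208, PA), c("a23", "APBA2", "duplication", 1715, PA),
    c("a24", "CHRNA7", "duplication", 435, PA), c("a25", "RBFOX1", "deletion", 294, PA),
    c("a26", "GRIN2A", "duplication", 452, PA), c("a27", "LAMA1", "duplication", 517, UN),
    c("a28", "MIB1", "deletion", 122, MA), c("a29", "PTPRT", "deletion", 77, MA),
    c("a30", "AIFM3", "duplication", 412, PA), c("a31", "IGBP1", "duplication", 401, MA),
    c("a32", "SMS", "duplication", 175, MA))
for (av in asd_vus)
    addv(av[1], av[2], av[3], if (av[3] == "deletion") "1" else "3",
         as.numeric(av[4]), av[5], VU, paste0("asd:", av[2]))
## X-linked ASD duplications in boys sit on a 1-copy baseline
for (vv in c("a31", "a32")) vr[[vv]]$copy <- "2"

vdf <- do.call(rbind, vr)
rownames(vdf) <- vdf$vid
A(nrow(vdf) == 129, "129 variants")

## ----------------------------------------------------- coordinate layout
## per-chromosome cursor placement; manual regions reserved below cursors
cursor <- c(`1` = 1e6, `2` = 1e6, `3` = 1e6, `4` = 1e6, `5` = 1e6,
            `6` = 1e6, `7` = 4e6, `8` = 1e6, `9` = 8e7, `10` = 1e6,
            `11` = 1e6, `13` = 1e6, `14` = 1e6, `15` = 4e7, `16` = 1e6,
            `17` = 1e6, `18` = 1e6, `19` = 1e6, `20` = 1e6, `21` = 1e6,
            `22` = 2.5e7, X = 1e6)
entry <- list()   # key -> c(start, end)
for (key in names(L)) {
    lc <- L[[key]]
    vs <- vdf[vdf$locus == key, , drop = FALSE]
    sizes <- ifelse(is.na(vs$size_kb), vs$end - vs$start + 1,
                    vs$size_kb * 1000)
    A(nrow(vs) > 0, paste("locus has variants:", key))
    if (!is.na(lc$mstart)) {
        entry[[key]] <- c(lc$mstart, lc$mend)
        next
    }
    cap <- if (lc$evidence == "candidate_gene") 2e5 else 3e6
    elen <- min(floor(0.8 * min(sizes)), cap)
    maxs <- max(sizes)
    cen <- cursor[lc$chrom] + maxs / 2
    entry[[key]] <- round(c(cen - elen / 2, cen + elen / 2))
    cursor[lc$chrom] <- cursor[lc$chrom] + maxs + 4e6
}
## place variants: centred on the entry, clamped at 1 with small offsets
offset_counter <- new.env(); assign("n", 0L, offset_counter)
for (i in seq_len(nrow(vdf))) {
    if (!is.na(vdf$start[i])) next
    key <- vdf$locus[i]
    en <- entry[[key]]
    size <- vdf$size_kb[i] * 1000
    cen <- mean(en)
    k <- get("n", offset_counter); assign("n", k + 1L, offset_counter)
    st <- max(1 + (k %% 7) * 1000, round(cen - size / 2))
    vdf$start[i] <- st
    vdf$end[i] <- st + size - 1
}
## every variant must cover >= 50% of its entry (here: fully)
for (i in seq_len(nrow(vdf))) {
    en <- entry[[vdf$locus[i]]]
    cov <- (min(vdf$end[i], en[2]) - max(vdf$start[i], en[1]) + 1) /
        (en[2] - en[1] + 1)
    A(cov >= 0.5, paste("entry coverage", vdf$vid[i], round(cov, 3)))
}
## no variant may cross a foreign same-dosage or stronger-evidence window
dos_of <- function(t) if (t == "deletion") "loss" else
    if (t == "duplication") "gain" else "upd"
for (i in seq_len(nrow(vdf))) {
    ty <- dos_of(vdf$type[i])
    for (key in names(L)) {
        if (key == vdf$locus[i]) next
        lc <- L[[key]]
        if (lc$chrom != L[[vdf$locus[i]]]$chrom) next
        compat <- (ty == "loss" && lc$dosage %in% c("loss", "either")) ||
                  (ty == "gain" && lc$dosage %in% c("gain", "either")) ||
                  (ty == "upd" && grepl("^upd", lc$dosage))
        if (!compat) next
        en <- entry[[key]]
        ov <- max(0, min(vdf$end[i], en[2]) - max(vdf$start[i], en[1]) + 1)
        cov <- ov / (en[2] - en[1] + 1)
        ## a cross-match at >= 50% coverage would corrupt classification,
        ## except same-tier established/established (tie broken by name)
        if (cov >= 0.5) {
            tierEquiv <- L[[vdf$locus[i]]]$evidence == lc$evidence
            A(tierEquiv, paste("cross-window hit", vdf$vid[i], "->", key))
        }
    }
}

## --------------------------------------------------- subjects / grouping
## ID/DD dual-CNV subjects (18); the rest of the 97 variants are singles
duals <- list(
    d1 = c("r46", "r47"), d2 = c("r59", "r60"), d3 = c("r69", "r81"),
    d4 = c("r57", "r92"), d5 = c("r72", "r24"), d6 = c("r12", "r49"),
    d7 = c("r74", "r66"), d8 = c("r94", "r76"), d9 = c("r13", "r88"),
    d10 = c("r01", "r04"), d11 = c("r02", "r71"), d12 = c("r07", "r09"),
    d13 = c("r68", "r79"), d14 = c("r80", "r86"), d15 = c("r87", "r93"),
    d16 = c("r03", "r90"), d17 = c("r37", "r84"), d18 = c("r64", "r53"))
dualv <- unlist(duals)
A(!anyDuplicated(dualv) && length(dualv) == 36, "36 distinct dual variants")
iddd_vids <- rownames(vdf)[grepl("^r", rownames(vdf))]
singles <- setdiff(iddd_vids, dualv)
A(length(singles) == 61, "61 single-variant ID/DD subjects")

## diagnosed ID/DD subjects in cell-fill order (sex, age-bin, variant set)
unit <- function(x) if (x %in% names(duals)) duals[[x]] else x
males <- list(
    `<1`  = c("r05", "r06", "r08", "r10", "r14", "r15", "r16", "r17", "r18",
              "r19", "r20", "r23", "r26"),
    `1-2` = c("r27", "r28", "r29", "r30", "r31", "r32", "r33", "r34",
              "d2", "d7", "d8", "d9"),
    `2-5` = c("r91", "d18", "d10", "d11", "d12", "d13", "r38", "r42", "r48",
              "r51", "r67", "r73", "d1", "d3"),
    `>5`  = "d4")
females <- list(
    `<1`  = c("r70", "r78", "r89", "r21", "r22", "r35", "r36", "r43", "r44",
              "r45", "r50", "r52", "r54"),
    `1-2` = c("r55", "r56", "r58", "r61", "r62", "r63", "d6", "d14", "d15",
              "d16", "d17", "r11", "r25"),
    `2-5` = c("r39", "r40", "r41", "r65", "r75", "r77", "r82", "r83", "r85",
              "r95", "r96"),
    `>5`  = c("r97", "d5"))
A(setequal(c(unlist(lapply(unlist(males), unit)),
             unlist(lapply(unlist(females), unit))), iddd_vids),
  "all 97 ID/DD variants assigned to subjects")
A(length(unlist(males)) + length(unlist(females)) == 79, "79 ID/DD cases")

binAge <- c(`<1` = 6, `1-2` = 18, `2-5` = 36, `>5` = 72)
subjects <- list(); vassign <- list(); pid <- 0
addSubject <- function(sex, bin, group, vids = character(),
                       father = TRUE, mother = TRUE, kary = "normal",
                       age = NULL) {
    pid <<- pid + 1
    id <- sprintf("%s%03d", if (group == "ASD") "A" else "D", pid)
    subjects[[id]] <<- data.frame(subject_id = id, sex = sex,
                                  age_months = age %||% binAge[[bin]],
                                  group = group, father = father,
                                  mother = mother, kary = kary,
                                  stringsAsFactors = FALSE)
    for (v in vids) vassign[[v]] <<- id
    invisible(id)
}
for (bin in names(males)) for (u in males[[bin]])
    addSubject("male", bin, "ID_DD", unit(u),
               father = !all(vdf[unit(u), "inh"] == UN))
for (bin in names(females)) for (u in females[[bin]])
    addSubject("female", bin, "ID_DD", unit(u),
               father = !all(vdf[unit(u), "inh"] == UN))
## ID/DD aneuploid subjects (8, male; outside the 251 analysed)
kary8 <- c(rep("trisomy 21", 6), "47,XXY", "47,XYY")
for (k in kary8) addSubject("male", "2-5", "ID_DD", kary = k)
## ID/DD undiagnosed fill to the stratified denominators
fillIDDD <- list(male = c(`<1` = 45, `1-2` = 21, `2-5` = 29, `>5` = 12),
                 female = c(`<1` = 33, `1-2` = 16, `2-5` = 14, `>5` = 2))
nMissF <- 22; nMissM <- 24
for (sx in names(fillIDDD)) for (bin in names(fillIDDD[[sx]]))
    for (j in seq_len(fillIDDD[[sx]][[bin]])) {
        fa <- TRUE; mo <- TRUE
        if (nMissF > 0) { fa <- FALSE; nMissF <- nMissF - 1 }
        else if (nMissM > 0) { mo <- FALSE; nMissM <- nMissM - 1 }
        addSubject(sx, bin, "ID_DD", father = fa, mother = mo)
    }
## ASD diagnosed / clinically relevant subjects
addSubject("male", ">5", "ASD", "a01", age = 66)
addSubject("male", "2-5", "ASD", "a02", age = 48)
addSubject("female", "2-5", "ASD", "a03", age = 42)
addSubject("male", "2-5", "ASD", "a04", age = 30)
addSubject("male", "2-5", "ASD", "a05", age = 39)
addSubject("female", "2-5", "ASD", c("a09", "a21"), age = 28)   # dual (F3)
addSubject("female", "2-5", "ASD", c("a15", "a17"), age = 46)   # dual (Y26)
addSubject("male", "2-5", "ASD", "a10", age = 48)
addSubject("male", "2-5", "ASD", "a11", age = 40)
addSubject("male", "2-5", "ASD", "a07", age = 36)
addSubject("female", "2-5", "ASD", "a08", age = 28)
asdM25 <- c("a12", "a13", "a14", "a16", "a18", "a19", "a20", "a22", "a23",
            "a24", "a25", "a26", "a27", "a31", "a32")
for (v in asdM25)
    addSubject("male", "2-5", "ASD", v, father = vdf[v, "inh"] != UN)
for (v in c("a06", "a28", "a29", "a30"))
    addSubject("female", "2-5", "ASD", v)
## ASD undiagnosed fill
fillASD <- list(male = c(`1-2` = 2, `2-5` = 73, `>5` = 30),
                female = c(`2-5` = 12, `>5` = 4))
for (sx in names(fillASD)) for (bin in names(fillASD[[sx]]))
    for (j in seq_len(fillASD[[sx]][[bin]]))
        addSubject(sx, bin, "ASD")

sdf <- do.call(rbind, subjects)
A(nrow(sdf) == 410, "410 subjects")
A(sum(sdf$group == "ASD") == 151, "151 ASD")
A(sum(sdf$group == "ID_DD") == 259, "259 ID/DD")
A(sum(sdf$kary != "normal") == 8, "8 aneuploid")
A(sum(!sdf$father) == 40, paste("40 missing fathers, have", sum(!sdf$father)))
A(sum(!sdf$mother) == 24, "24 missing mothers")
A(sum(sdf$sex == "male") == 282 && sum(sdf$sex == "female") == 128,
  "282 male / 128 female")

vdf$subject_id <- vapply(vdf$vid, function(v) vassign[[v]], "")
A(!any(vdf$subject_id == ""), "every variant has a subject")

## ---- stratified strict-yield cell assertions (group x sex x age bin)
strictBy <- function(group, sex = NULL, bin = NULL) {
    s <- sdf[sdf$group == group & sdf$kary == "normal", ]
    if (!is.null(sex)) s <- s[s$sex == sex, ]
    if (!is.null(bin)) s <- s[names(binAge)[findInterval(s$age_months,
        c(0, 12, 24, 60))] == bin, ]
    dg <- vdf$subject_id[vdf$tier %in% c(P, LP)]
    c(num = sum(s$subject_id %in% dg), den = nrow(s))
}
expect_cell <- function(got, num, den, what)
    A(got["num"] == num && got["den"] == den,
      paste(what, ":", got["num"], "/", got["den"], "wanted", num, "/", den))
expect_cell(strictBy("ID_DD"), 79, 251, "ID/DD total")
expect_cell(strictBy("ASD"), 5, 151, "ASD total")
expect_cell(strictBy("ID_DD", "male"), 40, 147, "ID/DD male")
expect_cell(strictBy("ID_DD", "female"), 39, 104, "ID/DD female")
expect_cell(strictBy("ASD", "male"), 4, 127, "ASD male")
expect_cell(strictBy("ASD", "female"), 1, 24, "ASD female")
expect_cell(strictBy("ID_DD", "male", "<1"), 13, 58, "IDDD M <1")
expect_cell(strictBy("ID_DD", "male", "1-2"), 12, 33, "IDDD M 1-2")
expect_cell(strictBy("ID_DD", "male", "2-5"), 14, 43, "IDDD M 2-5")
expect_cell(strictBy("ID_DD", "male", ">5"), 1, 13, "IDDD M >5")
expect_cell(strictBy("ID_DD", "female", "<1"), 13, 46, "IDDD F <1")
expect_cell(strictBy("ID_DD", "female", "1-2"), 13, 29, "IDDD F 1-2")
expect_cell(strictBy("ID_DD", "female", "2-5"), 11, 25, "IDDD F 2-5")
expect_cell(strictBy("ID_DD", "female", ">5"), 2, 4, "IDDD F >5")
expect_cell(strictBy("ASD", "male", "1-2"), 0, 2, "ASD M 1-2")
expect_cell(strictBy("ASD", "male", "2-5"), 3, 94, "ASD M 2-5")
expect_cell(strictBy("ASD", "male", ">5"), 1, 31, "ASD M >5")
expect_cell(strictBy("ASD", "female", "2-5"), 1, 20, "ASD F 2-5")
expect_cell(strictBy("ASD", "female", ">5"), 0, 4, "ASD F >5")

## ---- headline count assertions
iddd <- vdf[grepl("^r", vdf$vid), ]; asd <- vdf[grepl("^a", vdf$vid), ]
A(nrow(iddd) == 97 && nrow(asd) == 32, "97 + 32 variants")
A(sum(iddd$tier == P) == 90 && sum(iddd$tier == LP) == 4 &&
  sum(iddd$tier == VU) == 3, "ID/DD 90P/4LP/3VUS")
A(sum(asd$tier == P) == 4 && sum(asd$tier == LP) == 1 &&
  sum(asd$tier == VU) == 27, "ASD 4P/1LP/27VUS")
A(sum(iddd$inh == DN) == 65, "65 de novo ID/DD")
A(sum(asd$inh == DN) == 5, "5 de novo ASD")
A(sum(iddd$inh == UN) == 20 && sum(iddd$inh == MA) == 8 &&
  sum(iddd$inh == PA) == 4, "ID/DD 20 unknown / 8 mat / 4 pat")
A(sum(asd$inh == PA) == 16 && sum(asd$inh == MA) == 9 &&
  sum(asd$inh == UN) == 2, "ASD 16 pat / 9 mat / 2 unknown")
A(sum(iddd$type == "deletion") == 53 && sum(iddd$type == "duplication") == 39 &&
  sum(iddd$type == "UPD") == 5, "53 del / 39 dup / 5 UPD")
A(sum(asd$type == "deletion") == 14 && sum(asd$type == "duplication") == 18,
  "ASD 14 del / 18 dup")
A(length(unique(vdf$subject_id)) == 109, "109 clinically relevant cases")
syndOf <- vapply(vdf$locus, function(k) isTRUE(L[[k]]$synd), logical(1))
A(sum(vdf$inh == DN & syndOf) == 53 && sum(vdf$inh == DN) == 70,
  "53 of 70 de novo variants at known-syndrome loci")
dnsub <- unique(vdf$subject_id[vdf$inh == DN])
A(length(dnsub) == 60, "60 subjects with a de novo CNV")
A(length(unique(iddd$subject_id[iddd$inh == DN])) == 55, "55 ID/DD de novo cases")
dn_sex <- table(sdf[unique(iddd$subject_id[iddd$inh == DN]), "sex"])
A(dn_sex[["male"]] == 31 && dn_sex[["female"]] == 24,
  "ID/DD de novo cases: 31 male / 24 female")
## size extremes on non-interpolated rows
ni <- vdf[!vdf$interp, ]
sz <- ni$end - ni$start + 1
A(min(sz) == 56000, "cohort minimum size 56 kb")
A(max(sz) == 95119000, "cohort maximum size 95.119 Mb")
A(min(sz[grepl("^r", ni$vid)]) == 377000, "ID/DD minimum 377 kb")
A(max(sz[grepl("^a", ni$vid)]) == 8418000, "ASD maximum 8.418 Mb")

## ------------------------------------------------------------- outputs
fmtnum <- function(x) format(x, scientific = FALSE, trim = TRUE)
## knowledge base
kb <- do.call(rbind, lapply(names(L), function(key) {
    lc <- L[[key]]; en <- entry[[key]]
    data.frame(name = key, chrom = lc$chrom, start = fmtnum(en[1]),
               end = fmtnum(en[2]), expected_dosage = lc$dosage,
               evidence = lc$evidence, mechanism = lc$mech,
               syndrome = lc$synd, genes = lc$genes,
               stringsAsFactors = FALSE)
}))
write.table(kb, file.path(outdir, "fixture_kb.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
## subjects
subj_out <- data.frame(subject_id = sdf$subject_id, sex = sdf$sex,
                       age_months = sdf$age_months, group = sdf$group,
                       karyotype = sdf$kary, stringsAsFactors = FALSE)
write.table(subj_out, file.path(outdir, "fixture_subjects.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
## aneuploidies
an_out <- data.frame(subject_id = sdf$subject_id[sdf$kary != "normal"],
                     karyotype_label = sdf$kary[sdf$kary != "normal"])
write.table(an_out, file.path(outdir, "fixture_aneuploidies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
## pedigree
ped <- data.frame(family = sdf$subject_id, id = sdf$subject_id,
                  father = ifelse(sdf$father, paste0(sdf$subject_id, "_F"), "0"),
                  mother = ifelse(sdf$mother, paste0(sdf$subject_id, "_M"), "0"),
                  sex = ifelse(sdf$sex == "male", 1, 2), phenotype = 2)
write.table(ped, file.path(outdir, "fixture_pedigree.ped"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
## variants
chrom_of <- function(v) L[[vdf[v, "locus"]]]$chrom
vout <- data.frame(
    subject_id = vdf$subject_id,
    chrom = vapply(vdf$vid, chrom_of, ""),
    start = fmtnum(vdf$start), end = fmtnum(vdf$end),
    type = vdf$type, copy_state = vdf$copy,
    marker_count = pmax(20, (vdf$end - vdf$start + 1) %/% 2000),
    parent_of_origin = ifelse(vdf$type == "UPD",
                              ifelse(vdf$inh == MA, "maternal", "paternal"),
                              ""),
    tier = vdf$tier, syndrome = vdf$locus, inheritance = vdf$inh,
    size_interpolated = vdf$interp, provenance = vdf$prov,
    stringsAsFactors = FALSE)
write.table(vout, file.path(outdir, "fixture_variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
## parental calls for inherited CNVs
inher <- vdf[vdf$inh %in% c(MA, PA) & vdf$type != "UPD", ]
inher_chrom <- vapply(inher$vid, chrom_of, "")
## carrier parent's copy state on the parent's own baseline (fathers have
## one X, so a transmitted X duplication is 2 copies in the father)
parent_copy <- ifelse(inher$type == "deletion", "1",
                      ifelse(inher_chrom == "X" & inher$inh == PA, "2", "3"))
pc <- data.frame(
    subject_id = paste0(inher$subject_id, ifelse(inher$inh == PA, "_F", "_M")),
    chrom = inher_chrom,
    start = fmtnum(inher$start), end = fmtnum(inher$end),
    type = inher$type,
    copy_state = parent_copy,
    marker_count = pmax(20, (inher$end - inher$start + 1) %/% 2000),
    parent_of_origin = "", stringsAsFactors = FALSE)
## the carrier parent must exist in the pedigree
par_ok <- ifelse(inher$inh == PA, sdf[inher$subject_id, "father"],
                 sdf[inher$subject_id, "mother"])
A(all(par_ok), "carrier parents are all available")
write.table(pc, file.path(outdir, "fixture_parent_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("fixture written:", nrow(sdf), "subjects,", nrow(vdf), "variants,",
    nrow(kb), "KB entries,", nrow(pc), "parental calls\n")
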