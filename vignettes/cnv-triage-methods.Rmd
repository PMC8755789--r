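---
title: "Clinical triage of chromosomal microarray CNV calls: models and methods"
author: "CNVtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical triage of chromosomal microarray CNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(CNVtriage))
```

# Scope and model

Chromosomal microarray analysis (CMA) is the first-tier genetic test for
children with autism spectrum disorder (ASD) or unexplained intellectual
disability / developmental delay (ID/DD). The array-side software emits
per-subject segment calls — deletions and duplications with coordinates,
copy state and probe support, plus annotated uniparental disomies (UPDs)
and whole-chromosome aneuploidies. Everything downstream of segment calling
is interpretation, and that is what this package implements:

1. a **reporting threshold** on segment size and probe support,
2. a **rarity filter** against an ethnically matched control panel and a
   reference CNV frequency set,
3. a **segmental-duplication mask**,
4. five-tier ACMG-style **classification** against a curated knowledge base
   of syndrome critical regions and candidate genes,
5. trio-based **inheritance** (de novo / paternal / maternal / biparental /
   unknown), and
6. cohort **diagnostic-yield** stratification with exact 2×2 tests.

Calls are held as `GRanges` with 1-based inclusive coordinates, the native
Bioconductor convention; a call's size in bp is its width, so the size of a
span written `chr9:203,861–4,199,819` is 3,995,959 bp. Copy states are
low/high pairs, which represents mosaic states such as `x3-4` (gain in a
fraction of cells) and `x1-2` (mosaic loss) directly. The copy-state sanity
rule is sex-aware: X and Y sit on a 1-copy baseline in males, so a 2-copy
X segment in a boy is a duplication while the same state in a girl is
normal dosage. The aberrant bound of a call must cross its baseline; the
other bound may touch it, which is exactly what a mosaic state does.

# Thresholds

All numeric thresholds live in a single `FilterConfig` object so that a
triage run is auditable in one place:

| parameter | default | meaning |
|---|---|---|
| `minSizeBp` | 50,000 | minimum reported segment size (bp) |
| `minMarkers` | 20 | minimum supporting probes |
| `reciprocalOverlap` | 0.50 | identity rule for two CNVs |
| `controlFreqMax` | 0.01 | max carrier frequency in the control panel |
| `referenceFreqMax` | 0.01 | max frequency in the reference CNV set |
| `segdupFractionMax` | 0.70 | drop calls at or above this segdup coverage |
| `controlPanelN` | 1679 | control panel size (subjects) |
| `syndromeCoverageMin` | 0.50 | fraction of a critical region a variant must cover |
| `alpha` | 0.05 | significance level for cohort contrasts |

Boundary conventions are deliberate and tested:

* The reporting threshold is inclusive on both axes (50,000 bp with 20
  markers is reported).
* Two CNVs are "the same variant" when the **smaller** of the two overlap
  fractions reaches the threshold **and** their dosage (loss vs gain)
  matches. The boundary counts as identical: exact ties are measure-zero in
  real data, and a closed rule is testable. Copy state is not compared, so
  an `x3` and an `x4` duplication of the same segment match — whether
  identity should further require equal copy state is genuinely open, and
  dosage-only matching is the permissive, conventional reading.
* Rarity means *not present in more than 1%*: a carrier frequency of
  exactly 16/1679 (0.95%) passes, 17/1679 (1.01%) fails.
* The segmental-duplication mask is strict: coverage of exactly 0.70 drops
  the call. Coverage is measured against the union of the mask intervals,
  never double-counting self-overlapping annotations. What the mask file
  contains (segmental duplications only, or other repeat classes too) is
  the caller's choice; the package treats it as an opaque interval set.

Control frequency uses **carrier-subject counting**: a control subject with
two calls matching the query still counts once, because the panel size is
denominated in subjects. Reference frequencies (a stand-in for public CNV
frequency databases, which distribute frequencies rather than genotypes)
are supplied precomputed per entry; a query takes the maximum frequency
over matching entries.

# Classification

The knowledge base is an explicit input — a table of critical regions and
candidate genes with an expected dosage (`loss`, `gain`, `either`,
`upd_maternal`, `upd_paternal`) and a curated evidence level. Evidence is
irreducibly human: whether a region is established in multiple independent
reports, described once, or merely a compelling candidate cannot be
computed from coordinates. The packaged reference knowledge base encodes
those judgements for every locus in the reference cohort; the
`mechanism` flag marks the rare candidate genes whose dosage mechanism is
specific enough to upgrade a hit.

A variant is assigned the best-matching entry whose expected dosage is
compatible and of which it covers at least `syndromeCoverageMin` (50% of
the *critical region*, the common clinical heuristic — large CNVs that
engulf a small established region are thereby recognised). Ties break by
covered fraction, then evidence strength, then name, so assignment is
deterministic. Tiers follow from the match:

* **pathogenic** — established region (or a UPD of an imprinted established
  region, or an aneuploidy, which bypasses the CNV funnel entirely);
* **likely pathogenic** — single-report region, or a mechanism-flagged
  candidate gene;
* **VUS** — rare and overlapping knowledge-base gene content, nothing
  stronger;
* **likely benign** — rare, no knowledge-base content;
* **benign** — not rare (reachable only in annotate-all mode).

Every variant receives exactly one tier, and enlarging a variant that
contains an established region can never lower its tier (coverage of the
region is monotone in variant size).

Subject-level rollup takes the most severe tier. The **strict** diagnostic
yield counts subjects with at least one pathogenic or likely pathogenic
variant (plus aneuploid subjects when they are included); the **broad**
yield adds VUS carriers ("clinically relevant"). A subject with two
qualifying variants counts once.

# Inheritance

A child CNV is paternal when it matches (same identity rule) at least one
of the father's calls and none of the mother's; maternal symmetrically;
biparental when both; de novo when **both** parents were genotyped and
neither carries it. When a parent is unavailable and no genotyped parent
carries the call, the status is **unknown** — including when the single
available parent was genotyped and negative. This is the conservative
choice: calling "de novo" from one negative parent would inflate the de
novo rate precisely in the families with missing samples. UPD parent of
origin is carried from the input annotation (it derives from
methylation-sensitive assays upstream, not from CNV matching) and is never
recomputed.

# Cohort statistics

Yield tables stratify by diagnosis group, sex and age bin. Age bins are
`<1`, `1-2`, `2-5`, `>5` years, computed from age in months with
lower-closed boundaries (24 months falls in `2-5`); the exact placement of
boundary ages is unstated in routine clinical tables, and lower-closed is
the convention that keeps `findInterval` semantics. Percentages round
half-up to one decimal (40/128 prints as 31.3), matching how clinical
tables are typeset; `round()`'s half-even rule would print 31.2. Empty
strata are emitted with a flag rather than dropped.

`fisherTwoSided()` is the two-sided exact test under the probability-mass
rule: the p-value sums the hypergeometric probabilities of all tables with
the observed margins whose probability does not exceed the observed
table's. This is `stats::fisher.test`'s rule; the test suite checks it
against an independent enumeration oracle over 1000 random tables. The
"two times one tail" convention differs and is not used. Zero-margin
tables are refused rather than defaulting to 1.

`compareGroups()` reports the exact p-value **and** the uncorrected
chi-square. The reason is practical: legacy statistical software labelled
both as tests "of significance between groups", and reported cohort
p-values frequently correspond to the asymptotic value even when the exact
test is named. For the sex-by-diagnosis contrast `[[40,88],[44,230]]` the
exact test gives 9.0×10⁻⁴ while the uncorrected chi-square gives
4.8×10⁻⁴ — a 1.9-fold discrepancy with no analysis consequence (both are
far below α = 0.05), but worth reporting side by side rather than silently
choosing. The same applies to the group-by-de-novo contrast
(7.5×10⁻⁸ exact vs 4.0×10⁻⁷ asymptotic). For variant-size differences
between groups, `sizeCompare()` reports Welch's t test; the choice of test
for a size difference is a reporting convention and its p-value should be
read as descriptive, not confirmatory.

# The packaged reference cohort

`loadReferenceCohort()` returns a 410-subject clinical cohort encoded at
subject and variant level: 151 ASD and 259 ID/DD probands (8 of them
aneuploid: six trisomy 21, one 47,XXY, one 47,XYY), 129 clinically
relevant CNVs/UPDs with tier, syndrome assignment and inheritance, the
knowledge base they classify against, a pedigree with 40 missing fathers
and 24 missing mothers, and the parental calls that support every
inherited variant. Loading re-checks the marginal counts and aborts on any
corruption.

Encoding choices worth knowing:

* **Coordinates are synthetic placeholders.** Sizes are exact, but loci
  are laid out in disjoint per-chromosome windows rather than at genome
  positions (which are not recoverable from summary tables). The three
  variants whose breakpoints are known exactly use them. Nothing in the
  pipeline depends on absolute positions, only on interval relations,
  which the layout preserves.
* **Grouped sizes are interpolated and flagged.** Where several subjects
  share one table row with a size range (e.g. eleven Williams–Beuren
  deletions spanning 1424–1570 kb), the interior sizes are linear
  interpolations flagged `size_interpolated`; `sizeSummary()` excludes
  them, and no acceptance-level check uses them.
* **Internal inconsistencies resolve toward the subject-level stratified
  table.** The source tallies disagree in a few places (variant-row counts
  vs totals, a likely-pathogenic count of 3 vs 4, paternal/maternal
  splits of 4/8 vs 3/9). The fixture encodes the two footnoted adjacent
  x4+x3 duplication pairs as two variants each (which is also the only
  reading that reproduces the printed 39 duplications and 65 ID/DD de novo
  events), keeps the mosaic 9p24 x3–4 event as one variant, follows the
  variant rows for the paternal/maternal split, and encodes one de novo
  deletion as likely pathogenic so that the stratified yield table's four
  LP subjects (three girls under 1, one boy 2–5) are reproducible.
* **One dual-CNV pairing was adjusted.** A subject described as carrying a
  de novo deletion plus a second CNV of unknown inheritance is not
  representable under the inheritance rule above (unknown requires a
  missing parent; de novo requires both). The fixture pairs that deletion
  with a de novo second variant and keeps the unknown-inheritance
  duplications with subjects whose fathers are unavailable. All cohort
  totals are unaffected.

# The synthetic trio-cohort generator

`simulateCohort()` exists so every pipeline stage can be exercised, scaled
and power-tested without patient data. It emulates:

* cohort composition (group fractions, per-group sex ratios, per-group age
  ranges, ~2% aneuploidy);
* a background of benign CNV polymorphism: a pool of loci with log-normal
  sizes (median 150 kb, σ(log) = 1 — a generic array-scale background, as
  no empirical background distribution is available) and per-locus carrier
  frequencies between 0.2% and 20%, from which both the cohort and the
  1679-subject control panel draw, so background calls are *common* and
  the rarity filter removes them;
* syndromic, candidate-gene and UPD events drawn from the knowledge base
  with dosage respected, absent from the panel, de novo with a per-group
  probability and otherwise copied into one parent;
* missing parents, which convert events the pipeline would otherwise
  resolve into `unknown`.

It does **not** simulate probe-level noise, false-positive segmentation,
linkage structure, or genotype data; recovery results say that the
*interpretation* layers are correct and well-calibrated, not that segment
calling is. Benign loci live in a coordinate band (400–500 Mb) disjoint
from knowledge-base windows so that tier truth labels are unambiguous.

Reproducibility: every subject's draws come from an RNG substream seeded
by a stable hash of the subject id mixed with the master seed, so subject
`SIM00007` is identical in a 30-subject and a 5000-subject cohort with the
same seed, and repeated runs are byte-identical.

`recoverParameters()` re-runs the full funnel on a simulated cohort and
compares assigned against intended tiers and inheritance. The de novo
fraction is estimated on complete trios only; with a missing parent the
pipeline cannot return de novo, so including incomplete trios would bias
the estimate downward by construction. The test suite runs recovery at
n = 5000 with a design strict yield of 0.20 and de novo fraction 0.80 and
requires both inside their 99% binomial intervals; 5000 subjects keeps the
binomial interval tight (±1.5 percentage points on the yield) while a full
run stays under a minute.

# Degenerate inputs and numerical notes

* Empty call sets, empty knowledge bases (with a warning) and empty
  cover sets are legal and return empty/zero results.
* `annotateFrequency()` refuses a non-positive panel size and a panel with
  more distinct subjects than the declared size.
* Zero-margin 2×2 tables error; yield strata with empty denominators are
  flagged, not dropped.
* All thresholds compare on exact integer or rational quantities (bp
  counts, carrier counts over a fixed denominator), so boundary behaviour
  does not depend on floating-point rounding.

# Limitations

* Evidence levels and critical regions are inputs; the package does not
  mine literature or databases, and its classifications are only as good
  as the knowledge base supplied.
* The identity rule is dosage-matched 50% reciprocal overlap everywhere
  (frequency, inheritance); real laboratories often confirm parental
  carriage by qPCR, which can resolve cases the overlap rule cannot.
* UPD detection is upstream: UPD events are consumed as annotated input,
  never inferred from genotypes.
* The reference cohort's coordinates are synthetic; it validates the
  pipeline's logic and the cohort-level statistics, not genome-position
  lookups against external resources.
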