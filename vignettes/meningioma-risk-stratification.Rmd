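---
title: "Integrated risk stratification of meningiomas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated risk stratification of meningiomas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meningrisk)
```

## The model

Histological grading of meningiomas under the CNS WHO 2021 scheme gives
limited information about the risk of early recurrence: most Grade 1
tumours behave indolently, but Grade 2 tumours are heterogeneous. The
integrated model implemented here adds two molecular layers on top of the
grade and sums them into a score of 0–9:

| component | values | points |
|---|---|---|
| CNS WHO grade | 1 / 2 / 3 | 0 / 1 / 2 |
| methylation family | benign / intermediate / malignant | 0 / 2 / 4 |
| arm losses among 1p, 6q, 14q | 0 / 1–2 / 3 arms | 0 / 2 / 3 |

Totals 0–2 are *low*, 3–5 *intermediate* and 6–9 *high* risk. Because the
components are coarse, not every total is attainable at every grade:

```{r}
reachable_scores("1")
reachable_scores("2")
reachable_scores("3")
```

For a Grade 2 tumour the minimum is 1 and totals 2 and 9 cannot occur —
useful sanity checks when auditing scored cohorts.

The methylation family and its *calibrated score* (classifier confidence
in $[0,1]$) come from an external DNA-methylation classifier; this package
deliberately does not reimplement the classifier, probe-level CNV
estimation or segmentation (conumee-style pipelines do that upstream). Only
classifier calls with calibrated score $\ge 0.9$ enter the scored analysis;
results in $[0.3, 0.9)$ form a low-confidence band and results below 0.3
count as unclassified (`gate_by_calibrated_score()`).

## Arm-level loss calling

Input is the segmented log2 copy-number ratio track exported by
methylation-array CNV pipelines (IGV SEG dialect, 1-based inclusive on
disk, converted to 0-based half-open internally). The calling rules, all
exposed as parameters:

* a segment is *lost* when its log2 ratio is $\le$ `loss_log2`
  (default $-0.1$, the single-copy-loss level of the array export). The
  threshold is a calling rule, not a copy-number estimate;
* an arm is *lost* when the union of lost-segment overlaps covers
  strictly more than `min_fraction` (default 5%) of the arm length. The
  union is computed with `IRanges::reduce()`, so overlapping segments are
  never double-counted and a segment spanning the centromere contributes
  to each arm only its overlap. The denominator is the full genomic arm
  length from the bundled definitions table — if the upstream pipeline
  reports probe-covered length instead, fractions near the 5% boundary can
  differ; we accept that as a documented convention;
* CDKN2A/B homozygous deletion is called when the *minimum* log2 ratio of
  segments overlapping the locus falls below `deletion_log2` (default
  $-0.4$). A deletion must be a negative log2 ratio, so the threshold is
  signed even though colloquial reports quote its magnitude. A locus with
  no overlapping segment yields an explicit *no-call* that propagates as
  "unknown" — it never silently becomes "not deleted", and an unknown
  never upgrades a grade;
* gains are irrelevant to the score and are ignored (no fraction-gained is
  computed).

Arm and locus coordinates are data, not code: an hg19-style table (p arm =
0 to centromere gap start; q arm = gap end to chromosome end) ships in
`inst/extdata/`, and any other build or convention can be supplied
(`one_based = TRUE` for 1-based tables).

## Grading rules

`assign_grade()` encodes the CNS WHO 2021 criteria. Grade 3: effective
mitotic count $\ge 20$ per 10 HPF (HPF standardised to 0.16&nbsp;mm², so
$\ge 12.5$ mitoses/mm²), or CDKN2A/B homozygous deletion, or TERT promoter
mutation. Grade 2: mitotic count 4–19 ($\ge 2.5$/mm²), brain invasion,
chordoid or clear cell subtype, or at least 3 of the 5 atypia features
(hypercellularity, sheet-like growth, prominent nucleoli, spotty necrosis,
small cell change). Rhabdoid and papillary subtypes are graded by the same
criteria but never Grade 1. When a referred case carries two mitotic
counts, the higher one is used.

Design choices where the rules under-specify:

* **Criterion category.** For Grade 2 reporting the four mutually
  exclusive strata are: brain invasion *and* mitoses 4–19 → *brain
  invasion + mitoses*; invasion alone; mitoses alone; anything else
  (subtype or atypia) → *histology type*. Subtype and atypia are merged
  because reports conventionally carry a single "histology type" stratum.
* **Tri-state evidence.** Brain invasion "unassessable" and molecular
  flags "unknown" are absent evidence: they never fire a criterion, and
  unknown molecular status is surfaced in `caveats`.
* **Ungradeable samples** (crush/cautery artefact, insufficient sample)
  return `grade = "ungraded"` before any other rule: such tumours still
  get CNV and methylation reports but no model score.

## Cohort analytics

`crosstab()` produces the labelled count/row-proportion tables used in
reporting, with proportions rounded to 2 decimals and in-text percentages
(`pct()`) to the nearest integer — matching the rounding conventions of
published allocation tables so recomputed tables are comparable cell by
cell. `mitotic_stratum()` uses closed integer bins 0–3, 4–7, 8–11, 12–15,
16–19, 20–30 (counts above 30 join the top bin with a warning). F:M ratios
are reported with the male count normalised to 1 ("2.4:1"); a stratum with
a zero count on either side reports counts only. `cochromosome_groups()`
partitions samples by joint 1p/22q status into four groups; samples
without CNV are counted in a remainder bucket, never silently dropped.

## The synthetic cohort

Real meningioma cohorts with linked histology, classifier output and
per-sample segments are not publicly depositable, so validation uses a
generative model (`generate_cohort()`) whose defaults are the published
cohort structure:

* planted grades 1/2/3 with probabilities 0.801/0.183/0.015 (routine
  diagnostic prevalences), plus an independent 3.9% masking probability
  that renders a sample ungradeable by hiding its histology (small/crushed
  samples) while leaving the molecular channels intact;
* Grade 2 criterion strata at their published frequencies
  (95/247/70/28 out of 441), and conditional methylation-class
  probabilities per stratum taken from the published allocation rows
  (row-normalised where the printed cells and marginals disagree);
* arm-loss probabilities conditional on (grade, methylation class).
  1p and 22q conditionals were chosen once so the *marginal* loss rates
  match the published per-grade rates (1p: 31%/56%/100%; 22q:
  52%/69%/100%); 6q and 14q are not printed per grade, so plausible
  increasing-with-class values were fixed a priori;
* sex ratios per grade (F:M 2.4:1, 1.6:1, 0.7:1), ages from a truncated
  normal (means 58–62, sd 14, range 16–91), calibrated-score bands at
  0.81/0.16/0.03, and per-stratum mitotic counts consistent with the
  planted criterion (e.g. a mitotic-count Grade 2 draws 4–19 with weights
  following the published strata frequencies);
* Grade 3 tumours are mitotically defined (20–30 mitoses) or, with
  probability 0.15, molecularly defined (CDKN2A/B deletion, mitoses 6–19);
  mitotic Grade 3 tumours co-delete CDKN2A/B with probability 0.3. Only
  Grade 3 tumours carry the deletion, so grade round-trips exactly.

**Segment emission** inverts the caller: a lost arm gets a telomeric block
covering a uniform 30–98% of the arm at log2 $\le -0.15$; intact arms get
neutral segments truncated above $-0.08$. Both margins keep every segment
clearly on one side of the $-0.1$ threshold, which is what makes the
round-trip exact and is the reason a green round-trip test certifies the
interval arithmetic and rule logic — *not* robustness to borderline noise.
Chromosome 9p is split around the CDKN2A/B locus so the locus minimum is
exactly the planted value.

**CDKN2A/B correlation channel.** The quantitative locus value is
generated to have a target Pearson correlation with the mitotic count
(default $-0.38$). Deep-deletion values are drawn first — they are part of
the biology and carry most of the leverage — and the slope of the
continuous channel for non-deleted samples is then solved by root-finding
so the overall correlation matches the target; a naive additive channel
overshoots its own target once deletions are overlaid.

**What the generator does not emulate**, hence what a green test does not
establish: inter-arm correlation of losses (real tumours concentrate
losses in a CNV-burdened subset, so the emergent risk-group distribution
within Grade 2 skews more intermediate than published tables); borderline
segment noise at the calling thresholds; classifier miscalls (the planted
methylation class is always the observed one); focal or subclonal events;
and any survival/outcome structure (none is modelled anywhere in the
package).

## Numerical and testing choices

* Coordinates are 0-based half-open internally; SEG I/O converts at the
  boundary. Fractions are exact rational arithmetic on integer base
  counts, and the test suite checks the IRanges-backed union against an
  independent per-base brute-force oracle on hundreds of randomised toy
  arms, requiring exact equality.
* The strict inequalities are deliberate: loss needs *more than* 5% of
  the arm; inclusion needs calibrated score $\ge 0.9$ (closed); CDKN2A/B
  deletion needs log2 strictly below $-0.4$; a 5.0% arm fraction is not a
  loss.
* Parameter-recovery coverage (`recovery_report()`) uses exact
  Clopper–Pearson intervals. Coverage is a property of the sampling
  distribution, so the test suite asserts the *mean* proportion of
  covered cells across 30 seeded replicates rather than a single draw,
  which would fail by chance in roughly a quarter of runs even for a
  correct generator.
* Determinism: one `set.seed()` at the top of `generate_cohort()` governs
  every draw; identical params + seed give byte-identical outputs, and
  the pipeline itself is deterministic, so reruns reproduce reports
  exactly (the manifest records config and seed, not timestamps).

## Known limitations

The grading engine trusts the cohort sheet's feature extraction; it does
not model inter-observer variability in mitotic counting. The SMARCE1-
altered methylation class has no published point value and is scored with
the benign family by default (`smarce1_points`), a convention that should
be revisited if a reference emerges. The 5%-of-arm denominator is genomic
arm length, not probe-covered length. Published allocation tables contain
small internal inconsistencies (rows whose cells, totals and proportions
cannot all be true simultaneously); recomputed tables here follow the
arithmetic of the stated counts, and where a printed proportion is
irreproducible from any consistent counts the recomputed value is
reported.
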