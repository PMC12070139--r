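# meningrisk

Integrated risk stratification of meningiomas from methylation-array copy
number profiles and CNS WHO grade.

Meningiomas are the most common primary CNS tumours in adults, and
histological grading alone predicts the risk of early recurrence only
coarsely. Integrated molecular classification combines three layers — the
CNS WHO grade, the methylation family (MF) called by a DNA-methylation
classifier, and chromosome-arm copy number losses — into an additive model
score:

```
score = grade points + MF points + chromosome points

  grade:      WHO 1 → 0,  WHO 2 → 1,  WHO 3 → 2
  MF:         benign → 0, intermediate → 2, malignant → 4
  chromosome: none of {1p, 6q, 14q} lost → 0, 1–2 lost → 2, all 3 lost → 3

  total 0–2  → low risk
  total 3–5  → intermediate risk
  total 6–9  → high risk     (of early recurrence)
```

This package is for neuropathology/neuro-oncology informaticians who want
to run that stratification reproducibly on cohorts. It provides:

* **Arm-level CNV calling** from the log2 segments exported by
  methylation-array CNV pipelines (IGV SEG dialect). A segment with
  log2 ratio ≤ −0.1 counts as lost; an arm is called "lost" when the union
  of lost segments covers strictly more than 5% of the arm. CDKN2A/B
  homozygous deletion is called from the locus minimum (log2 < −0.4, with
  an explicit no-call when the locus has no coverage).
* **A CNS WHO 2021 grading rules engine**: mitotic count 4–19/10 HPF
  (1 HPF = 0.16 mm², i.e. ≥ 2.5 mitoses/mm²), brain invasion, chordoid /
  clear cell subtype, or ≥ 3 of 5 atypia features for Grade 2; ≥ 20
  mitoses/10 HPF, CDKN2A/B deletion or TERT promoter mutation for Grade 3;
  rhabdoid/papillary subtypes floor at Grade 2.
* **The integrated score and risk bins**, with the calibrated-score
  inclusion gate (classifier confidence ≥ 0.9) applied before scoring.
* **Cohort analytics**: allocation cross-tabulations (grade × methylation
  class, Grade 2 criteria × class / risk group / score), mitotic strata,
  F:M ratios by score, joint 1p/22q co-deletion groups, and the
  mitoses–CDKN2A/B correlation.
* **A seeded synthetic cohort simulator** with planted ground truth
  (grades, criteria, methylation classes, arm losses and expected scores),
  so the whole pipeline is testable end to end without patient data.

## Worked example

```r
library(meningrisk)

# a 500-sample synthetic cohort with known ground truth
sim <- generate_cohort(cohort_params(n_samples = 500), seed = 42)
run <- run_pipeline(sim$sheet, sim$segments)
print(run)
#> meningrisk pipeline run: 500 samples; 412 included at calibrated score >= 0.9
#> risk groups (included, graded):
#>          low intermediate         high
#>          305           78            5

run$tables$grade_by_mc
#> Cross-tabulation: grade x mc_class  (n = 412 )
#> counts:
#>          benign intermediate SMARCE1_altered malignant total
#> 1           275           37               1         0   313
#> 2            43           27               3         0    73
#> 3             0            0               0         2     2
#> ungraded     23            1               0         0    24
#> row proportions:
#>          benign intermediate SMARCE1_altered malignant
#> 1          0.88         0.12            0.00         0
#> 2          0.59         0.37            0.04         0
#> ...
```

88% of Grade 1 tumours land in the methylation class benign and Grade 2
tumours spread across classes — the behaviour that makes Grade 2 tumours
the ones that benefit most from profiling. The pipeline recovered 100% of
the planted grades in this run
(`mean(run$samples$grade == sim$truth$expected_grade)` is `1`).

Scoring a single tumour:

```r
model_score(grade = "2", mc_class = "intermediate",
            lost_1p = TRUE, lost_6q = FALSE, lost_14q = TRUE)
#>   grade_component mf_component chrom_component n_arms_lost total   risk_group
#> 1               1            2               2           2     5 intermediate
```

A WHO Grade 2 tumour (1 point) in the intermediate methylation family
(2 points) with two of the three scored arms lost (2 points) totals 5:
intermediate risk.

## Command line

```sh
Rscript -e 'meningrisk::mnr_main()' simulate --n 1000 --seed 7 --out sim/
Rscript -e 'meningrisk::mnr_main()' run-all --cohort sim/cohort.csv \
    --seg sim/cohort.seg --out results/
```

Subcommands: `simulate`, `call-cnv`, `grade`, `score`, `run-all`. All
thresholds are flags (`--loss-log2 -0.1`, `--min-arm-fraction 0.05`,
`--cdkn2ab-log2 -0.4`, `--cs-gate 0.9`) or a `--config` YAML/JSON file;
outputs are one CSV per report table plus a JSON manifest recording config,
seed and version. A launcher script is installed at
`system.file("cli", "meningrisk", package = "meningrisk")`.

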