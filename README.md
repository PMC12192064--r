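# hippasym

Normative asymmetry z-scores for hippocampal subfield volumetry.

## The problem

In temporal lobe epilepsy the classic lesion — hippocampal sclerosis —
produces unilateral atrophy that is easy to miss on visual reading.
Automated subfield segmentation (e.g. FreeSurfer's hippocampal module)
yields volumes for 19 subfields per hemisphere, but absolute volumes vary
with age, sex and head size, so they are hard to interpret per patient.
`hippasym` implements the intra-individual alternative: for each region
it standardizes a patient's **right − left** volume difference against a
healthy-control reference of such differences,

    z = ((V_right − V_left) − μ_healthy) / σ_healthy,

and flags regions outside the 95 % normal interval, **|z| > 2**, as
candidate pathology.  Because the statistic is within-subject, global
covariates cancel and no regression adjustment is needed; the price is
the assumption that pathology is unilateral.

The package is aimed at neuroradiology / epilepsy-imaging researchers:
it covers the anatomical aggregation from 19 subfields to merged (HEAD,
BODY, TAIL, FISSURE) and combined labels (whole hippocampal head, whole
hippocampal body, whole hippocampus — fissure excluded), packaged
normative references for two T2 TSE acquisition variants (conventional
GRAPPA reconstruction and a deep-learning-reconstructed accelerated
variant, tags `T2_TSE` and `T2_TSE_DRB`), tools to rebuild the reference
from any healthy cohort, the paired statistical protocol for comparing
acquisition sequences (paired t, Wilcoxon signed-rank, Shapiro–Wilk,
Holm–Bonferroni, Cohen's d), and a calibrated synthetic-cohort generator
so the whole pipeline is testable without scans.

## Worked example

The package ships the subfield volumes of a patient with right-sided
hippocampal sclerosis as a validation dataset:

```r
library(hippasym)
pat <- hsExampleVolumes()
res <- zscoreAsymmetry(pat$right, pat$left, packagedReference("drb"))
classifyAsymmetry(res)
#> AsymmetryReport: subject 'hs_example_01', T2_TSE_DRB (|z| > 2 rule)
#>   flagged: 13 of 19 subfields, 3 of 3 combined labels
#>   lateralization: right_smaller

cols <- c("region", "label_class", "right_mm3", "left_mm3", "diff_mm3", "z", "flagged")
subset(res, region %in% c("CA1-Head", "Whole_hippocampus"))[, cols]
#>               region label_class right_mm3 left_mm3 diff_mm3         z flagged
#> 4           CA1-Head   subregion     251.1    437.4   -186.3 -5.361413    TRUE
#> 22 Whole_hippocampus    combined    1684.0   2915.9  -1231.9 -6.341201    TRUE
```

Reading: the patient's right CA1 head is 186.3 mm³ smaller than the
left; in healthy controls that difference averages +11.0 mm³ with SD
36.8 mm³, so the patient sits 5.4 SD below the healthy norm — far
outside |z| ≤ 2.  All three whole-structure labels are flagged with
negative differences, so the report lateralizes the atrophy to the right
hippocampus, matching the clinical diagnosis.

Per-patient scoring from FreeSurfer-style two-column volume files is
also available from the shell:

```sh
Rscript inst/scripts/score_asymmetry.R \
  --patient-right rh.hippoSfVolumes.txt --patient-left lh.hippoSfVolumes.txt \
  --sequence drb --out report.json
```

Other entry points: `readCohort()` / `SubfieldExperiment()` for
long-format cohort tables, `buildReference()` and `symmetryScreen()` for
constructing and auditing a normative reference, `compareSequences()`
for the two-sequence protocol, and `cohortSpec()` / `simulateCohort()`
for synthetic cohorts.  See the vignette in `vignettes/` for the model,
its assumptions and the design decisions.

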