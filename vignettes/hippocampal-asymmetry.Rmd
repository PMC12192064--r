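---
title: "Normative asymmetry z-scores for hippocampal subfield volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative asymmetry z-scores for hippocampal subfield volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippasym)
```

## The model

Unilateral hippocampal pathology — sclerosis above all — shrinks
subfield volumes on one side while the other side stays near the
subject's own baseline.  `hippasym` exploits this by modelling, per
region $r$, the intra-individual right-minus-left volume difference
$d_r = V_{right,r} - V_{left,r}$.  In healthy controls $d_r$ is treated
as Gaussian with mean $\mu_r$ and standard deviation $\sigma_r$; a
patient is scored with

$$ z_r = \frac{d_r - \mu_r}{\sigma_r}, $$

and a region is called pathological when $z_r < -2$ or $z_r > 2$,
i.e. outside the central 95 % interval of the healthy asymmetry
distribution ($2\,\Phi(-2) \approx 4.55\%$ of healthy subjects flag per
region by construction).  The inequality is strict: $|z| = 2$ exactly is
not flagged.

Two assumptions do the work.  First, healthy hippocampi are symmetric
enough that $d_r$ has a stable, narrow distribution; `symmetryScreen()`
audits this on any control cohort (paired t-tests across the 22 scored
regions, Holm–Bonferroni corrected, Cohen's $d$ = mean/SD of differences
attached to significant rows).  Second, pathology is unilateral: a
bilateral process shifts both sides and can cancel in $d_r$.  The design
deliberately trades that blind spot for freedom from age/sex/head-size
adjustment, which cancels in the within-subject difference.  Detecting
bilateral disease would need per-side normative volumes from a much
larger control cohort and is out of scope.

## Regions and aggregation

The scored surface is 22 regions: 19 subfields plus three combined
labels (whole hippocampal head = 9 head subfields, whole hippocampal
body = 8 body subfields, whole hippocampus = head + body + tail, 18
members).  The hippocampal fissure — a CSF cleft, not tissue — is one of
the 19 subfields but is excluded from the whole-hippocampus sum.  The
four merged labels HEAD/BODY/TAIL/FISSURE partition the subfields and
are computed by `aggregateVolumes()` for completeness, but carry no
reference rows and are not scored.

Naming in segmentation output is notoriously inconsistent (CA3 vs
CA2/3, case and separator variants), so every entry point resolves names
through a deterministic alias layer (`resolveRegions()`); the catalogue
itself ships as an auditable JSON resource.  Member sums are always
taken in catalogue order and the whole hippocampus is formed as
head + body + tail, so derived volumes are bit-reproducible and the
head/body/whole identity is exact in floating point.

Combined labels get their own reference rows ($\mu$, $\sigma$ of the
summed difference) rather than any function of member z-scores: the sum
of member differences has its own, correlation-dependent spread, and the
reference captures it directly.

## Normative references

`packagedReference(sequence)` returns the shipped reference (n = 20
healthy controls) for either acquisition variant: the conventional T2
TSE sequence (`"T2_TSE"`) or its deep-learning-reconstructed accelerated
variant (`"T2_TSE_DRB"`).  `buildReference()` recomputes $\mu_r$,
$\sigma_r$ from any healthy cohort with both hemispheres, using the
sample SD ($n-1$ denominator — the conventional choice for small
reference cohorts) and right-minus-left orientation throughout.  A
region with zero variance is an error, not a silent pass: a zero SD
cannot standardize anyone.

Sequence tags are never mixed implicitly.  Subfield boundaries shift
subtly between reconstruction variants, so a patient is scored against
the reference of the matching sequence; cross-sequence scoring requires
`allowSequenceMismatch = TRUE`.

## The two-sequence comparison protocol

`compareSequences()` implements the paired protocol used to establish
that an accelerated sequence is volumetrically interchangeable with the
conventional one: per region and hemisphere a paired two-tailed t-test
(differences oriented B − A), Holm–Bonferroni over all tests run in the
invocation (44 with both sides; the step-down rule is capped at 1), and
Cohen's $d$ attached only to rows significant after correction.  The
default $d$ uses the pooled per-sequence SD; with strongly correlated
pairs the difference-SD convention inflates $d$ by an order of
magnitude, so the mode is explicit in the output and both are exposed in
`cohensDPaired()`.  A nonparametric screen compares per-region
cross-subject variances between sequences with a paired Wilcoxon
signed-rank test (regions as pairs); its construction is a package
convention — it is clearly separated in the output (`varianceTest`) and
can be ignored.

Statistical conventions: Wilcoxon drops zero differences before ranking
and uses midranks for ties, with the exact null for up to 25 tie-free
differences and the continuity-corrected normal approximation otherwise;
Shapiro–Wilk follows Royston's approximation for $3 \le n \le 5000$.

## The synthetic cohort generator

`simulateCohort()` draws, per healthy subject and subfield, a latent
bilateral mean $B \sim N(\mu_{base}, cv \cdot \mu_{base})$ and an
asymmetry $a \sim N(\mu_r, \sigma_r)$, split symmetrically:
right $= B + a/2$, left $= B - a/2$.  The split is a modelling choice —
only the difference distribution is identified by the normative model —
and makes $d_r$ exactly $N(\mu_r, \sigma_r)$.  A second sequence adds a
per-subfield systematic shift plus independent per-hemisphere Gaussian
noise.  Patients multiply affected-side subfields by
severity-interpolated profile factors, $1 + s(f_r - 1)$; the sclerosis
profile $f_r$ is the right/left ratio of the packaged worked example
(e.g. CA4-body 0.393) and the edema profile is a uniform 1.2
enlargement, a magnitude consistent with the up-to-18 % asymmetries
reported in temporal lobe epilepsy.  Volumes are truncated at zero with
a warning; at default parameters truncation is essentially impossible.

Defaults are calibrated to the packaged summaries: asymmetry parameters
from the conventional-sequence normative rows, base means from the
per-region mean volumes, sequence effects from the right-hippocampus
mean-difference/SD columns.  The between-subject CV defaults to 0.10 —
a free knob, since cross-subject volume SDs are not part of the packaged
summaries.  Subfield asymmetries are drawn independently across regions,
matching the per-region univariate normative model; real asymmetries are
likely correlated within subject, which the generator (and the model)
ignores.  Consequently the simulated combined labels are *less*
variable relative to their reference rows than real ones, and pipeline
tests on synthetic data validate the machinery and its calibration, not
the biological realism of cross-region dependence.

```{r example}
spec <- cohortSpec(nHealthy = 20,
                   patients = data.frame(pathology = "HS_right", severity = 1),
                   seed = 7)
cohort <- simulateCohort(spec)
cohort
```

## Numerical and design notes

* **Degenerate inputs.** Constant paired differences give $t = 0, p = 1$
  (zero mean) or $p = 0$ with a warning (nonzero mean); all-zero
  Wilcoxon differences and constant Shapiro–Wilk inputs are errors; a
  spec with all spread parameters zero yields an exactly symmetric
  cohort, which `buildReference()` then rejects for zero variance.
* **Reproducibility.** Generator output is byte-identical for identical
  spec + seed.  CSV reports round volumes and z to one decimal and
  p-values to four; JSON keeps full precision.
* **Worked-example quantization.** The packaged example's reported
  z-values were computed from unrounded source volumes.  Recomputing
  from the 1-decimal volumes reproduces 21 of 22 reported z at one
  decimal; for CA4-body the rounded inputs give $-62.8$ mm³ where
  $-62.7$ was reported, moving $z$ from $-5.246$ ($\to -5.2$ as
  reported) to $-5.254$ ($\to -5.3$).  The package computes from
  volumes and documents the 0.05-z quantization rather than
  special-casing it.
* **Lateralization** is descriptive only (all flagged differences
  negative → right smaller; all positive → left smaller; otherwise
  indeterminate); no claim about seizure origin is made.
* **Problem sizes.** The test suite validates null coverage with 1e5
  simulated subjects, normative recovery at n = 2000, and shift
  detection with 200 replicates of 36-subject cohorts — sizes at which
  Monte-Carlo error is far below the tested tolerances while the whole
  suite stays fast.

## Limitations

Bilateral pathology is invisible by design; merged labels are reported
but unscored; the packaged references describe two specific acquisition
variants on one scanner class and do not transfer to other protocols
without rebuilding; and the generator's independence and uniform-edema
assumptions are simplifications, as discussed above.
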