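---
title: "Methods: NEWS2-L risk scoring and its evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NEWS2-L risk scoring and its evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncoscore)
```

## The clinical problem

Syncope — transient loss of consciousness from cerebral hypoperfusion with
rapid onset and spontaneous recovery — is a common reason for emergency
medical service (EMS) calls, and most episodes are benign. A minority,
however, herald a serious adverse event: death within 48 hours, the need
for advanced life support (intubation, external pacing, vasoactive drugs)
at the scene or en route, or intensive-care admission. In the prehospital
setting the crew has only vital signs, an ECG and point-of-care tests to
work with, so risk stratification must be built from exactly those inputs.

This package implements and evaluates two such instruments:

* **NEWS2** — the National Early Warning Score 2, a seven-parameter
  weighted vital-sign score (respiratory rate, oxygen saturation,
  supplemental oxygen, temperature, systolic blood pressure, heart rate,
  consciousness), each parameter contributing 0–3 points (supplemental
  oxygen 0 or 2), total 0–20. A total above 5, or any single parameter at
  3, flags an urgent clinical review; a total above 7 flags a
  critical-care review.
* **NEWS2-L** — the composite obtained by adding the numeric point-of-care
  venous lactate value (mmol/L, a marker of tissue hypoperfusion) to the
  NEWS2 total. The sum is unitless and deliberately simple: it can be
  computed at the bedside without a calculator.

Around these sit the evaluation machinery (2×2 diagnostic metrics with
confidence intervals, ROC/AUC with DeLong variance and paired curve
comparison, Youden cut-off selection) and a seeded synthetic cohort
generator, so the whole pipeline can be exercised and tested without
patient-level data, which the source study did not deposit.

## Scoring conventions

**Band-edge resolution.** The rubric is stated at fixed resolutions:
integers for respiratory rate, saturation, blood pressure and heart rate,
one decimal for temperature. Inputs are rounded half-up to that resolution
before banding (with a tiny relative epsilon so a binary value like
`38.05`, stored as 38.049999…, still rounds to 38.1). Consequently the
apparent gaps between bands (38.0 → 38.1) cannot be hit, and the bands
partition each input domain — a property the test suite checks over full
grids.

**Consciousness.** The study assessed mental state with the Glasgow Coma
Scale and defined confusion as GCS < 15. The package therefore maps
GCS 15 → alert (0 points) and any GCS below 15 → 3 points, equivalent to
the AVPU mapping A → 0 and V/P/U → 3, without distinguishing V from P
from U (the rubric gives them one weight). Exactly one representation
(GCS or AVPU) must be supplied; new-onset confusion en route is
represented by the caller passing GCS < 15 — no temporal logic is
modelled.

**Saturation scale 2.** The alternative saturation rubric applies only to
patients with diagnosed hypercapnic respiratory insufficiency. That is
clinical context, not something inferable from the saturation value, so it
is an explicit per-patient flag (`spo2_scale`), defaulting to scale 1. On
scale 1 the saturation sub-score is independent of oxygen therapy; oxygen
enters only through the separate supplemental-oxygen sub-score.

**Lactate range.** The point-of-care device measures 0.8–21.7 mmol/L.
Values outside that range are a device property, not a definition of the
composite, so they are accepted with a warning and an explicit
`lactate_in_range = FALSE` flag rather than rejected — heavy-tailed
synthetic cohorts remain scorable.

**Missing vitals.** A single observation with a missing vital is an error
naming the field; a cohort table is scored with incomplete rows excluded
and counted (`attr(x, "n_excluded")`), mirroring the study's exclusion of
incomplete first vital-sign sets.

## Diagnostic accuracy

Classification at a cut-off uses `score >= cutoff` as test-positive.
Reported cut-offs are midpoints between adjacent distinct observed score
values, so on real data ties cannot occur; the convention matters only for
synthetic edge cases.

From the 2×2 table the panel computes prevalence, Se, Sp, PPV, NPV,
LR+ = Se/(1−Sp), LR− = (1−Se)/Sp, the diagnostic odds ratio
OR = (TP·TN)/(FP·FN), and accuracy DA = (TP+TN)/n. The source study does
not state its confidence-interval methods, so the package uses standard
diagnostic-accuracy practice and documents it:

* **Wilson score intervals** for all proportions (Se, Sp, PPV, NPV, DA,
  prevalence). Their near-nominal small-sample coverage is verified by
  simulation in the test suite (empirical 95% coverage within
  [0.93, 0.97] at n = 50 across low, middle and high proportions).
* **Log-normal intervals** for the likelihood ratios, with
  `var(log LR) = 1/a − 1/(a+c) + 1/b − 1/(b+d)` over the two proportions
  forming the ratio.
* **Woolf log intervals** for the odds ratio. With an empty cell the OR
  (only) switches to the Haldane–Anscombe +0.5 correction and the report
  carries a `zero_cell` flag, keeping degenerate inputs finite and
  auditable.

Point estimates are matched to the published panel exactly; interval
methods are matched qualitatively (the study's are unstated).

**Reconstructing a published panel.** `reconstruct_contingency()` inverts
printed Se/Sp back to counts with half-up rounding
(`tp = round(se·n_pos)`, `tn = round(sp·n_neg)`); `reproduce_table3()`
applies this to the published NEWS2-L panel (group sizes 21/340, 51/310,
31/330 for mortality, advanced life support, ICU) and recomputes every
derived metric at printed rounding (percentages to one decimal, ratios to
two). All mortality and ICU metrics match exactly. One published cell is
internally inconsistent: the advanced-life-support OR is printed as 18.26,
while the counts implied by its own printed prevalence/Se/Sp
(tp 47, fp 119, fn 4, tn 191) give 18.86. Every other metric in that
column matches those counts, so the package reports the implied 18.86 with
`match = FALSE` rather than tuning the rounding to force agreement.

**Sample size.** The enrolment helper uses the normal-approximation
formula `n = ceil(z² p(1−p) / margin²)` with optional loss inflation
`1/(1−loss)`; at an expected event proportion of 5.93%, a 2.5% margin and
95% confidence it evaluates to 343 cases, the study's stated figure.

## ROC analysis

The empirical ROC curve uses midpoints between adjacent distinct score
values as candidate thresholds, groups ties at single operating points,
and anchors at (0,0) and (1,1). Its trapezoidal area equals the
Mann–Whitney pair-counting AUC — the probability a random positive
outranks a random negative, ties counting one half — and the package
computes both through separate code paths (trapezoid vs midranks) that
the tests require to agree to 1e−12.

The AUC variance and the paired curve comparison use DeLong structural
components: the placement of each positive among the negatives and vice
versa, computed via midranks in O(n log n). The source study compares
same-cohort AUCs without naming a test; the paired DeLong test is the
standard choice for that design and is what the package implements
(cross-checked against an independent implementation in the tests). With
perfect separation the component variance is zero; the interval collapses
to the point and is flagged `degenerate` rather than fabricating width.

The operating cut-off maximises Youden's J = Se + Sp − 1 by exhaustive
scan over all candidate midpoints (plus one half-unit beyond either
extreme). Ties are broken toward the **lower** cut-off, i.e. toward
sensitivity: in a triage context a missed death costs more than
over-triage, consistent with the emphasis on negative predictive value in
this setting. Score direction is fixed as higher = more severe; there is
no automatic direction detection.

## The synthetic cohort generator

The generator emulates the published study's two-class structure: a
Bernoulli 48-h mortality label (5.8%), then class-conditional vitals,
lactate and age drawn from distributions fitted to the published
survivor/non-survivor medians and IQRs, then secondary outcomes from their
published conditional rates (advanced life support: 76.2% of
non-survivors, 10.3% of survivors; ICU: 52.4% vs 5.9%; admission: 100% vs
34.1%). ECG rhythm is sampled from the published per-class frequencies but
feeds no downstream computation.

**Families.** Published tables give only median (IQR), not families. The
package uses lognormal for positive right-skewed variables (respiratory
rate, lactate) — fitted in closed form, `meanlog = log(median)`,
`sdlog = log(q75/q25)/(2·Φ⁻¹(0.75))`, which matches the median and the
IQR ratio exactly — and truncated normals with hard physiological bounds
for the rest (saturation ≤ 100, temperature, blood pressure, heart rate,
age), fitted by least-squares quantile matching. Because several published
IQRs are markedly asymmetric (non-survivor heart rate 82 (40–96)), the
median carries four times the weight of each quartile in that fit: the
median is the primary reported statistic, so a skewed IQR compromises the
quartiles rather than the centre.

**Consciousness.** The survivor GCS row is the degenerate 15 (15–15) and
the non-survivor upper quartile sits on the hard bound 15, both infeasible
for a continuous quantile fit, so GCS is modelled directly: survivors are
alert (GCS 15) with probability 0.95 with a small confusion tail;
non-survivor GCS is a Normal(14, 9) rounded to integer and clipped to
[3, 15], which reproduces the published median 14, lower quartile ≈ 8
(target 7) and upper quartile 15.

**Unreported parameters.** Supplemental-oxygen rates and the survivor
confusion rate are not published. They were fixed once at clinically
plausible values — survivors 8% on oxygen, non-survivors 60%, survivor
confusion 5% — under which the *computed* NEWS2 class margins line up
with the published ones (median 3 (1–5) vs 11 (6–15)). The NEWS2 is never
sampled: it is always computed from the generated vitals through the
scoring module, so the deterministic score/vital relationship is
preserved and the published NEWS2 row serves as a calibration check, not
a sampling target.

**Correlation.** Between-vital correlations are not reported. Variables
are conditionally independent given the class, except saturation and
respiratory rate, which share a Gaussian copula (ρ = −0.4, configurable)
so severe records look clinically coherent (hypoxic patients breathe
fast). The class-conditional independence already reproduces every
published margin; the copula is cosmetic and documented as such.

**What passing tests show — and don't.** At n = 10,000 the generator's
class medians of NEWS2 and lactate fall within 10% of the published
values, outcome prevalences within three binomial standard errors of
5.8%/14.1%/8.6%, and the mortality discrimination ordering
NEWS2-L > NEWS2 > 0.5 holds. The published AUCs (0.948 mortality, 0.842
advanced life support, 0.809 ICU) belong to the real 361-patient cohort,
which is not deposited; on synthetic cohorts they are qualitative
calibration references only, and the generator's AUCs (≈ 0.97/0.94/0.88
for NEWS2-L/NEWS2/lactate against mortality) are somewhat optimistic
because conditional independence understates the real data's redundancy
between vitals. Passing calibration therefore demonstrates that the
pipeline is correct and the generator matches the published margins — not
that real prehospital data would reproduce the published operating
characteristics. Repeated observations per patient, EMS time intervals
and medium-term mortality are deliberately not modelled.

## Numerical choices

* Half-up rounding (`floor(x + 0.5)` with a relative epsilon) wherever the
  published tables imply it: rubric banding and Se/Sp inversion.
* The truncated-normal quantile fit runs Nelder–Mead on (mean, log sd) to
  relative tolerance 1e−12, started from the sample-quantile moment guess.
* DeLong degenerate variance (perfect separation) collapses the interval
  and sets a flag; the paired test returns p = 1 for a zero difference
  with zero variance.
* The generator restores the caller's RNG state on exit; identical specs
  (including the seed, which is part of the spec) give byte-identical
  CSVs.
* Internal dual-route identities (trapezoid vs midrank AUC, count-based
  vs Bayes-form PPV, OR vs the Se/Sp cross-product) are held to 1e−12 in
  the tests; Monte-Carlo checks use 1,000 replicate null simulations for
  the DeLong type-I error, 2,000 binormal replicates for interval
  coverage, and n = 10,000 cohorts for generator calibration — sizes at
  which the binomial noise on the checked rates is well inside the stated
  bands.

## Limitations

* The generator reproduces published *margins*; joint structure beyond
  the single copula pair is simplified, so synthetic AUCs overstate real
  discrimination.
* Confidence-interval methods for the published panel are an informed
  choice, not a reconstruction of the study's (unstated) methods.
* No bootstrap AUC intervals, partial AUC, time-dependent ROC,
  calibration statistics or multiple-testing correction across outcomes —
  none were used in the source analysis.
* The escalation flags implement thresholds only; the clinical response
  pathways behind them are out of scope.
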