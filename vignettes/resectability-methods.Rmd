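---
title: "Methods: multimodal resectability prediction, agreement and paired non-inferiority"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal resectability prediction, agreement and paired non-inferiority}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectability)
```

## The scientific problem

In advanced tubo-ovarian carcinoma the central preoperative question is
whether complete cytoreduction is achievable. The ESMO-ESGO consensus
criteria reduce that judgment to eight anatomical involvement markers
(small intestine, small-bowel mesentery root, stomach/duodenum, pancreas,
non-resectable liver metastases, hepatic hilum and celiac trunk,
non-resectable abdominal lymph nodes, non-resectable extra-abdominal
metastasis): a patient is predicted **non-resectable** if any criterion is
met, **resectable** if none is. Three imaging modalities (ultrasound, CT,
whole-body diffusion-weighted MRI) and intraoperative surgical exploration
can each score the eight criteria; the reference standard is the surgical
outcome itself — R0 (no macroscopic residuum) and R1 (residuum ≤ 1 cm)
count as resectable, R2 (residuum > 1 cm, or cytoreduction not attempted)
as non-resectable. Patients whose R2 outcome reflects frailty
(inoperability) rather than tumor extent carry no information about the
discrimination task and are excluded.

This package implements that pipeline end to end: the per-patient data
model and cohort flow, the OR-aggregation rule, single-operating-point
accuracy metrics with confidence intervals, site-level percent agreement,
paired non-inferiority tests for correlated AUCs and F1 scores,
Obuchowski-McClish sample-size design, and a synthetic cohort generator
that makes every stage testable without patient-level data.

## Data model and cohort flow

A cohort is one row per patient in a wide CSV:
`patient_id, mri_available, outcome_residual, outcome_r2_reason, approach,
excl_flags, {us|ct|mri|surg}_c1..c8`. Criterion cells are **ternary**
(0 / 1 / NA). Although imaging reads are conceptually binary, partially
assessed patients exist in practice; the package's rule is that a patient
with some criteria unassessed and no criterion present is **indeterminate**
(resectability cannot be ruled out), and such records are dropped from
metric computation with a logged count. Records are removed by
`apply_eligibility()` (any of seven exclusion codes),
`exclude_inoperable()` (R2 for frailty) and `complete_case_subset()`
(records lacking a required modality), in any order — the operations
commute, which the test-suite asserts.

## Accuracy metrics

With non-resectable disease as the positive class, `point_metrics()`
computes Se, Sp, PPV, NPV, accuracy and
$F_\beta = (1+\beta^2)\,PPV \cdot Se / (\beta^2 PPV + Se)$ for
$\beta \in \{1, 0.5\}$. For a binary (single-threshold) test the empirical
ROC has one interior operating point, so the trapezoidal AUC equals
balanced accuracy, $(Se+Sp)/2$; the suite confirms this against a generic
empirical-ROC routine on random confusion tables.

Proportion intervals default to the **Wilson score** method. This choice is
empirical: Wilson reproduces exactly (at 1-decimal rendering) the published
sensitivity/specificity/PPV/NPV/accuracy intervals of the study tables this
pipeline models, while Clopper-Pearson (offered as an option) does not.
AUC intervals use the binary-score DeLong form,
$SE^2 = [Se(1-Se)/n_1 + Sp(1-Sp)/n_2]/4$, with Hanley-McNeil as an
alternative. No standard closed form (Wald, DeLong-binary, Hanley-McNeil)
reproduces the AUC intervals printed in the source tables, so AUC intervals
are flagged as method-dependent in reports and excluded from exact checks.

Percentages render half-up at 1 decimal and AUCs at 3 decimals, matching
clinical-table convention; base R's half-to-even `round()` is deliberately
not used for display.

## Agreement

`crosstab_site()` cross-tabulates an imaging modality against surgical
exploration per criterion (or at the patient-level OR label), and
`agreement_metrics()` computes overall/positive/negative percent agreement.
The default convention conditions PPA/NPA on the reference (surgical
exploration); the symmetric "specific agreement" convention
($PPA = 2a/(2a+b+c)$) is provided because published supplements do not
always state which was used — the two coincide for OPA. Published reports
often print only the margins and OPA of these tables;
`reconstruct_joint_from_margins()` inverts that triple to the unique
integer 2×2 table when one exists (uniqueness is verified by exhaustive
search in the tests).

## Paired non-inferiority

Two modalities read the same patients, so their AUC estimates are
correlated. The package tests
$H_0\colon AUC_A - AUC_B \le -\Delta$ against one-sided alternatives with a
shifted Z statistic, $Z = (\hat\delta + \Delta)/SE_{diff}$, with
$\Delta = 0.05$ and one-sided $\alpha = 0.05$ by default. $SE_{diff}$ comes
from the paired structural components of the DeLong decomposition: the
per-subject placement values of each modality are differenced within each
reference class and their sample variances summed across classes. For
two-valued scores the placements take closed forms
($V_{10} = (1+Sp)/2$ for a detected case, $Sp/2$ for a missed one, and
symmetrically for controls), so the whole statistic reduces to a function
of the 2×2×2 cross-classification. The cited variance formula for paired
AUC comparisons is not reprinted in the source text; this DeLong-component
interpretation is therefore validated by simulation calibration (below) and
by brute-force oracle tests that enumerate all placement pairs on small
pairings, rather than against the published P values — which are in any
case unreproducible without the patient-level pairing.

Paired F1 scores are compared with the same shifted one-sided Z. Two
variance engines are provided: a delta-method variance over the multinomial
vector of the eight joint cells (label A × label B × reference), and a
patient-level paired bootstrap (default, 2000 resamples), which is more
robust when cells are small. The engines agree within 15% relative SE on
moderate samples; the bootstrap is verified against exhaustive enumeration
of all $6^6$ resamples of a 6-patient toy. Identical predictions give
$SE_{diff} = 0$; by convention this degenerate case is declared
non-inferior with the p-value at the machine floor and a logged note.

## Synthetic cohort generator

`sim_config()`/`simulate_cohort()` generate cohorts with the structure the
analysis assumes. Per patient: a true resectability class
(prevalence 48/167 by default); given non-resectability, a true
site-involvement vector drawn site-independently and truncated so at least
one site is involved (the OR rule defines the class); per-assessor observed
criteria via a shared latent-Gaussian threshold model; a surgical outcome
consistent with the class (R2 split 23:39 between suboptimal-after-effort
and not-feasible-at-laparoscopy; R0:R1 = 145:17 among resectable); an
18/242 inoperable overlay; and 60/242 WB-DWI/MRI missingness. All numeric
defaults are the modeled study's observed rates.

Two calibrations make the generator quantitative:

* **Site margins.** True per-site probabilities are solved by fixed-point
  iteration so the truncated marginal frequencies match the
  surgical-exploration column of the modeled population (the closest
  available proxy for true involvement).
* **Operating points.** For each assessor a common per-site sensitivity and
  false-positive rate are solved (moment matching, exact under the
  conditional-independence site model) so the OR-aggregated patient-level
  Se/Sp equal the observed operating points (e.g. ultrasound 72.9%/94.1%).
  A diagnostic error is raised when a requested patient-level sensitivity
  is unreachable under a per-site sensitivity cap.

Between-modality dependence uses a single shared latent Gaussian per
patient-site; thresholding preserves each assessor's marginals while one
parameter (`inter_modality_rho`) spans independence to near-duplication.
The default is 0.5 — moderate positive dependence, as expected of
modalities reading the same lesions; nothing in the published margins
identifies this parameter. Surgical exploration is simulated with its own
high-but-imperfect operating point (97.9%/92.4%), not as truth.

What the generator does **not** emulate: center effects, FIGO-stage
structure, per-site differences in detection difficulty (a common per-site
error is calibrated to the patient-level operating point, not to per-site
data, which the source does not print), and any dependence structure beyond
the one-parameter latent family. Passing tests therefore demonstrate
internal consistency and statistical calibration under this model, not
performance on real patients.

## Calibration experiments and their results

`experiment_type1_power()` places both modalities at the ultrasound
operating point, shifts modality A's sensitivity by $2\delta$ so the true
AUC difference is exactly $\delta$, and measures rejection rates. Under
conditional independence at n = 167 (prevalence 48/167), the paired AUC
test holds its one-sided level at the non-inferiority boundary
($\delta = -0.05$): the rejection rate over 2000 replicates lies within
±2 Monte-Carlo SE of 0.05, and rejection is monotone in $\delta$. These
problem sizes (2000 replicates at the boundary, 600 along the grid) were
chosen to give Monte-Carlo SEs of about 0.5–1 percentage point.

Two caveats the experiments surfaced, kept as documented behavior rather
than hidden:

* Under conditional independence, power at $\delta = 0$ and n = 167 is only
  ≈ 0.29 — the 5% margin is small relative to $SE_{diff}$ at this size.
  Rejection exceeds 0.5 only under strong inter-modality dependence
  (ρ = 0.9 gives ≈ 0.59), consistent with the high site-level concordance
  (84.7–97.9%) the modeled study observed between modalities. A significant
  non-inferiority verdict at this design size is thus itself evidence of
  strongly correlated reads.
* At ρ = 0.9 the test's type-I rate inflates mildly (≈ 0.077): with nearly
  duplicated reads the variance estimate becomes near-degenerate and the
  normal approximation is strained. The degenerate limit (identical reads)
  is handled by the explicit convention above.

## Sample-size design

`required_n()` implements the Obuchowski-McClish binormal calculation for
non-inferiority of two correlated AUCs:
$n_1 = (z_{1-\alpha} + z_{1-\beta})^2 \cdot 2V(A)(1-\rho)/\Delta^2$
diseased subjects, scaled to total patients by the allocation ratio, with
$V(A) = 0.0099\,e^{-a^2/2}\,(5a^2 + 8 + (a^2+8)/R)$ and
$a = \Phi^{-1}(A)\sqrt{2}$. The design anchors (planning AUC 0.78, 5%
margin, one-sided α 0.05, power 0.90) are the modeled study's; the
correlation ρ and allocation were not published, so both are exposed
parameters (defaults ρ = 0.5 and the observed allocation 119:48). Over the
plausible paired-design range ρ ∈ [0.3, 0.96] the required total runs from
1608 down to 92 patients and brackets the historical planning figures of
166 and 99, which correspond to ρ ≈ 0.93 and ≈ 0.96 under this
parameterization — exact reproduction is out of reach without the original
ρ. The binormal variance is conservative relative to a two-valued score at
the ultrasound operating point (V(0.835) ≈ 0.082 vs ≈ 0.055), so
formula-based power sits a few points below the simulated power of the
binary-score test; the suite asserts the direction and a 12-point bound of
this comparison.

## Numerical conventions and degenerate inputs

* Zero-denominator metrics (e.g. PPV with no predicted positives) are `NA`
  with a warning, never 0.
* Wilson bounds at x = 0 and x = n are snapped to exactly 0 and 1 (the
  score bound is exact there; floating point would otherwise land an ulp
  off).
* All randomness is seeded explicitly and drawn on a private RNG stream;
  the caller's `.Random.seed` is untouched. Same configuration and seed
  give byte-identical cohort CSVs.
* Bootstrap resamples on which a statistic is undefined are skipped and
  counted; fewer than 100 replicates are rejected.
* `reconstruct_joint_from_margins()` errors when no consistent integer
  table exists (parity or negative-cell violations).

## The counts fixture

`inst/extdata/study_counts_fixture.csv` is a deterministic 279-record
synthetic cohort (not patient data) built by `build_counts_fixture()` so
that every published marginal tally is reproduced exactly: the cohort flow
279 → 242 → 224 → 167, the outcome distribution (R0/R1/R2 = 145/17/80; R2
reasons 23/39/18), WB-DWI/MRI availability (182), the per-site involvement
counts of all four assessors, and the per-modality confusion counts in both
analysis cohorts. Joint distributions beyond those margins (e.g. which
patients two modalities jointly miss, and the per-code breakdown of the 37
exclusions) are not published and are filled deterministically; quantities
that depend on them — notably the fixture's paired non-inferiority
P values — are illustrative, not reproductions.

## Known limitations

* The AUC confidence intervals of the modeled tables cannot be reproduced
  by any standard closed form; the method used there is unknown.
* The paired-AUC variance is an interpretation of the cited method
  (validated by calibration), not a verified transcription of it.
* Patient-level pairing is not deposited, so published non-inferiority
  P values are plausibility anchors only.
* The generator's conditional-independence site model and single-parameter
  dependence family are conveniences, not estimates.
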