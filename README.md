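# resectability

Analysis pipeline for paired diagnostic-accuracy studies of preoperative
resectability assessment in advanced tubo-ovarian carcinoma.

## The problem

Before cytoreductive surgery, clinicians must predict whether a tumor is
completely resectable. The ESMO-ESGO consensus criteria reduce this to
eight anatomical involvement markers (small intestine, small-bowel
mesentery root, stomach/duodenum, pancreas, non-resectable liver
metastases, hepatic hilum/celiac trunk, non-resectable abdominal lymph
nodes, non-resectable extra-abdominal metastasis): disease at **any** site
predicts non-resectability. Ultrasound, CT, whole-body diffusion-weighted
MRI (WB-DWI/MRI) and intraoperative surgical exploration each score the
eight criteria; the reference standard is the surgical outcome (R0/R1 =
resectable, R2 = non-resectable; patients inoperable for frailty are
excluded).

The package implements, for this design:

* the per-patient data model, CSV interchange, validation, eligibility and
  subcohort rules (`read_cohort`, `apply_eligibility`,
  `exclude_inoperable`, `complete_case_subset`);
* the OR classification rule and reference derivation
  (`classify_prediction`, `derive_reference`, `site_frequency_table`);
* single-operating-point accuracy metrics — for a binary test the AUC is
  balanced accuracy, AUC = (Se+Sp)/2 — with Wilson score intervals for
  proportions and a binary-score DeLong interval for the AUC
  (`confusion`, `point_metrics`, `wilson_interval`, `auc_interval`);
* overall/positive/negative percent agreement between imaging and surgical
  exploration, including an integer solver that reconstructs a 2×2 table
  from published margins and OPA (`crosstab_site`, `agreement_metrics`,
  `reconstruct_joint_from_margins`);
* paired non-inferiority tests with a shifted one-sided Z,
  Z = (δ̂ + Δ)/SE, for correlated AUCs (paired DeLong structural
  components) and paired F1 scores (delta-method or bootstrap variance)
  (`paired_auc_noninf`, `paired_f1_noninf`, `bootstrap_paired`);
* Obuchowski-McClish sample size for non-inferiority of two correlated
  AUCs (`samplesize_spec`, `required_n`, `power_at_n`);
* a calibrated synthetic cohort generator for validation
  (`sim_config`, `simulate_cohort`, `experiment_type1_power`).

The numbered scripts under `analysis/` drive the full workflow and write
their tables under `results/`; `run_analysis()` produces the whole bundle
from one configuration.

## Worked example

Score ultrasound against the surgical outcome in the 167-patient
complete-case subcohort of the packaged counts fixture:

```r
library(resectability)

cohort <- read_cohort(counts_fixture_path())
c242 <- apply_eligibility(cohort)$cohort        # 279 recruited -> 242 analyzable
c167 <- complete_case_subset(exclude_inoperable(c242), c("us", "ct", "mri"))

point_metrics(confusion_cohort(c167, "us"))
#> <metric_set>
#>   se   72.9% (59.0-83.4)
#>   sp   94.1% (88.4-97.1)
#>   ppv  83.3% (69.4-91.7)
#>   npv  89.6% (83.0-93.8)
#>   acc  88.0% (82.2-92.1)
#>   f1   77.8%
#>   f0.5 81.0%
#>   auc  0.835 (0.769-0.901)
```

Ultrasound detects 72.9% of non-resectable tumors while calling only 5.9%
of resectable ones non-resectable (specificity 94.1%); its
single-operating-point AUC is 0.835. Compare two modalities on paired
data with a 5% non-inferiority margin:

```r
pairs <- paired_from_cohort(c167, "us", "ct")
paired_auc_noninf(pairs, margin = 0.05)
#> <noninf_result> AUC: A=0.835 B=0.754 delta=+0.081 (margin 0.05)
#>   Z=5.308 one-sided p=5.54e-08 -> noninferior [analytic variance]
```

A positive δ̂ with p < α rejects the hypothesis that ultrasound is worse
than CT by more than 5 AUC points. (The fixture's joint cells are a
deterministic fill consistent with the published margins, so paired
P values on the fixture are illustrative.)

Plan a new study:

```r
required_n(samplesize_spec(auc_both = 0.78, margin = 0.05, rho = 0.93))
#> [1] 161
```

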