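# uremicomics

An R analysis pipeline for integrated serum metabolomics and proteomics
of end-stage kidney disease (ESKD) patients undergoing hemodialysis.

## The problem

Hemodialysis clears metabolic waste from the blood of ESKD patients
incompletely: many uremic solutes stay elevated even immediately after a
session, and some of them (e.g. homocysteine, taurine) are candidate
cardiotoxins. Given a three-arm serum cohort — healthy controls (CTRL),
patients before (PRE) and after (POST) one dialysis session — the
pipeline answers, feature by feature: *is it elevated in ESKD, and does
dialysis actually remove it?*

The core bookkeeping is a tri-category classification over the three
contrasts (Welch's t on log2 intensities for PRE/CTRL and POST/CTRL, a
paired t within patients for POST/PRE; BH-adjusted q-values):

- **Category I** — elevated pre-dialysis (FC ≥ 2, p < 0.05, q < 0.05 vs
  CTRL) *and* cleared (POST/PRE drop ≥ 2-fold, p < 0.05);
- **Category II** — elevated but *not* cleared: the persistent uremic
  solutes;
- **Category III** — decreased in ESKD vs healthy.

Around it: LC-MS feature QC (CV ≥ 50% over pooled QC, sample/blank ≤ 5,
S/N ≤ 3, peak width < 6 scans are removed), identity confirmation
against reference standards (≤ 1 ppm positive / ≤ 2 ppm negative mode vs
the theoretical adduct m/z, RT window 2 min, sqrt-intensity cosine MS2
score ≥ 0.7), quantile-normalized TMT protein quantification (FC > 1.5,
p < 0.05), hypergeometric pathway over-representation, a
metabolite–protein disease interactome with one-hop neighbors, and
four-parameter logistic IC50 fitting with concentration scaling. A
synthetic-data module generates every input with known ground truth.

## Worked example

```r
library(uremicomics)

lib    <- generate_reference_library(seed = 1)       # 21 serum standards
cohort <- generate_cohort(synth_config(seed = 1), library = lib)
qc     <- apply_feature_filters(cohort$table, filter_thresholds())
rec    <- run_differential(normalize_intensities(qc$table))
calls  <- classify_features(rec)
summarize_categories(calls)
```

```
$counts
   I   II  III none
 160  110   44 1686

$total_changed
[1] 314

$fractions
   I   II  III
51.0 35.0 14.0
```

314 of 2,000 simulated features are changed; 51.0% of the elevated ones
are cleared by dialysis (category I), 35.0% persist (category II), and
14.0% are decreased in ESKD (category III) — matching the planted
160/110/44 exactly (100% recovery at the default noise level). For
reference, the published cohort counts 697/470/186 summarize to
51.5 / 34.7 / 13.7% of 1,353 changed features, which
`summarize_categories(category_calls_from_counts(697, 470, 186))`
reproduces.

The full workflow, stage by stage with narrated output, lives in
`analysis/01_simulate.R` … `analysis/07_cytotoxicity.R` (run them in
order from the repository root; outputs land under `results/analysis/`).
`run_pipeline(pipeline_config(seed = 1))` runs the same stages in one
call and writes a run directory with per-stage TSVs, a JSON summary and
a log.

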