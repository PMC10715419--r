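---
title: "Methods: an integrated serum metabolomics + proteomics pipeline for hemodialysis cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated serum metabolomics + proteomics pipeline for hemodialysis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uremicomics)
```

## The scientific problem

End-stage kidney disease (ESKD) leaves the kidney unable to clear
metabolic waste; hemodialysis filters the blood but does so incompletely
and unselectively. Which circulating small molecules and proteins remain
elevated *despite* dialysis — the persistent uremic solutes — is the
central question this pipeline addresses. The study design it models is a
three-arm serum cohort: healthy controls (`CTRL`, n = 10) and a matched
group of 10 ESKD patients sampled immediately before (`PRE`) and after
(`POST`) one dialysis session, profiled by untargeted LC-MS metabolomics
and 15-channel TMT proteomics, with pooled QC injections and blank
injections alongside.

The pipeline's stages mirror the analysis a practitioner would run:

1. **Feature QC** (`apply_feature_filters`) — remove unreliable LC-MS
   features.
2. **Normalization and differential testing** (`normalize_intensities`,
   `run_differential`) — per-feature fold changes, p-values and
   Benjamini–Hochberg q-values for PRE/CTRL, POST/PRE (paired) and
   POST/CTRL.
3. **Dialysis-clearance classification** (`classify_features`,
   `summarize_categories`) — category I (elevated in ESKD, cleared by
   dialysis), II (elevated, persistent), III (decreased in ESKD).
4. **Identity confirmation** (`identify_features`) — candidate features
   against a reference-standard library by accurate mass, retention time
   and MS2 similarity.
5. **TMT proteomics** (`quantile_normalize`,
   `test_differential_proteins`).
6. **Pathway over-representation** (`enrich_all`) and the
   **metabolite–protein disease network** (`build_disease_network`).
7. **Cytotoxicity** (`fit_four_param_logistic`, `scale_concentration`) —
   dose–viability curves for candidate uremic cardiotoxins and
   concentration scaling of reference ranges.

Every input can be simulated with known ground truth by the
`generate_*` family, so the full pipeline is testable end to end without
any raw mass-spectrometry data.

## Feature-level quality control

Four removal rules are applied in a single conjunctive pass (a feature is
dropped if *any* rule fires), with boundary semantics taken verbatim from
the processing conventions they encode:

| rule | statistic | removed when | default |
|---|---|---|---|
| intensity stability | CV (%) over pooled-QC injections | CV ≥ `cv_max` | 50 |
| blank contamination | mean sample / mean blank intensity | ratio ≤ `blank_ratio_min` | 5 |
| signal quality | chromatographic S/N | S/N ≤ `snr_min` | 3 |
| peak shape | peak width (scans) | width < `peak_width_min` | 6 |

Notes on the edges: CV exactly 50 is removed, peak width exactly 6 is
retained. CV uses the sample (n−1) standard deviation and is computed
over QC injections by default (the pooled QC is the declared technical
replicate; `cv_source = "biological"` is available). A zero blank mean is
floored at 10⁻³ × the smallest positive intensity in the table so that
blank-absent features survive with a large finite ratio rather than
dividing by zero.

## Normalization, differential testing, classification

**Median normalization.** Every column is rescaled so its median nonzero
intensity equals the target, defined as the median of the per-column
medians of the biological (CTRL/PRE/POST) columns. QC and blank columns
are rescaled but never contribute to the target. The median-of-medians
target is robust to any single aberrant column; because it is
data-estimated, rescaling one column changes the output only through one
global factor. The pipeline normalizes *after* the blank-ratio filter,
since rescaling blanks to the sample median would defeat that filter.

**Tests.** Log2 intensities (zeros replaced by half the smallest nonzero
value of the table — a documented pseudo-count) are compared by Welch's
t-test for PRE/CTRL and POST/CTRL, and by a paired t-test for POST/PRE,
pairing columns by patient. The matched design is the reason the paired
test exists: each patient's PRE and POST samples share a subject
baseline, and differencing removes it. Fold changes are differences of
group means of log2 values, i.e. geometric-mean ratios, so a reported
"7.5-fold" is a ratio of geometric means. Groups with zero variance
(noiseless synthetic data) take the exact degenerate p-value — 1 when
means agree, 0 otherwise — so that noiseless recovery is well defined.
Features with fewer than `min_n = 3` values per group are untestable
(`p = NA`) and excluded from FDR adjustment.

**Significance** requires all three of p < 0.05, BH q < 0.05 and a
fold change of at least 2 (metabolites) by default. Both p and q gates
are enforced because both thresholds circulate in practice; either can
be relaxed (`alpha = Inf` / `q_alpha = Inf`).

**Classification.** "Elevated" is the up-flag on PRE/CTRL. "Cleared"
requires, by default, *both* POST/PRE significance (p < 0.05) and a
fold drop of at least `clear_fc = 2`; `cleared_requires_fc = FALSE`
reproduces the looser "no significant decrease" reading of persistence.
Category I = elevated ∧ cleared, II = elevated ∧ ¬cleared, III = the
down-flag on PRE/CTRL. Features significantly lower post-dialysis but
not changed versus control belong to no class — the taxonomy does not
define one. Fractions are reported over I+II+III to one decimal; with
the printed class counts 697/470/186 this gives 51.5 / 34.7 / 13.7 %.

## Identity confirmation

A feature confirms against a reference standard only if all three gates
pass:

- **accurate mass** — ppm deviation between the feature m/z and the
  *theoretical* adduct m/z ([M+H]⁺ = M + 1.007276 Da, [M−H]⁻ = M −
  1.007276 Da) computed from the standard's molecular formula; tolerance
  1 ppm in positive mode, 2 ppm in negative mode. The table of 21
  confirmed serum compounds carries printed observed m/z values; these
  are treated as instrument readings, never as the mass reference —
  several deviate from theory by more than their mode's tolerance, which
  is exactly why the theoretical mass anchors the gate.
- **retention time** — |ΔRT| ≤ 2.0 min by default, the largest shift
  observed across the 21 confirmed standards; configurable.
- **MS2 similarity** — score ≥ 0.7. The score is a square-root-intensity
  cosine: fragments are paired greedily by ascending m/z distance within
  0.05 Da (each fragment used once; ties resolved toward the lower-m/z
  pair), and the cosine is taken over the union of matched and unmatched
  fragments, so a missing fragment dilutes the score instead of being
  ignored. Dropping half the fragments of a uniform-intensity spectrum
  gives exactly 1/√2 ≈ 0.707. The score is symmetric and invariant to
  uniform intensity scaling. This is a transparent, reproducible score;
  commercial composite scores are not replicated here, only the 0.7
  operating point is shared.

Features without MS2 evidence are unconfirmed by default;
`allow_no_ms2 = TRUE` permits mass + RT confirmation for workflows that
accept it.

## TMT proteomics

Reporter intensities are log2-transformed and quantile-normalized
jointly across all 15 channels (one normalization for the experiment,
not per group): every channel's sorted vector is replaced by the
rank-wise mean, ties receiving their rank block's mean. Differential
calling then reuses the metabolite machinery with a 1.5-fold gate.

A property worth knowing: quantile normalization *attenuates* one-sided
signal. When ~12% of proteins are elevated in 10 of 15 channels, forcing
identical marginal distributions absorbs part of the shift (planted
2-fold effects emerge around 1.7–1.9-fold). With log-normal baseline
abundances (log2 means drawn N(18, 2), the dense-core/sparse-tail shape
of serum proteomes) and reporter noise SD 0.2, recall of 83 planted
2-fold proteins among 665 is 93–99% across seeds at the full gates. A
protein sitting at the extreme top rank in every channel has its fold
change annihilated entirely — an intrinsic cost of the method, not a
bug.

## Enrichment and the disease network

Over-representation uses the one-sided upper-tail hypergeometric test,
P(X ≥ k) for X ~ Hypergeom(N, K, n), with BH adjustment across pathway
sets and deterministic ordering (ascending p, ties alphabetical). The
universe defaults to all features that survived QC and entered
classification; no display threshold is hard-coded. Pathway sets are
read from standard GMT files.

The disease interactome seeds the metabolites elevated in ESKD
(categories I + II) and the differential proteins, joins them with
metabolite–protein association edges (TSV with `chemical`, `protein`,
`combined_score`; duplicates collapsed to the maximum score; default
score cutoff 0.4, the conventional medium-confidence level — the source
analysis states none, so it is configurable), keeps seeds even when
isolated, adds nodes exactly one hop from any seed as `neighbor`, and
induces the subgraph on the retained nodes. Identifier matching is
exact; fuzzy name matching is deliberately avoided (silent mismatch
risk) — synonym mapping is the caller's responsibility. Exports: SIF,
GraphML (annotations preserved), edge TSV; all round-trip.

## Dose–response

Viability follows the four-parameter logistic
`y = bottom + (top − bottom) / (1 + (x/ic50)^hill)`; at `x = ic50` the
response is the midpoint of the asymptotes. The model family is an
assumption — the assay being emulated names no curve model — but it is
the standard choice for WST-1 viability data. Fitting is least squares
with Levenberg–Marquardt iterations, the IC50 parameterized on the log
scale (positivity by construction), and multi-start initialization: Hill
slopes {±0.5, ±1, ±2} crossed with IC50 starts at the geometric mean of
the doses and at each distinct dose. The dose-grid starts matter: from
a single central start the optimizer reproducibly lands in a flat local
minimum for curves whose IC50 sits off-center in the dose ladder. The
best start by SSE wins; if `bottom > top` the equivalent reflected
parameterization is returned so `bottom ≤ top` always holds.

Identifiability caveat: with the 0.01–100 µM five-point ladder, an IC50
in the upper third of the range leaves the lower asymptote nearly
unconstrained, and fitted IC50s there carry large uncertainty (the
simulation drivers show this for taurine-like curves). Claims about such
compounds should rest on the curve, not the point estimate.

Concentration scaling is the simple arithmetic used to place relative
LC-MS intensities on an absolute scale: multiply a published healthy
reference interval by the observed between-group intensity ratio (e.g.
12 × 5–15 µM = 60–180 µM).

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions; its defaults are the
conditions, chosen once:

- 10 samples per arm, 3 QC, 3 blanks; 2,000 features.
- Planted fractions 0.08 / 0.055 / 0.022 for categories I/II/III — the
  proportions of the reported 697/470/186 changed features among all
  ~8,400 detected serum features.
- Elevation 8-fold (`effect_fc_up`), clearance 4-fold (`clearance_fc`):
  representative of the strong uremic-solute effects the taxonomy
  targets, and comfortably interior to the 2-fold decision thresholds so
  recovery measures classification, not threshold luck.
- Log-normal intensities: Gaussian noise on the log2 scale
  (`noise_sigma = 0.25`) around a feature baseline drawn U(12, 20) log2
  units — multiplicative MS intensity noise, which makes planted log2
  fold changes exact in expectation. No distributional parameters are
  published for the real cohort; these are stand-ins, not estimates.
- Matched pairs: each patient × feature has a baseline effect (SD =
  `noise_sigma`) shared between that patient's PRE and POST columns —
  exactly the correlation the paired test exploits. The effect is drawn
  independently per feature; real cohorts also carry sample-wide
  subject effects that correlate features, which the generator omits so
  that feature-level error rates are interpretable per run.
- QC columns resample the pooled mean of all biological samples with
  half the biological noise; blanks sit at 1/50 of the mean sample
  intensity, so compliant features pass the 5-fold blank filter.
- Peak width 8–30 scans and S/N 10–100, uniform: compliant with the
  default filters by construction, since the filters are exercised by
  dedicated violating fixtures in the tests.

When a reference library is passed, planted elevated features adopt the
m/z, RT, polarity and MS2 spectrum of successive standards, so the
identification stage has genuine positives. The MS2 fragment lists of
the library are synthetic (seeded, reproducible): real fragmentation
spectra are not redistributable here, so matching is validated by
self-consistency and perturbation (fragment jitter and dropout), not
against empirical spectra.

What passing on these simulations shows — and what it does not: the
pipeline's logic, thresholds, bookkeeping and statistics behave exactly
as specified under a faithful noise model; it does *not* show
robustness to retention-time drift, batch effects, isotope interference,
missingness structure or adduct ambiguity, none of which the generator
models (by design; see Non-goals throughout).

## Problem sizes and determinism

Default analysis and test sizes: 2,000 features × 36 samples, 665
proteins × 15 channels, 21 standards, 2,000-feature null cohorts for
error-rate checks, brute-force oracle enumeration up to universe size 12
— sizes at which every property is exercised meaningfully and the whole
suite runs in seconds. Every generator accepts a seed, saves and
restores the caller's RNG state, and is byte-reproducible; the pipeline
(`run_pipeline`) is deterministic given its seed.

## Known limitations

- Peptide→protein rollup, search-engine FDR and raw-spectrum processing
  are upstream concerns, out of scope.
- Adducts beyond ±H, isotope-pattern scoring and in-source fragments are
  not modeled.
- Quantile normalization's one-sided-signal attenuation (above) means
  fold-change thresholds act on slightly compressed values in the
  proteomic arm.
- The 4PL point estimate is unreliable when the IC50 approaches the top
  of the dose range (above).
- Enrichment universes are a known lever of ORA; the default (all
  classified features) is one defensible choice among several and is
  configurable.
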