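---
title: "Discovering multi-colour FISH panels for prostate cancer progression"
author: "FISHpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering multi-colour FISH panels for prostate cancer progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FISHpanel)
```

## The problem

Men diagnosed with clinically localised, low- or intermediate-risk
prostate cancer are increasingly managed by active surveillance (AS)
rather than immediate surgery or radiation. The clinical challenge is
identifying, at diagnosis, the minority whose disease will progress.
Fluorescence in situ hybridisation (FISH) counts copy-number and
rearrangement events in individual interphase nuclei of biopsy tissue,
so a small panel of FISH probes can in principle flag aggressive biology
before it is histologically evident.

FISHpanel implements the discovery workflow for such panels on a
retrospective case-control design: *cases* progress to clinical
intervention within ten years of diagnosis, *controls* do not progress
over at least ten years of follow-up. Because per-nucleus enumeration
data from real cohorts are rarely shareable, the package ships a
first-class synthetic cohort generator so that every downstream stage is
exercised end to end, deterministically, from a seed.

## From signals to specimen-level parameters

Each specimen is hybridised with three four-colour probe mixes
(`defaultProbePanel()`): locus probes (PTEN, NKX3.1, CDKN1B, FGFR1, MYC,
NMYC), centromeric controls (CEP10, CEP8) and two break-apart pairs (ERG,
ETV1). One hundred consecutive, intact, non-overlapping nuclei are
enumerated per specimen per mix. Six statistics summarise each probe:

* **Gain** — percent of cells with more than 2 signals;
* **Loss** — percent of cells with fewer than 2 signals (homozygous
  cells included, so Loss ≥ Homozygous always);
* **Homozygous** — percent of cells with 0 signals;
* **Ratio** — mean probe signals per cell divided by the mean of the
  same-chromosome centromeric control;
* **Split** — break-apart probes: percent of cells with at least one
  isolated red *and* one isolated green signal;
* **2Edel** — ERG break-apart: percent of cells with ≥ 2 isolated red
  signals and fewer isolated green than red (rearrangement through an
  interstitial deletion).

Two modelling conventions deserve a note. First, the microscopy
criterion for "separated" break-apart signals (≥ 1 signal width) cannot
be evaluated from counts; separation is resolved at enumeration time and
the data model stores fused and isolated counts directly. Second, Split
and 2Edel are treated as *disjoint* cell classes — a 2Edel-pattern cell
(red gain, green loss) is not additionally a Split cell — because they
are distinct reported parameters; and "2Edel" is operationalised as
(isolated red ≥ 2) and (isolated green < isolated red), reading "gain of
single red signals" as red multiplicity above one and "loss of at least
one green" relative to red multiplicity.

```{r parameters}
sim <- simulateCohort(simulationConfig(nCases = 4, nControls = 4,
                                       cellsPerSpecimen = 50, seed = 1))
cohort <- buildParameterMatrix(sim$cells, sim$clinical, sim$panel)
cohort
round(parameterMatrix(cohort)[c("MYC Gain", "PTEN Homozygous",
                                "ERG 2Edel", "PTEN Ratio"), 1:4], 2)
```

Specimens lacking cells for any panel probe fail hybridisation QC; they
are excluded from the matrix and listed with reasons in
`qcExclusions()`, mirroring how failed hybridisations are dropped from a
real study.

## Correlation screen

Markers that track ordinary clinical variables add no information beyond
the clinic and can confound the panel. Every FISH parameter is
Pearson-correlated with age, Gleason score, PSA and tumour stage (coded
ordinally T1c = 1 … T2c = 4); a raw two-sided p < 0.05 on *any*
parameter of a probe excludes the *whole probe* (`screenParameters()`).
The probe-level rule reflects how a deletion marker whose Loss parameter
tracks Gleason score (the NKX3.1 situation the generator reproduces by
default) is removed wholesale. No multiple-testing correction is
applied; with ~120 tests per cohort this rule is intentionally trigger-
happy, and on null data it will exclude some probes by chance — that is
a property of the screening rule itself, not of its implementation.

## Panel selection: DFI cut-off optimisation and AUC ranking

Seven candidate parameters survive feasibility screening: PTEN
Homozygous, MYC Gain, FGFR1 Gain, NMYC Gain, ETV1 Split, PTEN Loss and
ERG 2Edel. All $\binom{7}{3}+\binom{7}{4}+\binom{7}{5}+\binom{7}{6}=98$
combinations of 3–6 parameters are evaluated (`enumerateAndRank()`).

A specimen is **panel-positive** if *any* parameter in the combination
is greater than or equal to its cut-off (inclusive), negative only if
all fall below. For each combination, the full Cartesian product of
candidate cut-offs is searched exhaustively; the retained vector
minimises the distance from ideal

$$\mathrm{DFI} = \sqrt{(1-\mathrm{sensitivity})^2 +
  (1-\mathrm{specificity})^2},$$

the Euclidean distance of the operating point from the perfect-classifier
corner of ROC space (0 ideal, $\sqrt2$ at the worst corner). Cut-off
grids follow the class-specific ranges in percent-of-cells units —
amplification 2–15, deletion 10–20, break-apart 4–10 — at integer step:
with 100 enumerated cells, percent values are integers, so step 1 is
exhaustive.

Implementation note: rather than scoring every specimen at every cut-off
vector, `optimizeCutoffs()` reduces each specimen to the number of grid
cut-offs at or below its value per parameter and counts panel-negative
specimens with a k-dimensional histogram plus cumulative-sum dominance
table. This is exact — unit and acceptance tests verify equality with
naive Cartesian enumeration, including tie-breaks — and makes the
98-combination search run in seconds.

Numerical conventions:

* **Ties on DFI** are broken deterministically and conservatively:
  highest specificity first, then element-wise larger cut-offs in
  parameter order (the fewest positive calls). With perfectly separated
  data every cut-off of a grid is optimal and the largest is returned.
* **Combination AUC.** A single dichotomised panel call yields one ROC
  point, not a curve, so DFI and AUC must come from different
  constructions. The default scores each combination by an unpenalised
  logistic model on its *continuous* parameter values and takes the
  Mann–Whitney AUC (ties one half) of the fitted probabilities; exactly
  duplicated columns are collapsed first, and if the fit fails to
  converge the score falls back (flagged) to the per-specimen maximum of
  rank-standardised values. The alternative reading — the trapezoidal
  area of the one-point ROC polygon, $(\mathrm{sens}+\mathrm{spec})/2$ —
  is available as `aucMethod = "single-point"` for sensitivity analysis.
* Combinations are ranked by AUC descending, DFI ascending, then
  lexicographically; per-size leaders are reported alongside the full
  table.

## Association models

FISH positivity under the optimised cut-offs enters unconditional
logistic regressions (`fitLogistic()`: IRLS with step-halving, so the
log-likelihood is monotone across iterations; tolerance $10^{-8}$ on
the coefficient change, at most 50 iterations; Wald standard errors
from the inverse observed information; 95% limits at $z = 1.959964$):

* `fishOnlyModel()` — outcome ~ FISH;
* `fishClinicalModel()` — outcome ~ FISH + NCCN risk group, the risk
  group entered as a single ordinal score (Very Low = 1 … High = 4)
  because one adjusted odds ratio is reported per model; dummy coding is
  available behind `riskCoding = "dummy"`;
* `clinicalOnlyModel()` — outcome ~ NCCN + age (age is retained only in
  this model by default);
* `stratifiedAnalysis()` — the FISH-only model within three strata:
  Lower (Very Low + Low), Intermediate, Higher (High).

Degenerate inputs are first-class citizens: a constant predictor is a
rank-deficiency error naming the collinear term; quasi-complete
separation is flagged (`converged = FALSE` with a diagnostic), never
silently "fixed"; an empty 2×2 cell additionally reports a clearly
labelled Haldane–Anscombe (+0.5) corrected odds ratio as an auxiliary
value; small strata that cannot be fitted are skipped with a note rather
than failing the analysis. The NCCN risk-group assignment itself
(`assignNccnRisk()`) uses the standard stage/PSA/Gleason thresholds;
because core-count and percent-involvement data are not modelled, the
Very Low classification additionally requires an explicit caller flag.

## What the synthetic cohort emulates — and what it does not

`simulateCohort()` draws, per specimen and lesion-bearing parameter, an
abnormal-cell fraction from a Beta prior; per-cell lesion assignment is
i.i.d. given the fraction (no spatial or clonal structure); every true
hybridisation signal is then dropped independently with probability
`truncationProb`, the simplest mechanism for the signal truncation seen
in 5-micron FFPE sections. Key defaults, each chosen once:

* **58 cases / 49 controls, 100 cells/specimen/mix** — the cohort shape
  of the motivating study design.
* **truncationProb = 0.08** — a diploid locus then shows on average
  $2(1-0.08)=1.84$ signals, the observed centromere regime in FFPE
  biopsies (the acceptance checks require the simulated CEP mean in
  [1.80, 1.90]).
* **Beta(mean 0.03, concentration 50)** baseline abnormal fraction — a
  low per-marker background typical of interphase FISH scoring noise.
* **Case enrichment ×1.6** on the seven candidates — sized so each
  marker shifts by roughly half a within-group standard deviation and a
  three-marker panel lands in the moderate-discrimination regime
  (panel AUC ~0.7–0.85) typical of FISH progression panels, rather than
  near-perfect separation.
* **NKX3.1 Gleason coupling 1.5** — scales the NKX3.1 Loss prior mean by
  $1 + 1.5\,(G-6)^+$, strong enough that the correlation screen detects
  and excludes NKX3.1 in essentially every seeded cohort of study size.
* **Risk-group frequencies** (VL .10, L .40, I .27, H .23), identical
  for cases and controls — matching the matched design's stratum
  margins; consequently the synthetic NCCN-only odds ratio is near 1 by
  construction.
* Gain magnitude uniform on {3,…,6}; 2Edel red multiplicity uniform on
  {2,3,4}; specimen order fixed by generation sequence; one seeded RNG,
  so identical config + seed reproduces byte-identical TSVs.

Two honest consequences of the independent-Bernoulli truncation model:
a truly diploid locus shows fewer than 2 signals in
$2p(1-p)+p^2 \approx 15\%$ of cells at $p = 0.08$, so Loss-type
parameters carry a substantial truncation background and deletion-class
cut-offs (10–20%) sit partly inside it; and parameters are conditionally
independent across probes, which real tumours (aneuploid clones, field
effects) are not. Passing tests on this generator therefore demonstrate
algorithmic correctness and recovery of planted structure — not
clinical performance on real biopsies.

## Problem sizes used by the test suite

The packaged checks run, among others: 200 random tied datasets against
brute-force AUC pair counting; 50 random instances (≤ 4 parameters,
grids ≤ 5) against naive cut-off enumeration including tie-breaks; the
complete sweep of 2×2 tables with cells 1–30 (810,000 logistic fits)
against the closed-form cross-product ratio and Wald standard error;
100 random datasets for the cut-off monotonicity properties; and 20
seeded study-size cohorts (58/49 × 100 cells) for planted-panel
recovery, the intermediate-stratum effect, the NKX3.1 exclusion and the
CEP calibration.

## Known limitations

* Apparent (resubstitution) performance only: no cross-validation or
  bootstrap optimism correction, matching the discovery design being
  reproduced.
* Unconditional logistic models despite the matched design; no
  conditional likelihood, no Firth penalisation.
* No survival modelling; the outcome is the 10-year progression label.
* The generator's priors are free parameters of the package, not values
  calibrated to any published per-marker distribution (none are
  published); conclusions about real cohorts require real enumeration
  tables, which the pipeline reads from the same TSV interface.
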