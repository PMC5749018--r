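# FISHpanel

Discovery of multi-colour fluorescence in situ hybridisation (FISH)
marker panels that separate progressive from non-progressive prostate
cancer in active-surveillance case-control cohorts.

Men with clinically localised, low/intermediate-risk prostate cancer
are commonly managed by active surveillance; the open problem is
flagging, at diagnosis, the minority who will progress. FISH enumerates
copy-number and rearrangement events (gains, deletions, break-apart
rearrangements such as ERG "2Edel") in individual biopsy nuclei, and
small multi-probe panels can capture aggressive biology that single
markers miss. FISHpanel is for biostatisticians and assay developers
building and stress-testing such panels: it takes per-nucleus signal
enumeration tables (or generates realistic synthetic ones) and carries
them through marker screening, combinatorial panel optimisation and
clinical association models.

## The method

1. **Signal enumeration → parameters.** Per specimen and probe, six
   statistics: Gain (% cells > 2 signals), Loss (% < 2), Homozygous
   (% = 0), Ratio (mean probe / mean same-chromosome CEP control),
   Split (% cells with isolated red *and* green break-apart signals),
   2Edel (% cells with ≥ 2 isolated red and fewer green than red).
2. **Correlation screen.** Every parameter is Pearson-correlated with
   age, Gleason score, PSA and stage; any p < 0.05 excludes the whole
   probe (the rule that removes NKX3.1 when its Loss parameter tracks
   Gleason score).
3. **Panel selection.** All 3–6-parameter combinations of the seven
   candidates (PTEN Homozygous, MYC Gain, FGFR1 Gain, NMYC Gain,
   ETV1 Split, PTEN Loss, ERG 2Edel) are evaluated. A specimen is
   panel-positive if **any** parameter ≥ its cut-off. Cut-offs are
   found by exhaustive search over class-specific integer grids
   (amplification 2–15 %, deletion 10–20 %, break-apart 4–10 %),
   minimising the distance from ideal

       DFI = sqrt((1 - sensitivity)^2 + (1 - specificity)^2),

   and combinations are ranked by Mann–Whitney AUC (fitted
   probabilities of a logistic model on the continuous parameter
   values), ties broken by DFI.
4. **Association models.** Unconditional logistic regressions with
   Wald inference: FISH-only, FISH + NCCN risk group (ordinal
   Very Low = 1 … High = 4), clinical-only (NCCN + age), and the
   FISH-only model within Lower / Intermediate / Higher risk strata.

A seeded synthetic cohort generator (58 cases / 49 controls, 100 nuclei
per specimen per mix, per-signal FFPE truncation probability 0.08 so
centromere probes average ≈ 1.84 observed copies) makes the whole
pipeline reproducible without patient data.

## Worked example

```r
library(FISHpanel)

cfg <- simulationConfig(seed = 7)          # study-sized synthetic cohort
sim <- simulateCohort(cfg)
cohort <- buildParameterMatrix(sim$cells, sim$clinical, sim$panel)
cohort
#> FishCohort: 31 FISH parameters x 107 specimens ( 58 cases / 49 controls )
#>   parameters: PTEN Gain, PTEN Loss, PTEN Homozygous, PTEN Ratio ... (31 total)

ranking <- enumerateAndRank(cohort, kMin = 3, kMax = 5)
ranking
#> CombinationRanking: 91 combinations (AUC method: logistic )
#> Per-size leaders:
#>  n_parameters                                                        parameters
#>             3                          PTEN Homozygous & FGFR1 Gain & ERG 2Edel
#>             4              PTEN Homozygous & FGFR1 Gain & PTEN Loss & ERG 2Edel
#>             5 PTEN Homozygous & FGFR1 Gain & NMYC Gain & ETV1 Split & ERG 2Edel
#>        auc       dfi
#>  0.7749824 0.4082906
#>  0.7858902 0.4943570
#>  0.7997889 0.3556621

clin <- clinicalData(cohort)
calls <- ranking$results[[1]]$calls[clin$specimen_id]
fishOnlyModel(calls, clin$outcome)
#> LogisticFit: 58 cases / 49 controls; converged in 5 iterations
#>         term coefficient standard_error odds_ratio ci_low ci_high   p_value
#>  (Intercept)      -0.865         0.2980     0.4211 0.2348  0.7551 3.702e-03
#>         FISH       2.205         0.4511     9.0682 3.7454 21.9552 1.024e-06
```

The ranking table reads: the best 3-parameter panel on this cohort
(PTEN Homozygous & FGFR1 Gain & ERG 2Edel) reaches AUC 0.775 with a
minimum DFI of 0.408 at its optimised cut-offs, and specimens positive
on that panel have 9.1-fold higher odds of being a progressor than
panel-negative specimens (95 % CI 3.7–22.0). `fishClinicalModel()`
reports the same odds ratio adjusted for NCCN risk group, and
`stratifiedAnalysis()` repeats the fit within risk strata.

`runPipeline()` executes every stage from one configuration and writes
`cells.tsv`, `clinical.tsv`, `probes.tsv`, `parameters.tsv`,
`screen.tsv`, `combinations.tsv`, `calls.tsv`, `models.tsv`,
`models_stratified.tsv` and a JSON run manifest; the same stages are
available from a shell via `inst/scripts/fishpanel.R`
(`simulate | enumerate | screen | select | fit | all`). The methods
vignette (`vignettes/fish-panel-discovery.Rmd`) documents the model,
the generator's assumptions and every numerical convention.

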