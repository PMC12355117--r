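# phosphoSig

Phospho-protein expression signatures, TNBC molecular subtyping, and
case-cohort weighted survival analysis in R.

## What problem this package addresses

Protein phosphorylation states — such as phosphorylated c-Jun N-terminal
kinase (pJNK), a driver of an immunosuppressive tumor microenvironment in
triple-negative breast cancer (TNBC) — are rarely measured directly in
clinical cohorts, but bulk RNA-seq usually is. `phosphoSig` implements a
complete, testable pipeline for studies that:

1. **derive a transcriptional signature** estimating a continuous
   phospho-protein level from matched RNA-seq + phospho-proteomic data,
2. **score and dichotomize** tumors of a clinical cohort by that
   signature,
3. **classify** tumors into TNBC molecular subtypes (BL, IM, M, LAR, MSL,
   with BL2 reassignment) and tumor-immune-microenvironment (TIME)
   patterns (FI / SR / MR), and
4. **analyze survival** in a stratified case-cohort design with
   generalized Horvitz–Thompson inverse-probability weights, including
   subtype × signature and treatment × signature interaction tests with
   Benjamini–Hochberg correction.

Because the motivating trial and proteogenomic datasets are
access-controlled, the package ships a first-class **synthetic cohort
generator** that reproduces the statistical structure these analyses
assume (a latent phospho level with correlated signal genes, subtype
centroid structure, TILs, proportional-hazards outcomes with interaction
effects, and 1:3 stratified case-cohort sampling). Every stage of the
pipeline is exercised end-to-end without any download.

## The methods at its core

**Signature derivation** (training cohort, log-normalized expression
*x*, phospho response *y*): over 1000 stochastic subsamples of one third
of the samples, a gene is a *candidate* if its Pearson |r(x_g, y)| > 0.25
in at least 75% of draws. Candidates enter an elastic-net regression

&nbsp;&nbsp;&nbsp;&nbsp;min_β ‖y − Zβ‖² / (2n) + λ [ α‖β‖₁ + (1−α)/2 ‖β‖₂² ],  α = 0.5,

on gene-wise z-scored expression Z, with λ chosen by 7-fold
cross-validation (minimum mean CV error). The per-sample **signature
score** is mean_g (β_g · z_g), and cohorts are split at the **median**
score into low/high groups (ties go low).

**Subtyping**: per subtype score = mean z of positively associated genes
− mean z of negatively associated genes; the argmax wins, samples whose
winner is the unstable BL2 subtype are reassigned to their second-highest
score, and BL1 is reported as BL.

**Case-cohort weighting**: all BCFI cases are included, non-cases are
subsampled within strata (tumor size × nodal status × age × treatment);
each included sample is weighted by the inverse of its stratum's sampling
fraction. Weighted Kaplan–Meier curves use weighted event/at-risk sums;
weighted Cox models maximize the weighted partial likelihood (Breslow
ties) with robust sandwich variance. For a subgroup interaction,
HR_inter = exp(β_interaction) is the ratio of the stratum-specific hazard
ratios, tested by a robust Wald test and BH-adjusted across the subtype
family.

## Worked example

```r
library(phosphoSig)

cfg <- pipelineConfig(
  simulation = simulationConfig(
    nSamples = 300, nGenes = 1000, nSignalGenes = 20,
    signalCorrelation = 0.6, censoringRate = 0.75,
    logHrEffects = c("pjnk" = 0.4, "subtypeIM:pjnk" = 0.5), seed = 42),
  derivation = derivationConfig(nIterations = 300, seed = 1),
  readThreshold = 100000, endpoints = "dfs", seed = 42)

report <- runFullPipeline(cfg)
print(report)
#> AnalysisReport
#>   samples analyzed: 300 (case-cohort: 215)
#>   signature: 20 genes, held-out r = 0.957
#>   subtype counts: BL=76 IM=79 LAR=40 M=72 MSL=33
#>   endpoints analyzed: dfs

unlist(report$endpoints$dfs$km_rate_60mo)
#>       low      high
#> 0.7379134 0.5315608
```

The simulated cohort carries a positive pJNK hazard effect, so the
signature-low group has the better weighted 5-year DFS (73.8% vs 53.2%)
and the adjusted weighted Cox model estimates a protective pJNK-low
hazard ratio:

```r
str(report$endpoints$dfs$overall_pjnk)
#> $ hr      : num 0.474   # HR of the pJNK-low group, adjusted
#> $ ci_lower: num 0.266
#> $ ci_upper: num 0.845
#> $ wald_p  : num 0.0113
#> $ lr_p    : num 0.0037  # likelihood ratio vs the covariate-only model
```

`report$endpoints$dfs$subtype_interactions` tabulates, per subtype, the
hazard ratios within the pJNK-low and pJNK-high strata, their ratio
`hr_inter = hr_low / hr_high`, the Wald interaction p, and the BH q over
the five subtypes.

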