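# spatialsurv

Survival analysis of segmented single-cell imaging cohorts — imaging
mass cytometry of breast tumors being the motivating case. Each patient
contributes one image of phenotyped cells (centroid coordinates in μm,
a 27-class phenotype label grouped into immune / stromal / epithelial
compartments), receptor status (ER/PR/HER2) with tumor grade, and
right-censored overall survival. `spatialsurv` turns the spatial
arrangement of those cells into prognostic features, models survival
with neural Cox networks, and derives survival subtypes that can be
transferred to external expression cohorts.

## The method

**Cell-Cell Interaction Score (CCIS).** Cells within a radius (default
4 μm) of each other are direct neighbors; connected components of this
radius graph are *cellular communities*. For every unordered phenotype
pair (x, y),

```
CCIS(x, y) = Σ_communities ( C · B_xy ) / A
```

where `C` is the community's clustering coefficient (mean local
clustering over its cells), `B_xy` its count of edges joining the two
phenotypes, and `A` the tissue area (μm²). With 27 phenotypes there are
378 pairs: the 105 epithelial–epithelial pairs form the tumor-core
(TCI) set, the remaining 273 the tumor-microenvironment (TMI) set, and
the 27 per-area phenotype densities the CP set.

**Two-stage neural Cox model.** One Cox proportional-hazards network
(prognostic index `βᵀ tanh(Wx + b)`, hidden width `⌈√p⌉`, Breslow
partial likelihood, L2 penalty) is trained per feature set; their
hidden activations (6 + 17 + 11 = 34 at the default widths) are
concatenated and a second-stage network is trained on top. A linear
Cox-PH on clinical covariates is the baseline; models are compared by
Harrell's C-index over repeated stratified train/test splits.

**Importance and subtyping.** Stage-2 inputs are scored by mean-masking
partial-likelihood drops, propagated to the original features as
`Ô = Wᵀ·Ĥ`, min-max normalized per set and thresholded (0.5 for CP,
0.75 for TMI/TCI). Consensus NMF over the selected features (rank
chosen from 3–15 by cophenetic correlation and silhouette) yields
patient subtypes, renumbered 1..K by decreasing Kaplan-Meier survival,
then characterized by Mann-Whitney U tests (BH-adjusted), Spearman
correlation networks and log-rank comparisons within clinical molecular
subtypes.

**Label transfer.** Per-patient pseudo-bulk marker means are matched to
an external expression cohort by correlation distance on shared
z-scored features at a 99.5% similarity cutoff (any external aligner
can be plugged in), and the matched subpopulation's survival and
differential markers are tested in the external cohort.

A seeded synthetic cohort generator (spatially clustered communities,
subtype-driven composition, proportional-hazards survival with planted
density/interaction effects and uniform censoring) provides ground
truth for every recovery test.

## Worked example

```r
library(spatialsurv)

cohort   <- generateCohort(simConfig(nPatients = 80, seed = 42))
features <- dropZeroFeatures(assembleFeatures(cohort$images, cohort$palette))
features
#> class: SummarizedExperiment
#> dim: 405 80
#> rowData names(4): set category member1 member2

Xsets <- list(CP  = featureSetMatrix(features, "CP"),
              TMI = featureSetMatrix(features, "TMI"),
              TCI = featureSetMatrix(features, "TCI"))
model <- fitTwoStage(Xsets, cohort$survival, l2 = 0.1, seed = 1)
model
#> TwoStageModel: stage-1 hidden widths CP=6, TMI=17, TCI=11 -> stage-2 CoxNet on 34 inputs

imp <- normalizeAndSelect(splitAndPropagate(
  model, hiddenImportance(model, Xsets, cohort$survival)))
head(imp[imp$selected, c("feature", "set", "normalized")], 3)
#>                                       feature set normalized
#> CP_Fibronectin_hi_Fibroblast CP_Fibronectin_hi_Fibroblast  CP  1.0000000
#> CP_Endothelial                             CP_Endothelial  CP  0.7542925
#> CP_CK_low_HR_med_Epithelial   CP_CK_low_HR_med_Epithelial  CP  0.6888175

sel <- minMaxScale(t(SummarizedExperiment::assay(features)[
  imp$feature[imp$selected], ]))
rs  <- rankSearch(sel, kRange = 3:6, nRuns = 20, seed = 7)
rs$quality
#>   K cophenetic silhouette
#> 1 3  0.9657299  0.8509694
#> 2 4  0.9586436  0.7270792
#> 3 5  0.9547735  0.7631547
#> 4 6  0.9330517  0.7153884

sub <- orderBySurvival(rs$result, cohort$survival)
sub
#> SubtypeResult: K = 3 subtypes over 80 patients
#>  1  2  3
#> 33 26 21

lr <- kmLogrank(subtypeLabels(sub), cohort$survival)
c(chisq = lr$chisq, df = lr$df, p = lr$p)
#> chisq 30.36, df 2, p 2.56e-07
stratificationCindex(subtypeLabels(sub), cohort$survival)
#> 0.761
```

Reading the output: the consensus rank search prefers K = 3 subtypes on
this small simulated cohort (cophenetic 0.966); after survival
ordering, subtype 1 (n = 33) has the best outcome, the three-group
log-rank test separates the curves at p = 2.6e-07, and using the
subtype index alone as a risk score gives a concordance of 0.76 —
i.e. in 76% of comparable patient pairs the higher-numbered subtype
fails first.

See `vignettes/spatialsurv-methods.Rmd` for the full account of the
model, its defaults and its limitations.

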