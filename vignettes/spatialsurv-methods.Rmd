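---
title: "Spatial interaction features, neural Cox survival models and consensus subtyping"
author: "spatialsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial interaction features, neural Cox survival models and consensus subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialsurv)
```

# Overview

`spatialsurv` implements a survival-analysis pipeline for segmented
single-cell imaging cohorts (the motivating setting is imaging mass
cytometry of breast tumors, where each patient contributes one image of
phenotyped cells with centroid coordinates in micrometres, receptor
status and right-censored overall survival). The pipeline has five
stages:

1. **Feature engineering**: phenotype densities (CP) and pairwise
   Cell-Cell Interaction Scores (CCIS) over cellular communities,
   organized into the CP / TMI / TCI taxonomy.
2. **Survival modeling**: one-hidden-layer Cox networks per feature set
   and a two-stage composite, against a clinical Cox-PH baseline,
   compared by Harrell's C over repeated train/test splits.
3. **Importance**: mean-masking importance of the composite's stage-2
   inputs, propagated back to original features as `t(W) %*% H`, then
   per-set normalization and thresholded selection.
4. **Subtyping**: consensus NMF over the selected features, rank chosen
   by cophenetic correlation and silhouette, subtypes ordered by
   survival, then characterized against clinical molecular classes.
5. **Label transfer**: pseudo-bulk profiles, cross-cohort patient
   matching at a similarity cutoff, survival comparison and
   differential markers in the matched arm.

A synthetic cohort generator with planted spatial, compositional and
survival structure ties the stages together and is what every
recovery-style test runs on.

# The interaction score

Direct neighbors are cells whose centroids lie within a radius
(default 4 μm, i.e. 4 pixels at 1 μm/pixel) of each other; the
threshold is inclusive, so a pair exactly at the radius is an edge.
Cellular communities are the connected components of this radius graph.
For every unordered phenotype pair $(x, y)$, including self-pairs,

$$\mathrm{CCIS}(x,y) \;=\; \frac{\sum_{N} C \cdot B_{xy}}{A},$$

summing over the image's communities: $C$ is the community's clustering
coefficient, $B_{xy}$ the number of its edges joining a cell of
phenotype $x$ to one of phenotype $y$, and $A$ the total tissue area in
μm², so scores have units 1/μm². Scores are symmetric, non-negative,
halve when the area doubles, and are invariant to rigid motions of the
coordinates.

Choices that were genuinely open, and how they were settled:

* **Communities.** The source data format carries externally computed
  neighborhood communities; this package recomputes them as connected
  components of the radius graph, which is deterministic, reproducible
  from coordinates alone, and agrees with the intuition of "locally
  connected groups of cells".
* **Clustering coefficient.** $C$ is the mean *local* clustering
  coefficient over the community's cells, with cells of degree < 2
  contributing 0. Global transitivity is the natural alternative; the
  per-community mean was chosen because it is the component-wise
  restriction of the usual average-clustering statistic. The brute
  force oracle used in the tests makes the same choice, so the suite
  pins the convention rather than hiding it.
* **Edge counting.** $B_{xy}$ counts each undirected edge once. A
  per-cell enumeration would count cross-phenotype edges twice; single
  counting makes $B_{xy}$ a true edge count, and only rescales
  off-diagonal scores by 2, which matters to none of the downstream
  rank-based analyses.
* **Area.** The stored image area is used when present; otherwise the
  convex hull of the centroids. "Area occupied by all the cells" is not
  operationally defined by a segmented cell table, so the fallback is
  explicit rather than implicit.

Under the default palette (6 immune, 7 stromal, 14 epithelial
phenotypes) there are $\binom{27}{2} + 27 = 378$ pairs: 21
immune-immune, 42 immune-stromal, 84 immune-epithelial, 28
stromal-stromal, 98 stromal-epithelial and 105 epithelial-epithelial.
The 27 densities form the CP set, epithelial-epithelial pairs the TCI
set (tumor core) and all remaining pairs the TMI set (tumor
microenvironment, 273 pre-drop). Pairs that are zero for every patient
carry no information and are dropped with their names recorded.

# Survival networks

Each one-stage model is a Cox proportional-hazards network with one
hidden layer: prognostic index $\beta^\top \tanh(Wx + b)$, hidden width
$\lceil\sqrt{p}\rceil$ (27 → 6, 268 → 17, 105 → 11), fitted by
maximizing the Breslow-tie partial log-likelihood minus an L2 penalty
on all parameters. The two-stage model freezes the three one-stage
fits, concatenates their hidden activations (6 + 17 + 11 = 34 by
default) and trains a second network of the same family on the
concatenation.

Numerical choices:

* **Activation tanh**, so the stage-2 inputs are bounded and need no
  re-standardization (a `restandardize` switch exists).
* **Breslow ties** — the standard differentiable tie treatment for
  neural Cox losses; the implementation is checked term-by-term against
  a risk-set-enumeration oracle.
* **Standardization**: columns are z-scored with training-split
  statistics; CCIS scales are arbitrary, and the optimizer needs
  comparable gradients. Constant columns map to zero.
* **Optimizer**: full-batch L-BFGS with analytic backpropagated
  gradients, at most 2000 iterations, `factr = 1e7`. Initialization is
  small uniform noise controlled by a seed, so a fixed data + seed pair
  reproduces the parameters bitwise.
* **Penalty**: fixed `l2 = 0.1` by default; passing `l2 = NULL`
  selects it on an inner 75/25 validation split over a small log grid
  by held-out concordance, then refits. The objective is non-convex:
  restarting from a handful of seeds and keeping the best penalized
  likelihood is the recommended way to approximate "the" optimum, and
  the regularization-monotonicity test does exactly that.
* **Splits**: 80/20 train/test stratified by event status, 20 repeats
  by default in `evaluateModels`.

The clinical baseline is an ordinary linear Cox-PH on ER, PR, HER2 and
grade, fitted by the `survival` package.

# Importance and selection

Stage-2 input nodes are scored by mean-masking: replace one node's
column by its cohort mean and measure the drop in the stage-2 partial
log-likelihood, without refitting (a seeded permutation variant is
available). A node whose outgoing stage-2 weights are zero scores
exactly 0. The 34 node scores are split 6/17/11 by originating model
and propagated to the original features as $\hat O = W^\top \hat H$,
which is exact and linear.

The propagated product can be negative, while the reported importances
live in $[0,1]$: absolute values are taken, then min-max normalized
*within each feature set* (per-set, not global, because the three sets
have incommensurate scales). Selection keeps features with normalized
score strictly above the set's threshold — 0.5 for CP, 0.75 for TMI and
TCI — and caps the union at 50 features by descending score; the cap
exists because the thresholded union is what downstream clustering
consumes and its size should be bounded and predictable.

# Consensus subtyping

The selected feature matrix is min-max scaled to $[0,1]$ per feature
(guaranteeing non-negativity) and factorized `nRuns = 30` times from
seeded random initializations with multiplicative Frobenius updates
(500 iterations or $10^{-5}$ relative change). Each run assigns a
patient to its largest coefficient; the consensus matrix is the
co-assignment frequency; final labels cut an average-linkage tree of
(1 − consensus) at K. Rank search (default 3–15) scores each K by the
cophenetic correlation of that tree and the mean silhouette of the
labels, choosing the K with the best cophenetic score and breaking ties
by silhouette. The number of restarts matters for model selection: with
few restarts a wrong rank can look spuriously crisp because every run
splits a cluster the same way; at the default 30 restarts the planted
rank is recovered reliably in the test suite's planted-partition
fixtures.

Subtypes are renumbered 1..K by decreasing Kaplan-Meier median survival
(curves that never reach 0.5 sort first; ties break on the survival
probability at the last observed time), so subtype 1 is always the
best-surviving group. Characterization uses min-max-normalized
features, two-sided Mann-Whitney U tests of each subtype against the
rest and Benjamini-Hochberg adjustment across all (subtype, feature)
tests. **Note the significance marks**: `*` means adjusted p < 0.01 and
`**` means 0.01 < p < 0.05 — the stronger mark has fewer asterisks.
This inverted convention is kept deliberately for continuity with the
figure legends this analysis style comes from; it is the opposite of
the usual convention, hence this prominent warning.

Molecular subtypes are derived from receptor status alone (no Ki-67
cut, which the clinical schema does not carry): TNBC = ER−/PR−/HER2−,
HER2-enriched = ER−/PR−/HER2+, Luminal A = (ER+ or PR+)/HER2−,
Luminal B = (ER+ or PR+)/HER2+; missing status yields an explicit
Unknown. The dichotomized comparison collapses ordered subtypes into
good (1–4 by default) and bad arms and runs a two-group log-rank within
each molecular class, alongside the full contingency table.

# Label transfer

Pseudo-bulk profiles are per-patient marker means. Matching z-scores
each cohort per feature and uses one minus the Pearson correlation of
patient profiles as the cross-cohort distance; the "99.5% similarity"
cutoff retains the 0.5% smallest cross-pair distances (globally by
default; a per-source-patient mode exists, since the original
formulation does not say which was meant). Any external aligner can be
plugged in through `distanceFun`, which is the intended integration
point for joint-embedding methods; the built-in matcher is a
correlation matcher, not a re-implementation of any published aligner.
One caveat the tests document: after per-feature z-scoring, a uniform
up/down shift of all markers is invisible to correlation matching —
groups are distinguished by their expression *patterns*. Differential
markers between matched groups use Wilcoxon rank-sum tests with BH
adjustment and the sign of the median difference, a distribution-free
stand-in for moderated-t pipelines at this scale.

# The synthetic cohort generator

`generateCohort(simConfig(...))` draws, per patient: a latent subtype;
community centers uniform in a 1000 × 1000 μm box; cell positions
Gaussian (σ = 15 μm) around centers; phenotypes from the subtype's
multinomial mixture; receptor status and grade conditional on the
subtype (so clinical cross-tabulations are non-degenerate). Survival
times are exponential with hazard
$h_0 \exp(\mathbf{\beta}^\top z)$ where $z$ are the patient's *true*
feature values — computed from the generated image with the same
density/CCIS definitions the analysis uses — z-scored across the
cohort, and censoring is uniform on (0, 120] months with
$h_0 = 0.01$/month (≈ 35–45% event rate). Effects are therefore
per-standard-deviation log hazard ratios; raw CCIS values are of order
$10^{-6}$/μm², so unscaled coefficients would be meaningless.

Design notes:

* An exponential baseline is the simplest proportional-hazards
  generator; only the rank structure of the linear predictor matters
  for concordance and log-rank recovery.
* Uniform independent censoring keeps the partial likelihood correctly
  specified.
* The default spatial scales (5–10 communities of 30–80 cells,
  σ = 15 μm, radius 4 μm) give neighbor graphs with a connected core
  and realistic triangle density; they were chosen once for
  testability — the real cohorts' spatial statistics are not published,
  so no claim of realism is made.
* What the generator does **not** emulate: marker-level intensities,
  segmentation artefacts, spatially varying density gradients within a
  community, informative censoring, or correlation between image area
  and outcome. Passing recovery tests therefore demonstrates the
  pipeline's internal consistency on proportional-hazards data with
  planted compositional/spatial signal — not performance on real
  tissue.

# Problem sizes in the test suite

The suite runs recovery experiments at deliberate desk scale: a
strong-signal cohort of n = 300 patients (4–6 communities of 20–50
cells) for held-out concordance and importance-recovery checks; a null
cohort of n = 400 small images for calibration; planted-partition
matrices of 80 patients for rank-search recovery (10 seeded
repetitions); 200-replicate null simulations for FDR calibration; and
brute-force oracles up to 200 cells (CCIS) or 20 patients (partial
likelihood, concordance). These sizes are the package's reference
conditions; all are configurable upward.

# Known limitations

* Connected components stand in for externally defined neighborhood
  communities; on data where communities were defined differently the
  absolute CCIS values will differ (the scale-free downstream analyses
  are less affected).
* The network objective is non-convex; different seeds can reach
  different local optima. All fitting functions are deterministic given
  a seed, and best-of-restarts is the documented remedy.
* Harrell's C treats tied risk scores as 0.5 and ignores tied times;
  subtype-label stratifications therefore cannot reach C = 1 even for
  perfectly ordered groups with more than one patient per subtype.
* The NMF consensus conventions (multiplicative updates, average
  linkage, Pearson cophenetic correlation) follow the consensus-NMF
  literature but are one of several defensible variants.
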