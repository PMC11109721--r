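---
title: "Methods: permutation inference for ridge partial-correlation brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation inference for ridge partial-correlation brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netperm)
```

## The analysis problem

`netperm` implements the statistical core of a resting-state functional
connectivity study design that is common in deep-brain-stimulation (DBS)
research: healthy controls are scanned once, patients are scanned twice
(stimulator ON and OFF), and the patients are split by a binary clinical
grouping (here called the MADD / non-MADD subgroups, after mixed
anxiety-depressive disorder). Per scan, the data entering the package are a
parcellated ROI time-series matrix (rows = time points, columns = nodes);
everything upstream (acquisition, preprocessing, parcellation) is out of
scope.

The pipeline asks two families of questions:

* **Aim 1** — does stimulation change the network (ON vs OFF, paired), and
  how does each patient state compare with controls (HC vs ON, HC vs OFF)?
* **Aim 2** — does the stimulation *response* (per-subject ON − OFF change)
  differ between the clinical subgroups, in network terms and in clinical
  scores?

## Network estimation

Each run's connectome is a ridge-regularized partial-correlation matrix.
With column-standardized signals and sample covariance $S$,

$$P = \left(S + \rho\,\bar{s}\,I\right)^{-1}, \qquad
  r_{ij} = -\,\frac{P_{ij}}{\sqrt{P_{ii}P_{jj}}},$$

where $\bar{s}$ is the mean diagonal variance. Scaling the penalty by
$\bar{s}$ makes $\rho$ unitless; this is the common "ridgep" convention of
netmats-style tooling. At $\rho = 0$ the estimator is the textbook partial
correlation from the unregularized inverse covariance (a test asserts this
against an independent computation). The diagonal is fixed to zero so that
downstream graph metrics never count self-loops, and no Fisher
z-transform is applied to the edges. The default $\rho = 0.1$ is a
configuration parameter, not an estimate: with 230 nodes and 200 time
points the raw covariance is ill-conditioned and some positive penalty is
required; the exact value a given study used with its own tooling is
generally unknowable, so it is exposed in `analysisConfig()`.

## Signed graph metrics

Connectomes are signed. The package follows the standard signed treatment:
the network is split into a positive part and a magnitude-of-negative part,
and the *total clustering coefficient* is computed on each part separately.
Per part, weights are normalized by the maximum weight; the per-node
coefficient is the Onnela geometric-mean triangle form
$c_i = \sum_{jk}(w_{ij}w_{jk}w_{ki})^{1/3} / (k_i(k_i-1))$ with $k_i$ the
node degree (nodes of degree < 2 contribute 0), and the total is the mean
over nodes. The max-normalization makes the coefficient invariant to a
global rescaling of the part, and bounds it in [0, 1]. Because "total
clustering" names a family rather than one formula, the variant is a
configuration switch (`onnela`, default, or `zhang` for Zhang–Horvath);
tests pin the default to an exhaustive triangle-enumeration oracle.

*Global efficiency* is the mean over ordered node pairs of the inverse
weighted shortest-path length, with connection length $1/w_{ij}$ on the
positive part only and unreachable pairs contributing 0. Shortest paths
are exact (Dijkstra, via igraph); the test oracle is an independent
Floyd–Warshall. Negative weights are excluded from efficiency because no
standard signed path-length exists; the package reports efficiency ≥ 0.
*Node strength* (for reporting and figure labelling) is the per-node sum of
absolute edge weights.

## Permutation GLM inference

All inference is permutation-based. For a response vector $y$ and design
$X$ with contrast $c$, the statistic is the OLS contrast t. Nuisance
covariates (columns with zero contrast weight) are handled by
Freedman–Lane residualization: $y$ is residualized against the nuisance
block, the residuals are permuted (or sign-flipped) and added back to the
nuisance fit, and the full model is refit. Two exchangeability schemes
cover the repeated-measures structure without inventing a mixed model the
design does not need:

* `paired_sign_flip` — for within-subject session effects: the response is
  the per-subject ON − OFF difference and the flips are per-subject signs;
* `group_shuffle` — for between-group effects (HC vs patients, and the
  subgroup-by-session interaction tested on the per-subject differences).

Two-sided p-values are $p = \#\{|t^\ast| \ge |t_{obs}|\}/R$ with the
identity permutation always included, so $p \ge 1/R$. When the permutation
space is no larger than the requested budget it is enumerated exhaustively
(all $2^n$ sign patterns or all $n!$ orders); a test asserts that the
Monte-Carlo path and exhaustive enumeration coincide there. A response
with zero residual variance is assigned t = 0, so a constant response ties
with every permutation and yields the maximal p rather than a spurious
detection.

Joint inference over positive and negative total clustering uses
*non-parametric combination* (NPC): both modalities are tested under one
synchronized set of permutations, each permutation's statistics are
converted to per-permutation partial p-values by their rank in the
permutation distribution, and Fisher's combiner $-2\sum_m \ln p_m$ is
referred to its own permutation distribution. Synchronization preserves
the dependence between modalities, which is what makes the joint p valid.
Global efficiency is tested separately with a plain permutation t; the
alternative of including it in the NPC combination is a one-line change
but is not the default, since the two statistics are conventionally
reported separately.

## Network-based statistics

Edge-level inference uses the NBS approach. First, a per-comparison
one-sample t-test at $\alpha = 0.05$ across all runs entering the
comparison masks out edges with no consistent signal (zero-variance edges
are kept only if their common value is nonzero). Retained edges are tested
with the same Freedman–Lane machinery (synchronized across edges), edges
beyond a primary threshold (default $|t| = 3.0$) are clustered into
connected components, and each observed component's FWE-corrected p-value
is the fraction of the permutation distribution of the *maximal component
size* reaching its size. Component size is measured in **edges**, the
toolbox "extent" convention. The primary threshold is a required
configuration parameter because component-level inference is known to be
sensitive to it. Directional effects are tested by running the component
search separately per contrast direction, mirroring directional reporting
conventions; a two-sided mode exists and is what the calibration tests
use, so that "any rejection" is a single test at the nominal level.

Each aim's p-values — metric-level tests, NBS component FWE p-values and
(for Aim 2) the clinical GLMs — form one family and receive one
Benjamini–Hochberg FDR correction (`fdrBH`, backed by `p.adjust`), with
the family recorded in the report so the correction scope is auditable.

## The synthetic cohort generator

No patient data are distributable, so validation rests on a generator that
reproduces the statistical structure the analysis assumes. The default
design matches the emulated study: 20 controls (one run), 81 patients
(ON and OFF runs) of whom 42 form the MADD subgroup, 230 nodes, 200 time
points, matching counts reported for such cohorts. Tests use reduced
sizes.

Signals are multivariate Gaussian draws from a community-structured sparse
precision matrix (5 communities; within-community edges present with
probability 0.6 carry implied partial correlations of magnitude 0.15,
signs 70/30 positive/negative — values chosen to give connectomes whose
edge distribution roughly resembles regularized empirical ones). Temporal
structure is AR(1) mixing with coefficient 0.3 (scanner-typical smoothness
at a 3 s repetition time), applied as
$s_t = \phi s_{t-1} + \sqrt{1-\phi^2}\,\epsilon_t$ so the cross-sectional
covariance remains exactly the inverse precision; columns are not
re-standardized afterwards, since the contract is on the covariance.

Planted effects are *additive changes to implied partial correlations* on
named edge sets, applied to the precision matrix with positive
definiteness enforced (the perturbation is shrunk with a warning if
needed, and fails loudly if infeasible). Three hooks cover the designs the
pipeline must detect:

* `sessionEffect` — applied to every patient's ON precision (the
  stimulation effect);
* `interactionEffect` — applied additionally to non-MADD ON precisions
  (the subgroup-specific response);
* `baselineEffect` — applied to both patient sessions (disease-related
  degradation relative to controls). This third hook is what makes the
  qualitative ordering scenario expressible — OFF degraded relative to
  controls, ON restored exactly to the control level — and is a deliberate
  extension of the minimal session/interaction pair.

Covariates (age, sex, months since implantation, pre/post motor and
depression scores, antidepressant use, VTA overlap) are drawn from
plausibility-anchored distributions with missingness concentrated in the
post-implantation scores; the raw pre/post scores are generated and the
derived covariates (relative motor improvement $(pre-post)/pre$, signed
depression change $post-pre$) are computed by the pipeline, so the
complete-case clinical analysis has genuine missingness to contend with.
What the generator does **not** emulate: between-subject heterogeneity of
the true network (all subjects in a condition share one precision),
scanner artefacts, motion, physiological noise, and spatial structure of
parcels. Passing tests therefore demonstrate the statistical machinery's
correctness and calibration under the assumed model, not robustness to
real-data pathologies.

## Numerical and design choices

* Degenerate inputs: constant time-series columns are zeroed with a
  warning; singular covariance at $\rho = 0$ raises an instructive error;
  rank-deficient designs name the collinear columns; an empty
  supra-threshold graph is a valid result (no components), not an error.
* Component ordering is deterministic (size descending, then lexicographic
  node list), and every permutation stream is seeded from a master seed by
  a fixed integer recurrence, so a config + seed pair reproduces every
  output file byte for byte.
* Group-mean imputation computes means over unique subjects, not
  subject-sessions, so paired rows are not double-counted; imputation is
  flagged in a provenance column. Raw pre/post clinical scores are never
  imputed — analyses that use them as dependent variables run on the
  complete-case subset.
* The Aim 2 clinical GLM omits motor improvement from its nuisance set
  because that covariate is derived from the same scores that form the
  dependent variable.
* The maximal-component-size statistic is integer-valued, so at sparse
  primary thresholds (few supra-threshold edges under the null) its
  permutation null is heavily tied and the achieved FWE level sits well
  below nominal — the test is conservative, never anticonservative. The
  calibration experiments therefore operate NBS at a denser threshold
  (|t| = 1.5 on the 20-node designs), where the size null is
  non-degenerate and the achieved level is close to 0.05. Detection
  analyses keep the sparser default (|t| = 3.0), where components are
  interpretable.
* The one-sample edge mask interacts with planted effects: an additive
  session delta on an edge whose baseline partial correlation is about
  minus half the delta gives a pooled ON+OFF mean near zero, and the mask
  removes the edge despite the strong session effect. Recovery experiments
  therefore plant effects on cross-community edges, whose baseline is
  exactly zero. On real data the analogous caveat applies: sign-flipping
  edges can be excluded by the masking step.
* Problem sizes in the test suite were chosen to keep the full suite in a
  few minutes while leaving each check statistically meaningful: oracle
  equivalence uses 8-node graphs (100 of them), calibration uses 200 null
  cohorts of 6 + 12 subjects at 20 nodes with 200 permutations, recovery
  uses 50 replicates of 40 patients, and the qualitative ordering uses 25
  replicates of 10 + 14 subjects. Planted effect sizes (partial-correlation
  deltas of 0.3–0.35 on 6–28 edges) were calibrated once against the
  simulation oracle to give high edge-level t at those cohort sizes; they
  are free parameters of the generator, not estimates of any study's
  effect sizes, which are not identifiable from published group
  statistics.
* The acceptance script runs the full pipeline at the emulated design
  scale (230 nodes, 81 + 20 subjects) with a permutation budget of 500,
  which resolves p-values to 1/501 — sufficient for the component-level
  decisions it reports.

## Known limitations

* Efficiency on negative weights is undefined here; published tables that
  print signed efficiency values cannot be compared in sign.
* NPC uses Fisher's combiner; other combiners (Tippett, Stouffer) would
  need a small extension of `npcFisher`.
* The permutation GLM assumes exchangeability within the chosen scheme;
  designs with nested blocks (e.g. site) would need block-restricted
  permutations, which are not implemented.
* With very small groups and many nuisance covariates the OLS fit can
  exhaust degrees of freedom; the rank check fails loudly rather than
  silently dropping columns.

## A minimal worked run

```{r example, eval = FALSE}
spec <- cohortSpec(nHC = 6, nPD = 12, nMADD = 6, nNodes = 20,
                   nTimepoints = 200,
                   sessionEffect = effectSpec(cbind(1:4, 2:5), 0.3),
                   seed = 1)
cohort <- generateCohort(spec)
cfg <- analysisConfig(nPermutations = 500, seed = 2)
bundle <- runAim1(cohort, cfg, outDir = "aim1_report")
subset(bundle$inference, comparison == "ON_vs_OFF")
```
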