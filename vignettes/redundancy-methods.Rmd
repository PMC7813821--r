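---
title: "Functional redundancy in brain connectivity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional redundancy in brain connectivity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redunet)
```

## The scientific question

Resting-state fMRI connectivity can be summarised as a graph: nodes are
parcellated brain regions, edges are strong pairwise correlations between
their BOLD time series. Most graph statistics describe how *efficiently* such
a network communicates. Redundancy asks a complementary question: how many
*alternative* routes connect two regions? A network in which region pairs are
joined by many direct and indirect routes can keep communicating when nodes
or edges fail — a candidate neuroprotective reserve mechanism in ageing,
where the hippocampus is damaged early. This package implements the full
analysis pipeline for that question: graph construction from ROI time
series, the redundancy / degree / efficiency metrics, and the inferential
machinery for comparing diagnostic groups (cognitively normal, early and
late mild cognitive impairment) and relating redundancy to cognition.

## Metrics

For a binary undirected adjacency matrix $A$ the pairwise redundancy is

$$R(i,j) = \sum_{l=1}^{L} p(i,j,l), \qquad L = 4,$$

where $p(i,j,l)$ counts routes of length $l$ between $i$ and $j$. The cap at
$L=4$ keeps the count local (and computable); longer detours are unlikely to
carry meaningful signal in a 300-node network at the densities analysed.

**Walks versus simple paths.** The route count is ambiguous: walks may
revisit nodes, simple paths may not. `counting_mode = "walks"` (the default)
takes $p(i,j,l) = (A^l)_{ij}$, the matrix-power walk count — the only
interpretation that is tractable at $n = 300$, and the standard matrix
formulation in the prior network-redundancy literature.
`counting_mode = "simple_paths"` enumerates self-avoiding paths by bounded
depth-first search and is available for graphs up to 500 nodes; both modes
are tested against exhaustive enumeration oracles on small graphs. All
counts are exact integers (held in doubles; the largest possible entry,
$n^3$ at $L=4$, is far below the 2^53 integer-exactness limit).

Aggregations: *nodal redundancy* is the row sum of $R$ (diagonal excluded);
*ROI redundancy* is the mean over a node's $n-1$ partner pairs, i.e. the row
sum divided by $n-1$. *Degree* $k_i = \sum_j A_{ij}$ is exactly the
length-1 term of nodal redundancy, which is why it serves as the control
metric: group differences present in redundancy but absent in degree must
come from indirect routes. *Global efficiency* is the mean inverse shortest
path length over ordered pairs, with unreachable pairs contributing 0 — the
convention matters because graphs thresholded at 2.5% density are routinely
disconnected. Shortest paths are delegated to igraph; tests verify the
result against an independent Floyd–Warshall implementation.

At whole-brain scale the package never materialises $R$: row sums of $A^l$
are accumulated by matrix–vector products, and the diagonal corrections use
the identities $\mathrm{diag}(A^2)_i = k_i$,
$\mathrm{diag}(A^3)_i = u^\top A u$ and
$\mathrm{diag}(A^4)_i = \lVert A^2 e_i \rVert^2$ with $u = A e_i$. Tests
assert exact agreement between this fast route and the full-matrix route.

## Graph construction

Edges are Fisher-z transformed Pearson correlations
($z = \operatorname{atanh} r$). Correlations with $|r|$ at 1 are clipped to
$1 - 10^{-7}$ before the transform (finite matrices; the event is reported).
Each subject's matrix is binarized at a grid of densities — by default 2.5%
to 25% in 2.5% steps, ten levels, the step being a configurable choice —
retaining exactly $\mathrm{round}(\rho\, n(n-1)/2)$ edges at density $\rho$,
so every subject has the same edge count and metric differences cannot be
driven by overall connectivity strength. Rounding is round-half-to-even;
ties in $z$ are broken by ascending $(i, j)$ node order, which makes
binarization deterministic across platforms and the stacks nested
(lower-density graphs are subgraphs of higher-density ones).

Edges are ranked by *signed* $z$, most positive first. Whether ranking
should use signed or absolute values is genuinely open; signed is chosen
because negative edges then never enter at the densities analysed, and the
overall-connectivity control analyses (`overall_connectivity()`) treat
positive-only and absolute-value summaries as separate, explicit checks.

Analyses are run per density and on the across-density average (the
arithmetic mean over the ten levels), the granularity at which results are
reported. Temporal band-pass filtering (0.008–0.09 Hz, zero-phase
Butterworth via forward–backward filtering; order a configurable knob,
default 2) is provided for real scans; the exact filter used upstream of a
given dataset is rarely fully specified, which is why the order is exposed.
Subjects with more than 50% of volumes flagged as motion outliers are
excluded (strictly greater — a subject at exactly 50% is retained), and
flagged volumes of retained subjects are censored.

## Inference

**Permutation ANCOVA.** Group comparisons of graph metrics avoid
distributional assumptions by permutation. The observed statistic is the
classical $F$ for the group term in $y \sim \mathrm{group} + \mathrm{covariates}$;
the null distribution follows the Freedman–Lane scheme — permute the
residuals of the covariate-only model, add them back to its fitted values,
recompute $F$ — which is the default of the reference R implementation of
permutation ANCOVA. The p-value is $(b+1)/(m+1)$ with $b$ the number of
permuted statistics at or above the observed one, so Monte-Carlo p-values
are never exactly zero. With no covariates the procedure reduces to the
ordinary permutation ANOVA used for the two-group post hocs. Education is
the default covariate; in post hoc pairs it enters only the eMCI–lMCI
comparison, mirroring a design where only those groups differ in education.
Post hoc p-values are Benjamini–Hochberg corrected within the family of
pairs tested per node (whether the correction family should span nodes is
undefined in this design; per-node is the default and configurable by
calling `pairwise_posthoc()` on a pooled family). Cohen's d uses the plain
pooled-SD definition on $n_1+n_2-2$ degrees of freedom with the asymptotic
standard error for its interval. Auxiliary comparisons (cognition scores,
overall connectivity) use parametric one-way ANOVA with Tukey HSD.

**Nodal ratios.** The magnitude of group differences per node is the ratio
of group-mean nodal redundancies (1 = equivalence). The two target
(posterior hippocampal) ratios are averaged and compared to a null built
from random node pairs: each of 10,000 draws picks two distinct non-target
nodes uniformly (with replacement across draws, mirroring the two-node
target average) and averages their ratios. The test is one-sided
($\geq$) because the hypothesis is directional. Only the target nodes are
excluded from the null pool; the draw scheme and exclusions are
configurable because the precise resampling protocol admits variants
(single-node nulls, wider exclusions).

**Regressions.** Cognition (MEM, EF) and global efficiency are regressed on
ROI redundancy, pooled and within groups, with education as covariate only
in the pooled efficiency fit; within MCI subjects the direction reverses
(redundancy on MMSE) as an alternative staging check. "Standardized β"
z-scores the outcome and the focal predictor but leaves covariates raw — the
convention that makes the simple-case β equal the Pearson correlation
(asserted to 1e-12 in tests). Every fit is repeated with Huber robust
regression (tuning constant 1.345, the standard 95%-efficiency choice) and
a Wald t test on the robust coefficient. Because standardization uses
sample SDs, a gross outlier inflates the scale of *both* estimators; the
robustness tests therefore assess resistance on the slope in original
units, where the Huber fit barely moves while OLS tilts.

## The synthetic cohort generator

No clinical data ship with the package; the generator creates cohorts with
the statistical structure the analysis assumes, so every stage is testable.

*Latent model.* A stochastic block correlation matrix: 12 contiguous
communities (echoing functional networks) with within-community correlation
0.4 and between-community 0.05 — values chosen to produce
density-thresholded graphs with hubs and modules at realistic sparsity.
Subject time series are i.i.d. multivariate normal rows (140 volumes at
TR = 3 s by default; a conventional resting-state scan length, chosen here
as a default rather than a property of any particular dataset). Group
sizes default to 39/54/37 (CN/eMCI/lMCI).

*Effect injection.* Group deficits are injected upstream, on latent edge
weights: all edges incident to the designated posterior-hippocampal target
nodes are attenuated by a factor $1-a$ in the MCI groups. Injecting
upstream rather than shifting the metric keeps the pipeline honest — the
effect must survive correlation estimation, thresholding and counting. The
mapping from a requested Cohen's d — defined per target node, on the
across-density ROI redundancy, the scale on which such effects are
conventionally reported — to $a$ was calibrated once by simulation (200
draws per arm) and stored as interpolation tables
(`redunet:::ATTENUATION_CALIBRATION`). The relation is visibly nonlinear
(moderately attenuated within-community edges still clear the density
threshold) and scale-dependent (ROI redundancy averages over fewer partners
in smaller parcellations, raising estimation noise), so tables are kept at
two reference scales, 300 nodes (the default conditions) and 100 nodes
(the simulation scale the package's own recovery tests use), and the
nearer table is inverted. The eMCI–lMCI difference defaults to zero (the
plateau the design stipulates).

*Cognition.* MEM is generated on the composite z-like scale (group means
1.01/0.47/0.07, SD 0.55) as
$\mu_g + \sigma\,(c\,z_{\mathrm{red}} + \sqrt{1-c^2}\,\varepsilon)$ with the
coupling $c = 0.3$ only in the CN group and $z_{\mathrm{red}}$ the
within-group z-score of the subject's realized target-ROI redundancy
(computed through the same connectome path the analysis uses). EF (means
0.78/0.49/0.22, SD 0.85) is uncoupled everywhere; MMSE, age, sex and
education come from simple truncated-normal covariate models, with the
lMCI > eMCI education gap that motivates the covariate policy. Motion
outlier flags are i.i.d. Bernoulli per volume (rate 0.03).

*What the generator does not emulate:* haemodynamics, scanner noise,
autocorrelated BOLD spectra, motion artefacts beyond boolean flags,
spatially embedded (distance-dependent) connectivity, or between-subject
heterogeneity in the latent covariance — between-subject variance in
metrics arises purely from correlation-estimation noise at 140 volumes.
Passing tests therefore demonstrate that the *pipeline* recovers known
upstream structure, not that real data satisfy these models. Because the
generator's series are spectrally flat, the pipeline's band-pass stage is
off by default for synthetic cohorts (it would only discard degrees of
freedom); it exists for real scans.

## Numerical and design choices

- All randomness flows from a single seed; child seeds are derived for
  subjects, permutation tests and null draws, and every result object
  records its seed and draw count. The caller's RNG state is never
  clobbered.
- Permutation and null-draw counts default to 10,000; the simulation-based
  tests in the package use 200–500 permutations and 100-node cohorts, sizes
  chosen so the whole suite completes in minutes while leaving Monte-Carlo
  error well inside the asserted bands (stated per test).
- Covariances are factored by eigendecomposition with negative eigenvalues
  below $-10^{-8}$ treated as errors and tiny negatives clamped to zero, so
  rank-deficient (attenuated) covariances are accepted.
- Degenerate inputs fail loudly: constant time series name the node,
  constant responses refuse the F test, zero denominators in ratio sets are
  flagged and excluded from ranking, all-negative rows in positive-only
  connectivity return 0 with a warning.
- The analysis operates on raw metric values; any normalization is left to
  visualization.

## Known limitations

Walks-mode redundancy counts revisit-permitting routes, so it grows
combinatorially with degree and is best interpreted comparatively (between
groups at fixed density) rather than absolutely. The ratio null test
conditions on the observed ratio set and ignores spatial autocorrelation
between nodes. The generator's simplifications listed above mean absolute
metric scales in synthetic cohorts should not be compared to real data.
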