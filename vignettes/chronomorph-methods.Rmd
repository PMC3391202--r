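---
title: "Methods behind chronomorph: size-adjusted morphospaces, time-scaled trees, and chronophylomorphospaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind chronomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomorph)
```

chronomorph is a toolkit for asking how a clade's morphological diversity is
distributed across its phylogeny and through geological time. It was designed
around the workflow used in comparative studies of skull shape in clades that
mix extant species with fossils: specimen-level linear measurements are
size-adjusted and ordinated; group separation and classifiability are tested
at the specimen level; a composite phylogeny is time-scaled from fossil
occurrence dates and molecular node dates; phylogenetic signal in the species
means is quantified; and finally the phylogeny is embedded in trait space,
with or without a temporal axis (a *chronophylomorphospace*, CPMS). This
vignette explains each model, the tunable parameters and their defaults, the
numerical choices, and what the accompanying synthetic-data generators do and
do not emulate.

## Size adjustment: Mosimann shape variables

Linear measurements confound size and shape. For a specimen with $k$
measurements $a_1,\dots,a_k$ (all strictly positive, same unit), the
geometric mean $\mathrm{GM} = (\prod_i a_i)^{1/k}$ is an isometric size
estimate in the same unit, so the ratios $z_i = a_i/\mathrm{GM}$ are
dimensionless shape variables. Two exact properties follow and are enforced
by tests: $\prod_i z_i = 1$ for every specimen, and invariance of the $z_i$
under multiplication of a specimen's row by any positive constant. Unlike
regression residuals, the correction uses only the specimen's own values.
`geometric_mean()` works in log space, so products of 29 measurements in the
hundreds of millimetres do not overflow or lose precision.

The morphospace is a principal component analysis of the shape variables
with unit-variance scaling (`pca_morphospace(standardize = TRUE)`), i.e. an
eigendecomposition of the correlation matrix, computed through the singular
value decomposition of the standardized data matrix for numerical stability.
Axis signs are made deterministic by forcing the largest-magnitude loading
on each axis positive, so plots and downstream statistics are reproducible
across platforms. Constant columns are rejected when standardizing — a
correlation with a zero-variance variable is undefined, and silently
dropping data would be worse than an error. `axes_for_cumulative_variance()`
implements the usual retention rule (smallest leading set of axes reaching a
target fraction, default 90%). Species centroids (arithmetic means of
specimen scores) are the tip data for all phylogenetic analyses.

## Classification: LDA with leave-one-out validation

`lda_fit()` is the shared-covariance Gaussian classifier: group means, a
pooled within-group covariance $S$ (divisor $n - g$), and priors that
default to group proportions (`"uniform"` and explicit priors are
available; the choice matters for strongly unbalanced designs).
`jackknife_classify()` refits the full model $n$ times, each time excluding
one specimen and predicting it from the rest — no rank-one shortcut is
taken, so the fold model is exactly the documented procedure. Per-specimen
posterior probabilities are retained; the confusion table reports per-group
and overall accuracies, where overall accuracy is identically the
group-size-weighted mean of per-group accuracies.

When $S$ is ill-conditioned (collinear measurements), a ridge term
$\lambda I$ with $\lambda = 10^{-8}\,\mathrm{tr}(S)/k$ is added and the event
is reported; tests verify the classifier still agrees with an independent
implementation on well-conditioned data (posteriors match `MASS::lda` to
$10^{-6}$).

## Group separation: NPMANOVA

Permutational MANOVA operates on squared Euclidean distances among the
supplied axes (the caller selects which axes — typically the leading PCs; no
re-ordination happens internally). With $a$ groups of sizes $n_g$:

$$SS_\text{total} = \frac{1}{n}\sum_{i<j} d^2_{ij},\qquad
  SS_\text{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},\qquad
  F = \frac{SS_\text{among}/(a-1)}{SS_\text{within}/(n-a)}.$$

Significance comes from random permutations of group labels with the $+1$
convention, $p = (\#\{F_\pi \ge F_\text{obs}\}+1)/(B+1)$, so $p = 0$ is
impossible and the smallest attainable value with $B = 9999$ permutations is
$10^{-4}$. In one dimension with two groups the pseudo-$F$ reduces exactly
to the classical ANOVA $F$ (verified to $10^{-10}$), and the type-I error at
$\alpha = 0.05$ is calibrated under the null (500-replicate check).
`pairwise_npmanova()` re-permutes independently for every pair (rather than
reusing one global permutation set — the conservative reading of the
sequential design) and applies the Holm step-down (sequential Bonferroni)
correction via `p.adjust`.

The test units are specimens, not species centroids: the specimen-level
design deliberately omits phylogenetic correction, which is appropriate for
within-species replicated data; a centroid-level test can be run by passing
centroids as the points.

## Time-scaling a composite tree

`time_scale()` converts a topology plus a calibration table into a
`timetree`, whose single source of truth is the vector of node ages
(Ma before present); branch durations are always derived as
`age(parent) - age(child)`, so the two can never disagree.

Terminal dating has three modes. In the default (`"main"`) mode, fossil tips
sit at the arithmetic midpoint of their stratigraphic range — uncertainty in
fossil dating is typically an interval, and the midpoint is the neutral
point estimate — while extant tips are dated by first occurrence for
internal-node purposes and their terminal branches extended to the present
(0 Ma). The `"range"` mode dates all nodes by first occurrences and extends
every terminal branch to its last occurrence (ranges treated as known
durations); the `"midpoint"` mode uses midpoints for all taxa with the
present as the upper margin for extant tips. Internal nodes then take the
maximum of any molecular date attached to them and the ages of their
children, enforced by a post-order sweep, so a parent is never younger than
a child. Molecular dates are attached by the most recent common ancestor of
a named tip pair (`mrca_of = "tipA|tipB"` in the calibration CSV): a file
convention is needed because published dates are usually keyed to figures,
not to machine-readable node identifiers. A molecular date younger than a
fossil constraint is overridden by the fossil (the max rule) and reported; a
molecular date that pushes a node above an already-dated ancestor is
propagated upward by a second post-order pass.

Identical first occurrences of a taxon and its subtending node produce
zero-duration branches. `resolve_zero_branches()` offers two policies. The
default `share` policy finds, for each maximal zero-length chain, the
nearest ancestral branch with positive duration and re-spaces the chain's
node ages linearly below it, sharing that duration equally along the chain;
ages outside the chain — hence root-to-tip ages of unaffected tips — are
untouched. The `epsilon` policy instead imposes a minimum duration by
pushing each offending child younger by a configurable ε (default 0.1 Myr),
cascading tipward. `share` is the default because it conserves the total
time span instead of inventing new time. One situation is a hard error by
design: a zero chain reaching the root. The root is always dated by its
oldest descendant unless an older constraint exists, so scaling a tree whose
deepest calibration is a terminal taxon requires a root (or deep-node)
date — exactly what molecular trees provide in practice. The synthetic
generator therefore emits a molecular root date with its calibrations.

`graft_subtree()` supports composite phylogenies: a supraspecific terminal
(e.g. a subfamily coded as a single OTU in a cladistic matrix) is replaced
by a fully resolved donor tree before scaling. `prune_tree()` restricts the
scaled tree to the morphometric sample, collapsing unary nodes with
durations summed, so patristic distances and absolute ages of retained tips
are preserved exactly (tested against an explicit path-sum oracle).

## Discrete characters: scoring, not searching

`read_char_matrix()` parses TNT `xread` and NEXUS matrices with polymorphic
(`[01]`, `(01)`, `{01}`) and missing (`?`, `-`) cells; missing cells enter
computations as the full set of states observed for that character.
`score_supraspecific_otu()` implements the majority-style rule for
collapsing five member species into one terminal: sums of 0–1 score 0, 2–3
score polymorphic `{0,1}`, 4–5 score 1, with non-binary characters passed
through only under a 4-of-5 consensus.

`fitch_length()` scores a *given* topology by the Fitch set recursion
(intersection if non-empty, else union plus one step), with polymorphic tips
entering as their state sets — matching how polymorphism is written in the
matrix rather than resolving it per character. Tree search is deliberately
out of scope; the package evaluates published or externally inferred
topologies. The implementation is validated two ways: against exhaustive
minimization over all internal-state assignments on hundreds of random
instances, and against `phangorn::parsimony` on fixed-state matrices.

For the ensemble indices, each character needs its minimum steps $m_i$
(over all trees) and maximum steps $g_i$ (star-tree length). With
polymorphism, $m_i$ is one less than the size of a minimum hitting set of
the tip state sets (exact by subset enumeration; states are bounded at 10),
and $g_i = n_\text{scored} - \max_s(\text{tips whose set contains } s)$,
which lets every polymorphic tip align with the cheapest centre state
without an arbitrary tie-break. A character is treated as
parsimony-uninformative when $g_i = m_i$ — its fit is the same on every
tree — which makes the exclusion variant of the consistency index exactly
invariant to adding such characters. Because published values of the
rescaled consistency index are not always consistent with one CI convention,
both $CI$ variants and both $RC = CI \times RI$ conventions are always
reported, with `rc_convention` selecting the headline value (default:
all-characters CI).

## Phylogenetic signal

**PCO eigenvectors.** `pco_eigenvectors()` double-centres the squared
patristic distance matrix (Gower) and eigendecomposes it; variance fractions
are computed over positive eigenvalues and the smallest prefix reaching the
cutoff (default 95%) is retained. "Distances built from branch lengths" is
read as patristic path sums; a square-root option (`sqrt_dist`) is provided
because square-root patristic distances are always Euclidean-embeddable,
whereas raw patristic distances can produce negative eigenvalues on some
trees — with the default, negative-eigenvalue axes are simply excluded from
the variance accounting.

**PVR and MPVR.** Phylogenetic eigenvector regression is ordinary least
squares of a trait on the retained eigenvectors plus an intercept; its $R^2$
is the fraction of trait variance attributable to phylogeny. With all $n-1$
eigenvectors any response is reproduced exactly ($R^2 = 1$, the saturation
identity used as a test), which is why the cutoff matters. The multivariate
form regresses every response column on the same predictors and pools
variance by traces, $R^2_\text{tot} = 1 - \sum_j RSS_j / \sum_j SST_j$ —
appropriate when responses are PC scores already on comparable variance
scales — and tests overall significance by Wilks' Λ with Rao's F
approximation (the determinant-based Λ is reported alongside the trace-based
fraction). All retained axes are used as predictors; no further selection
step is applied.

**Independent contrasts and Blomberg's K.** `pic_contrasts()` is the
Felsenstein recursion (contrast $(x_i-x_j)/\sqrt{v_i+v_j}$,
precision-weighted ancestral working values, parent branch lengthened by
$v_iv_j/(v_i+v_j)$), vectorized over columns so that permutation tests cost
one traversal. Polytomies are rejected with a clear error rather than
silently resolved — the intended input is a fully resolved composite tree.
K compares the observed ratio $MSE_0/MSE$ (variance around the GLS mean
over GLS mean squared error, with $V$ the Brownian tip covariance) to its
Brownian expectation $(\mathrm{tr}\,V - n/\mathbf{1}'V^{-1}\mathbf{1})/(n-1)$.
On a star tree $V = v I$ makes observed and expected ratios both $v$, so
$K = 1$ identically for any data — an exact algebraic identity used as a
test at $10^{-8}$. The permutation significance shuffles tip values and
compares mean squared contrasts (+1 convention); because it standardizes by
contrasts it requires a binary tree, and on polytomous trees K is returned
with `p = NA` and a message. Under Brownian simulation the suite checks that
mean K sits in [0.9, 1.1], that mean squared contrasts recover σ² within 5%,
and that the permutation test's type-I rate at α = 0.05 lies inside the
binomial 95% band.

## Ancestral states and the chronophylomorphospace

With tips fixed, the Brownian-motion maximum-likelihood ancestral states
minimize $\sum_\text{edges} (\Delta x)^2/\text{duration}$ — a weighted
least-squares problem solved exactly as one linear system in the
internal-node block of the tree's $1/\text{duration}$-weighted graph
Laplacian (`ancestral_ml()`). This is also the weighted squared-change
parsimony solution, which is why no separate "parsimony" estimator exists.
The root estimate coincides with the GLS phylogenetic mean
$(\mathbf{1}'V^{-1}\mathbf{1})^{-1}\mathbf{1}'V^{-1}x$ (verified
algebraically per instance), and the whole solution matches direct numerical
minimization to $10^{-6}$ on random instances.

The Brownian rate σ² is estimated by REML by default — the GLS quadratic
form divided by $n-1$, which equals the mean squared independent contrast on
binary trees but is defined for any tree — with an ML option (divide by
$n$); which of the two a published figure used is rarely stated, so both are
exposed. Per-node estimation variances are $\hat\sigma^2$ times the diagonal
of the inverted internal Laplacian block, and 95% intervals use the normal
multiplier 1.96. With estimated σ² the intervals are slightly liberal
(normal rather than t quantiles); at the tree sizes the package targets
(tens of tips) simulated root coverage sits within two points of the nominal
95%, which the acceptance suite checks over 1000 replicates on a 100-tip
tree.

Traits are reconstructed independently per axis — the target use is two PC
axes reconstructed separately — so correlated multi-trait Brownian motion is
out of scope.

`build_phylomorphospace()` places tips at their observed scores and internal
nodes at the ML estimates, with edges given by the tree.
`build_cpms()` adds the temporal coordinate: each node's age from the
`timetree`, so extant tips sit at 0 Ma, fossil tips at their assigned
(midpoint) dates, and every edge runs from older to younger. The age column
is copied from the tree, never recomputed, so dropping it reproduces the
two-dimensional phylomorphospace bit-for-bit (a tested identity). The 1-D
variant (`build_cpms_1d()`) plots one trait against age and carries the 95%
intervals per internal node. Ages are stored as Ma-before-present
throughout; plotting orientation is a rendering choice, not data. Graphs
export to JSON or a nodes/edges CSV pair and re-import losslessly; a static
plot is provided, while interactive or animated 3-D rendering is left to
dedicated tools.

## The synthetic study system

The generators exist so the whole pipeline can be exercised, with known
truth, from a single seed. `sim_birth_tree()` draws an ultrametric
pure-birth tree and truncates a configured fraction of terminal branches
into fossil tips (truncation point uniform over the middle 70% of the
branch); the attached calibration table draws each fossil's first/last
occurrence symmetrically around the true truncation age — clipped by
shrinking the half-width near the present — so midpoint dating recovers the
true ages exactly and time-scaling round-trips. Extant taxa get a first
occurrence inside their terminal branch, and a molecular root date (the true
root age) accompanies the table, as it would in any real study combining a
molecular tree with fossils. `sim_bm_traits()` draws from the exact
multivariate normal implied by Brownian motion, with a Pagel-λ dial scaling
the shared-path covariance (λ = 1 pure Brownian, λ = 0 star-equivalent);
the dial is monotone in expected K, which is tested at λ ∈ {0, 0.5, 1}.
`sim_specimen_table()` maps species Brownian log-means through `exp()` (so
all measurements are positive, as the Mosimann transform requires), adds
within-species log-normal noise, and multiplies each specimen by a shared
log-normal size factor — by construction, Mosimann shapes within a species
are identical when within-noise is zero, however large the size scatter.
Lineage labels are true clades obtained from the oldest $k-1$ splits.

Defaults were fixed once to emulate a felid-like study: 52 species (about a
third fossil), 29 measurement variables, 11 lineages, 2 + Poisson(4.3)
specimens per species (~330 total), birth rate 0.18/Myr (a ~25–30 Myr root),
Brownian rate 0.01 per Myr on log-measurements, within-species noise sd
0.05, size-factor log-sd 0.12, and fossil range half-width 0.5 Myr. These
are plausible magnitudes for cranial measurements in a recent mammalian
radiation, not a fit to any real covariance structure: the generator does
not mimic real among-variable correlations, allometry, sampling biases, or
measurement error, so passing tests demonstrate the correctness and
calibration of the algorithms under their stated models — not that any
biological conclusion follows for a particular empirical dataset.

## Problem sizes and costs

The test and acceptance suites run on one CPU in a few minutes total. The
statistically expensive checks use: 200 six-tip instances for the parsimony
oracle; 500 Brownian replicates on 50-tip trees for the K calibration (199
permutations per replicate for the type-I check); 50 twenty-tip instances
plus 1000 replicates on a 100-tip tree for the ancestral-state oracle and
root coverage; and 500 replicates of 999 permutations for the NPMANOVA
type-I check. Permutation defaults in the user-facing functions are 9999
with a mandatory seed in the CLI; all generators are bit-reproducible under
their seed.

## Known limitations

* No phylogenetic tree search, bootstrap, or decay indices — scoring only.
* No Ornstein–Uhlenbeck or multi-rate trait models; the λ dial is a
  simulation device, not a fitted parameter.
* No landmark/Procrustes geometric morphometrics; the shape model is ratios
  of linear measurements.
* NPMANOVA covers one-way designs only (no dispersion test, no nesting).
* CPMS output is static coordinates and figures; interactive 3-D viewers
  are intentionally not bundled.
* Confidence intervals on ancestral states use normal quantiles with a
  plug-in σ²; for very small trees they will be anticonservative.
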