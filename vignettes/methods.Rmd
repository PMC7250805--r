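---
title: "From profile-HMM scores to a single dominant function: the model behind hmmann"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From profile-HMM scores to a single dominant function: the model behind hmmann}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmann)
```

## The problem

A protein of unknown function scored against a panel of function-specific
profile HMMs yields one raw bit score per candidate function. Any single
score is a noisy, scale-heterogeneous signal: profiles differ in length,
information content and training-set depth, so the argmax column alone is a
fragile classifier. `hmmann` implements an integrative pipeline that turns
the whole score vector into a single well-behaved scalar, partitions the
scalar axis into per-function confidence intervals, and lets a small neural
network place each sequence into exactly one interval — one *dominant*
function per sequence, or an explicit refusal.

The candidate set (the "superset" $A$, $|A| = n \ge 3$) must be chosen by
the analyst; the axiomatic minimum of three functions runs through every
stage and is enforced everywhere.

## Combinatorial feature expansion

From the $n$ raw scores $\alpha_i \ge 0$ we form all unordered score pairs
$B$ ($|B| = \binom{n}{2}$) and all unordered pairs of distinct pairs — the
pair-of-pairs (POP) set $D$, $|D| = \binom{|B|}{2}$, identically equal to
the quartic $0.125n^4 - 0.25n^3 - 0.125n^2 + 0.25n$. $|D|$ is the input
width of the network, so superset size dictates architecture:

```{r}
architecture_table(8)
```

H1–H3 are the three hidden-layer sizing heuristics
($0.5(|D|+1)+\sqrt{|D|}$, $2\sqrt{|D|+1}$, $2(|D|+1)/3$), rounded half away
from zero — the rule that reproduces the reference table at every size.
Back-propagation networks of this 1:1:1 shape (one input layer, one hidden
layer, one output unit) stop benefiting from hidden nodes somewhere near 18,
which caps the practical superset size at $3 \le |A| \le 6$
(`feasible_superset_sizes(18)`); the cap comparison carries a 20%
multiplicative slack because the node budget is an order-of-magnitude guide,
not a wall — at $n = 6$ the smallest heuristic gives 21, which practitioners
still run.

Two deliberate faithfulness notes. First, the canonical POP enumeration
couples *every* pair with every other pair; the chained variant (two pairs
sharing one index) is exposed via `enumerate_pops(chained = TRUE)` for study
but is inconsistent with the reference counts (12 vs 15 at $n = 4$) and is
never used by the pipeline. Second, `fitted_cardinality()` ships the
published regression curves verbatim, including the $|B|$ polynomial whose
printed linear coefficient ($-0.25$) does not reproduce the exact binomial
count (it yields 3.75 at $n = 3$); all computation uses the exact forms, the
curves exist for comparison only and are never re-fitted.

## POP scores, standardization scope, and the beta line

Each POP collapses its four score slots to one number. How the four slots
combine is a pluggable *strategy* recorded in every fitted object; the
default `mean4` is their arithmetic mean (a shared column, when the two
pairs overlap, is counted each time it appears), with `sum4` and `geomean4`
as alternatives. The choice is the package's own: the combining rule is the
one genuinely under-determined primitive in this design, and the mean is the
least surprising scale-preserving option.

The raw POP matrix is then z-standardized **per POP column across the
training corpus**, so each POP value becomes its own z-score, and the
per-sequence beta-value is the row sum over all $|D|$ standardized columns.
The standardization scope matters: standardizing within a sequence instead
would force every beta to exactly zero (a row sum of its own z-scores),
collapsing the clustering stage. A corollary worth knowing: the *corpus*
mean of beta is exactly zero by construction, so functions separate on the
beta line only through between-class structure, never through a global
offset. Zero-variance POP columns are flagged and mapped to zero both at fit
time and on new data.

## Clusters, chi-squared refinement, intervals

Training sequences of known function form per-function clusters on the beta
line. The centroid is the cluster mean — which is also the minimizer of the
within-cluster sum of squared deviations (the test suite checks this against
a golden-section search). Cluster tightness is summarized by
$\chi^2 = \sum_m (\beta_m - \beta')^2 / \beta'$, exactly zero for a constant
cluster. Because standardized betas can be non-positive while the statistic
assumes a positive denominator, a positivity shift $c = 1 + |\min|$ is
applied to members and centroid together whenever any value is $\le 0$; the
shift preserves the zero point and the ordering of $\chi^2$ across candidate
refinements, and is recorded alongside the statistic. Members at or beyond
one cluster standard deviation from the centroid are flagged as refinement
candidates, and an unsupervised k-means concordance check (`stats::kmeans`,
10 seeded restarts) reports how recoverable the labelled structure is from
beta alone.

Each cluster then gets a confidence interval for its centroid:
$\beta' \pm t_{\alpha/2}\,\sigma/\sqrt{|G|}$ with $|G|-1$ degrees of freedom
for clusters under 30 members, the normal quantile from 30 up
(default $\alpha = 0.05$). A zero-sigma or singleton cluster degenerates to
a point interval with a warning rather than an error. The sorted intervals
form the partition; disjointness is checked strictly because the intervals
are open — a prediction exactly on a boundary is *unassigned*, never
silently snapped. The enclosing search-space bounds use the wider
$\pm\sigma$ band around the extreme centroids, $a = \min\beta' - \sigma$,
$b = \max\beta' + \sigma$, and the partition's outer measure is $|b - a|$;
the two scales (standard error for the intervals, whole sigma for the
bounds) are both implemented exactly as specified by the method and are not
reconciled here. The mapping probability $\tau = 1/n$ spans $0.33$ down to
$0.166$ (truncated, as conventionally quoted) across the feasible range
$3 \le n \le 6$.

Non-disjoint partitions are detected, warned about, and degrade prediction
to an explicit `ambiguous` status listing all containing intervals plus a
nearest-centroid suggestion; a `strict` flag turns them into errors for
pipelines that require the disjointness assumption to hold. Interval
expansion at mapping time defaults to $\varepsilon = 0$; the preset
`epsilon = "sigma"` widens each interval by its own cluster sigma,
recovering the one-sigma band around each centroid.

## The network

The regressor is deliberately minimal: $|D|$ inputs, one hidden tanh layer,
one identity output producing the scalar $\beta''$. Hidden size is the
chosen heuristic (default: the minimum of H1–H3) capped at `node_cap`
(default 18). A single output is kept although it is the ill-conditioned
choice — an unbiased one-dimensional assignment is the point of the method —
and no softmax variant exists here.

Training minimizes mean squared error between $\beta''$ and each training
sequence's target, namely its own function's centroid, so the network learns
the map from POP space onto the centroid line. The optimizer is full-batch
resilient propagation (iRprop$^-$): each weight carries its own step size,
grown 1.2$\times$ while its gradient keeps sign, halved on a sign flip, with
the flipped step skipped and the best weights retained. Resilient
propagation is the standard trainer for small dense feed-forward networks of
exactly this shape, and in our experiments plain gradient descent (fixed or
bold-driver adapted step) reliably stalled an order of magnitude short of
the loss this architecture can reach, which matters because prediction
spread must be narrower than the interval half-widths. Targets are
standardized internally for conditioning; predictions are returned on the
original scale. Defaults: at most 5000 epochs, initial step 0.01, early stop
once the best loss has failed to improve by a relative $10^{-6}$ for 25
consecutive epochs. Everything is full-batch and seeded: a fixed
configuration and dataset reproduce identical weights, and serialized models
(JSON, no timestamps) are byte-identical across reruns.

Weight initialization is small-uniform ($U(-0.5, 0.5)/\sqrt{\text{fan-in}}$),
keeping the tanh units near their linear regime at the start; this is what
lets the same architecture recover a noiseless linear teacher with held-out
correlation above 0.999, the sanity bound the network must clear before its
nonlinearity is trusted.

## Validation

Three modes. *Holdout*: a seeded stratified split (default fraction 0.275,
the midpoint of the conventional 25–30% band; stratification by function is
our choice) — intended for clusters of 30 or more. *Leave-one-out*: one
refit per held-out sequence, for small clusters. *Empirical*: fit on
everything and check each assigned label against the argmax raw-score
column, the external sanity criterion (argmax is taken over the sequence's
per-function raw scores). Precision and recall per function count only
strictly assigned sequences, so an unassigned sequence costs recall;
`accuracy_resolved` additionally resolves ambiguous/unassigned sequences to
the reported nearest centroid. Mode/size mismatches warn rather than error.

## What the synthetic generator does and does not emulate

`simulate_scores()` draws function-$k$ sequences from Gaussians with the
$k$-th column mean elevated to
$\text{base} + k \cdot \text{separation} \cdot \text{noise\_sd}$, all other
columns at base, truncated below at the score floor (default 0, honouring
score positivity; the default base of 10 bits with unit noise makes
truncation negligible). Defaults are 3 functions $\times$ 30 sequences at
separation 6, the regime in which the interval partition is reliably
disjoint.

The *staggered* elevation (proportional to $k$) rather than an equal bump
for every function is load-bearing: with equal elevation the corpus is
permutation-symmetric across functions, and one can show the class means of
beta then coincide exactly — column standardization plus the row sum cancel
any exchangeable structure — so no amount of separation would reach the beta
line. Distinct per-function score magnitudes are also what real profile
panels look like: profiles differ in length and information content, so
their in-family score scales differ.

What this generator does **not** emulate: inter-profile score correlation
from shared domains, heavy-tailed score noise, unbalanced cluster sizes,
inter-sequence redundancy, and sequences whose true function is outside the
superset. Passing recovery tests on this generator therefore demonstrates
that the machinery is correct and well-conditioned, not that any particular
biological panel will separate; on real data the partition may be
non-disjoint, which the pipeline surfaces rather than hides.

Problem sizes used by the shipped tests and the acceptance script — 3 or 6
functions, 10–30 sequences per function, separations 0–6, five seeds for
the recovery curve — were chosen as the smallest designs at which the
behaviour under test is stable, so the whole suite runs in well under a
minute.

## Numerical choices and degenerate inputs, collected

* Negative raw bit scores are clamped to 0 with a warning (opt-out
  available); missing (sequence, function) cells are imputed 0, sequences
  missing more than half their functions are dropped; duplicate hits keep
  the maximum score.
* Zero-variance POP columns: flagged, standardized to 0, excluded from sd
  bookkeeping.
* Singleton clusters: sigma 0 with a warning; their intervals degenerate to
  points.
* Chi-squared positivity shift $c = 1 + |\min|$, recorded.
* Ties and boundaries: open intervals, strict containment, boundary hits
  unassigned with a warning; ambiguity always reported, nearest-centroid
  suggestion never silently applied.
* Half-away-from-zero rounding for H1–H3.
* k-means with fewer distinct beta values than clusters falls back to
  clustering by value (the optimal partition in that degenerate case).
* All seeds (weights, splits, k-means restarts, generator) are explicit
  config fields serialized with every output.

## Known limitations

The method's single scalar bottleneck means functions whose POP profiles
differ but whose beta projections coincide are indistinguishable —
separability on the beta line is an assumption, checked (disjointness,
k-means concordance) but not guaranteed. The feasibility cap restricts
practical supersets to six candidates; larger panels must be pre-clustered.
The suitability index used to filter training sequences is consumed as a
pre-computed column, never computed here. And the fitted reference curves
are evaluated, not re-fitted: their fitting protocol is not part of this
package's claims.
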