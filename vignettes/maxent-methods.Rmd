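---
title: "Methods: maximum-entropy niche modelling of overwintering groves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche modelling of overwintering groves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groveniche)
```

## The model

`groveniche` fits a presence-only species distribution model of the Maxent
family. The study area is a raster grid; the *background* is the set of valid
cells (all of them, or a seeded sample when the grid is large). Each cell $x$
has a feature vector $f(x)$ built from the climate layers, and the model is
the Gibbs distribution over background cells

$$q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z_\lambda}, \qquad
  Z_\lambda = \sum_{x' \in \text{background}} \exp(\lambda \cdot f(x')).$$

The coefficients maximize the penalized log-likelihood of the $m$ presence
cells,

$$\ell(\lambda) = \bar f \cdot \lambda - \ln Z_\lambda
  - \beta \sum_j s_j\, |\lambda_j|,$$

where $\bar f$ is the mean feature vector over presences and
$s_j = \mathrm{sd}(f_j \mid \text{presences})/\sqrt{m}$ scales each penalty
by the sampling uncertainty of the corresponding presence mean. $\beta$ is
the single *regularization multiplier* the selection protocol tunes. At the
optimum the soft-moment conditions hold:
$|\mathbb{E}_q f_j - \bar f_j| \le \beta s_j$, with equality (signed) at
every non-zero coefficient.

*Features.* Three classes per layer: linear, quadratic, and pairwise
products, each rescaled to $[0,1]$ over the background. Constant layers are
dropped with a warning.

*Logistic output.* Maps the raw distribution to an interpretable relative
probability of presence: $p(x) = e^H q(x) / (1 + e^H q(x))$, where $H$ is
the entropy of $q$. A fully-shrunk (uniform) model has $p = 0.5$ everywhere.

*Assumptions.* Presence cells are an unbiased sample of occupied habitat
(no detection-effort correction is applied); one representative point per
grove after the occurrence-reduction step; background cells characterize the
available environment.

## Fitting

The trainer (`fit_maxent()`) is cyclic coordinate descent with exact
one-dimensional soft-threshold solves, implemented in C++. Each coordinate
update solves its subproblem to Newton precision; a batch gradient computed
once per sweep allows exact KKT-based skipping of zero coordinates.
Convergence requires two consecutive sweeps improving the objective by less
than `tol` (default `1e-8`); the objective-gain accumulated by each update is
the basis of percent contribution (product features split evenly between
their parents). The test suite checks the trainer cell-by-cell against an
independent brute-force grid-refinement optimizer on small problems.

## Model selection

Models are scored by AICc, $2k - 2\ln L + 2k(k+1)/(n-k-1)$, with $k$ the
number of non-zero coefficients (L1 zeroes coefficients exactly) and $n$ the
presence count; AICc is undefined when $n - k - 1 \le 0$. The $\beta$
protocol has three stages, each averaging AICc over seeded bootstrap
replicates of the presences (default 10):

1. coarse sweep over integers 1–7;
2. 0.1-step bracketing between the coarse optimum's integer neighbours
   (truncated below at 0.1);
3. after variable elimination, a final scan of 0.1–2.0 on the retained
   layers.

Ties break toward the smaller $\beta$. Every fit cold-starts, so the record
at a given (β, replicate) is identical whichever scan computes it; bracketing
therefore can never do worse than the coarse stage it refines.

## Variable elimination

Pairwise Pearson correlations are computed once over the full stack's valid
cells. The iterative cycle: fit at the stage-2 $\beta$; (strict method only)
drop layers contributing less than 5% — never the current top; promote the
highest-contribution layer (ties to the lexicographically smallest name);
drop remaining layers with $|r| \ge 0.7$ against the new top; repeat until
every layer is promoted or dropped.

Two procedures share this engine: the strict one applies the 5% rule, the
relaxed one (`eliminate_uncorrelated()`) does not, keeping weak but
uncorrelated variables. The relaxed retained set always contains the strict
one. A cycle whose fit is fully shrunk (no gain) treats all contributions as
zero ties. Each run emits a trace that `replay_trace()` can re-derive
decision by decision.

## Projection and shift diagnostics

`project_model()` rebuilds the features on a target stack with the
*training* scaling ranges, clamping out-of-range raw values to them (the
count of clamped entries is recorded), renormalizes $Z$ over the target's
valid cells, and reuses the training entropy in the logistic transform
(`recompute_entropy = TRUE` switches to the target entropy for sensitivity
checks). `shift_report()` summarizes current-versus-projected surfaces:
cells above thresholds, the surface–elevation Pearson correlation (the
headline diagnostic for upslope shifts under warming), and difference-map
statistics. A projected surface whose mean probability falls below a
configurable threshold flags the run as non-transferable.

## Synthetic study system

The generator produces a coastal landscape: a monotone coast-to-inland
elevation ramp (default 100×100 cells at 30 arc-seconds, up to 1500 m), two
smoothed coast-parallel ridges, and Gaussian-smoothed relief noise. Monthly
climate layers (October–February) derive from elevation with a lapse-rate
analogue (−6.5 units per km for the temperature variables), a
coast-distance term, and smoothed noise; months of one variable share a
noise field with weight `shared_rho` (default 0.85), reproducing the strong
within-variable collinearity of real monthly climatologies. The true niche
is a logistic function of a small set of standardized layers; grove centers
are drawn without replacement with probability proportional to suitability,
and each grove scatters 1–3 records by a truncated normal. All randomness
flows through named substreams of one seed, so every artifact is
reproducible.

*Realism and limits.* The generator captures the properties the methods
exercise — elevation-coupled climate, collinear months, clustered
presence-only records, scenario deltas — but it is not a climate model:
fields are stationary Gaussian-smoothed noise, the niche is a two-variable
logistic, and there is no observation bias. Note that with the default
`shared_rho`, month layers correlate ~0.98: elimination then correctly
collapses each variable to one representative month, but *which* month is
arbitrary — recovering a specific named layer is only a well-posed question
when the layers carry identifying variation of their own (the recovery tests
lower `shared_rho` for exactly this reason).

## Numerical choices

- ASCII grids are written with 17 significant digits so finite values
  round-trip bit-identically (6 digits cannot represent e.g. a 30
  arc-second cellsize exactly).
- Convergence tolerance `1e-8` on the objective; coefficients are counted as
  parameters when $|\lambda_j| > 10^{-12}$.
- Ties: smaller $\beta$ in AICc ties; lexicographically smallest layer name
  in contribution ties; in cell thinning the lowest grove id wins a shared
  cell.
- Presence order is canonicalized (by cell index) inside scans, making them
  invariant to record ordering.
- Half-open cell indexing: a point on a cell's north or west edge belongs to
  that cell; the grid's outer boundary is inclusive.

## Problem sizes

The default study is a 100×100 grid (10,000 background cells), 10 layers
(65 features), and 200 groves; a fit takes well under a second and the full
three-stage protocol (~500 fits) a few minutes on one CPU. The test suite
uses 25×25 to 100×100 fixtures and runs in well under a minute.

## Limitations

- Only linear, quadratic, and product features (no hinge or threshold
  features).
- No spatial bias correction or target-group background.
- Percent contribution is path-dependent (training-order attribution), as is
  conventional; under strong collinearity it concentrates on an arbitrary
  representative of a correlated group.
- Projection assumes the target stack aligns with the training grid
  cell-for-cell.
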