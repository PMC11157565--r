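---
title: "Two-stage swarm feature selection: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage swarm feature selection: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmselect)
library(dplyr)
```

## The problem

Metabolomics regression tables are extreme examples of
high-dimensional small-sample (HDSS) data: tens of samples, hundreds to
tens of thousands of ion-intensity features, most of them irrelevant to
the continuous outcome (a pharmacodynamic indicator, a phenotype score),
and many of the informative ones near-duplicates of each other. Ordinary
subset selection is hopeless at that scale, and single-objective
wrappers return one subset with no sense of the size/accuracy
trade-off. `swarmselect` implements a two-stage hybrid:

1. **Filter + wrapper.** Features are ranked by minimum-redundancy
   maximum-relevance (mRMR) mutual information; sequential forward
   search (SFS) then walks ranked prefixes, scoring each by 10-fold
   cross-validated partial least squares (PLS) regression, and keeps the
   prefix with the lowest RMSE as the *candidate set*. This removes the
   bulk of irrelevant features cheaply.
2. **Multi-objective particle swarm.** A swarm searches subsets of the
   candidate set against two minimized objectives — subset size
   \(f_1 = |S|\) and cross-validated RMSE
   \(f_2 = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2}\) — maintaining a
   bounded archive of mutually non-dominated solutions. The result is a
   Pareto front: for every affordable subset size, the best subset
   found.

## Stage 1: ranking and the candidate set

**Mutual information.** \(I(X;Y)\) is estimated by the histogram
plug-in: both variables are discretized and
\(\hat I = \sum \hat p(x,y)\ln[\hat p(x,y)/(\hat p(x)\hat p(y))]\)
over nonzero joint cells, in nats. Integer-coded variables with at most
20 distinct values keep their levels; continuous variables get
equal-width bins over the observed range.

*Bin count.* The default is the cube-root rule
\(k = \max(2, \lceil n^{1/3}\rceil)\) per variable, not the more common
\(\lceil\sqrt n\rceil\). The reason is that the estimator fills a
\(k \times k\) *joint* table: with \(\sqrt n\) bins per axis the joint
table has about \(n\) cells — one observation each — and the plug-in
estimate is dominated by its small-sample bias (roughly
\((k_x-1)(k_y-1)/2n\) nats) and variance. At \(n = 60\) that regime
makes weakly informative features indistinguishable from lucky noise.
The cube-root rule keeps the joint cell count near \(n^{2/3}\). Both
rules (and any fixed integer) are available through `bins`.

**mRMR.** The ranking is the classical greedy incremental scheme: the
first feature maximizes \(I(f, Y)\); each later step adds the feature
maximizing \(I(f,Y) - \frac{1}{|S|}\sum_{s \in S} I(f,s)\). Ties break
toward the lower column index, making the ranking deterministic. A
one-shot relevance-only ordering (`scheme = "relevance"`) and absolute
Pearson/Spearman correlation baselines (`correlation_rank()`) are
provided for comparison.

**PLS scoring.** The wrapper's score is k-fold CV RMSE under PLS
regression with 2 latent components by default — a small-sample-safe
choice for wide, collinear blocks; components are reduced to the usable
rank when a subset is smaller. Standardization statistics are computed
on the training folds only, so no information leaks from the held-out
fold. Per-fold RMSEs are averaged (`aggregate = "fold_mean"`); pooling
all out-of-fold residuals first is available as `"pooled"`. The PLS
kernel is a univariate-response NIPALS implementation written for the
inner loop (the optimizer cross-validates tens of thousands of
subsets); the test suite verifies its predictions against
`mixOmics::pls` to 10 decimal places.

**SFS step.** Prefixes grow by `sfs_step` features at a time; the
default 0.01 adds 1% of the ranking per step (at least 1), matching the
granularity at which candidate sizes in published HDSS analyses of this
kind vary. The full ranking is always the last prefix evaluated, so the
candidate can never score worse than the full feature set on the same
folds. Ties go to the smaller prefix.

## Stage 2: the swarm

Each particle is a point in \([0,1]^D\), one dimension per candidate
feature; dimensions above `threshold` (default 0.6) are "on", and an
all-off particle is repaired to its single largest dimension, so
decoded subsets are never empty. This continuous encoding keeps the
classic velocity/position update applicable verbatim:

\[
v' = w\,v + c_1 r_1 (p_{best} - x) + c_2 r_2 (p_{leader} - x), \qquad
x' = x + v',
\]

with fresh \(r_1, r_2 \sim U(0,1)\) per dimension, velocities clamped to
\(\pm 0.5\) (half the position range), positions clipped to \([0,1]\)
with the clipped component's velocity zeroed.

**Schedules.** The inertia weight decreases nonlinearly,
\(w(t) = (w_{max}-w_{min})(t/T-1)^2 + w_{min}\) (defaults 0.9 to 0.4),
keeping exploration early and damping late. The acceleration factors
ramp linearly: \(c_1\) from 2.75 down to 1.25 (cognitive pull fades),
\(c_2\) from 0.5 up to 2.25 (social pull grows as the archive matures).
A literal variant of the \(c_2\) line with the opposite sign is exposed
as `literal_c2 = TRUE`; it runs out of the intended 0.5–2.25 range
(ending at \(2c_{2f} - c_{2i} = -1.25\)) and exists only for
comparison, since a negative social coefficient repels particles from
the archive. `optimizer = "mopso"` is the unscheduled baseline
(\(w = w_{max}\), \(c_1 = c_2 = 2\)).

**Archive and leaders.** The archive holds at most `archive_size`
(default 50) mutually non-dominated solutions; equal objective vectors
from different feature sets are distinct solutions and both stay, exact
duplicates collapse. When over capacity, the entry with the smallest
crowding distance is removed one at a time, recomputing after each
removal; among ties the later-inserted entry is dropped, keeping
truncation deterministic. Crowding distance follows the NSGA-II
convention — per-objective neighbour gaps normalized by the objective
range, extremes infinite — because subset size (integers) and RMSE are
on incomparable scales; an objective with zero range contributes
nothing. Leaders are drawn per particle by adaptive-grid roulette: the
objective space over the archive (bounds inflated 10%) is cut into
`mesh` × `mesh` cells (default 20) and a cell is chosen with weight
inversely proportional to its occupancy, then a uniform member of it —
biasing leadership toward sparse regions of the front.

**Personal bests** are replaced when the new position dominates, kept
when dominated, and replaced with probability one half when mutually
non-dominated.

**Determinism.** Fold assignment is fixed once per run from the seed,
subset evaluations are memoized, and every random draw flows from the
single seed, so \(f_2\) is a pure function of the subset and a run is
exactly reproducible — the manifest written by `write_results()` is
sufficient to regenerate the front byte for byte. Fixing the folds is
what makes Pareto dominance between subsets well defined mid-run; its
cost is discussed under Limitations.

## Defaults

| Parameter | Default | Meaning |
|---|---|---|
| `iterations` (T) | 300 | swarm iterations |
| `pop_size` | 100 | particles |
| `archive_size` | 50 | Pareto archive capacity |
| `mesh` | 20 | grid divisions per objective |
| `w_max`, `w_min` | 0.9, 0.4 | inertia endpoints |
| `c1f` → `c1i` | 2.75 → 1.25 | cognitive ramp |
| `c2f` → `c2i` | 0.5 → 2.25 | social ramp |
| `threshold` | 0.6 | decode cutoff |
| `folds` | 10 | CV folds |
| `ncomp` | 2 | PLS components |
| `sfs_step` | 0.01 | SFS prefix step (fraction) |

## The synthetic generator

`synth_hdss()` emulates the HDSS regime with known ground truth:
relevant features are i.i.d. standard normal; redundant features are
noisy copies of round-robin-assigned relevant parents (jitter sd 0.3 by
default, parent–copy correlation \(1/\sqrt{1+\sigma^2} \approx 0.96\));
noise features are independent standard normals; and
\(y = \sum_j \beta_j x_j + \varepsilon\) with \(\beta_j = 1\) and
\(\varepsilon \sim N(0, 0.5^2)\) by default — per-feature signals that
are individually modest but jointly strong, which is what makes the
selection problem non-trivial rather than decorative. The linear
Gaussian form is deliberate: it is the simplest structure under which
the mRMR ranking, PLS and the optimizer all have known ground truth.
`hdss_presets()` reproduces the shapes of the metabolomics tables the
method targets (54 × 10,283 and 42 × 798).

What the generator does *not* emulate: LC–MS missingness mechanisms,
retention-time drift, heteroscedastic intensity noise, correlated
feature blocks beyond parent–copy pairs, and nonlinear responses.
Passing the recovery tests therefore demonstrates the machinery works
under a clean linear regime, not that it will rank real metabolite ions
correctly.

## Numerical choices and degenerate inputs

- Constant features carry zero MI (zero entropy) and correlation 0
  (with a warning in the correlation baselines); an all-constant table
  is an error.
- A constant target makes ranking and \(R^2\) undefined — both error.
- PLS component counts are silently capped at `min(p, n-1)` and the
  deflation loop stops early if a weight vector collapses; a cap below
  the request produces a warning outside the optimizer's inner loop.
- A candidate set of one feature skips the swarm with a warning (the
  front is forced).
- Argmax ties anywhere (ranking, SFS, decode repair) break toward the
  lower index/smaller size, so every stage is deterministic.
- Problem sizes used by the test suite and the acceptance script — 60
  samples with 500 features for recovery runs, swarm runs of 100
  iterations with 40 particles, repeated over 10 seeds — were chosen to
  exercise the HDSS regime at a scale where the swarm's behaviour is
  measurable while a full protocol completes in minutes on a laptop
  core.

## Known limitations

**CV winner's curse.** Because fold assignment is fixed per run (for
reproducibility and well-defined dominance), the optimizer compares
thousands of subsets on the *same* folds and the minimum-RMSE front
member is selected partly for fitting those folds. At 60 samples this
is visible: the min-CV-RMSE member often carries a few noise features
that genuinely lower CV RMSE on the fixed folds, and occasionally swaps
a weak relevant feature for its redundant copy. Recovery of the planted
subset is therefore good but not perfect (the acceptance protocol
measures it directly). Users who need an unbiased error estimate for a
selected subset should re-evaluate it on folds drawn with a different
seed, or on held-out samples.

**MI estimator noise at small n.** With tens of samples, histogram MI
ranks weak linear signals far less sharply than correlation does; the
mRMR stage is the method's noisiest link in the linear-Gaussian regime.
The Pearson/Spearman baselines frequently rank relevant features
higher. This mirrors the general filter trade-off: MI buys
nonlinearity-awareness at a variance cost that small samples make
expensive.

**Scope.** One continuous target per run (multiple targets are run
separately); no raw spectral processing; no statistical comparison
machinery between optimizers; no hypervolume or ε-dominance archiving.
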