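---
title: "Methods: grey-wolf wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey-wolf wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbgwo)
```

## The model

Feature selection for a two-class problem with *n* samples and *D*
features is posed as binary optimization over masks $X \in \{0,1\}^D$. A
mask's quality is the scalarized biobjective fitness, minimized:

$$\mathrm{fit}(X) \;=\; (1-\alpha)\,\frac{S}{D} \;-\; \alpha\,\mathrm{AvgAcc}(X),$$

where $S$ is the number of selected features, $\mathrm{AvgAcc}$ the mean
per-fold accuracy of a stratified 10-fold cross-validated KNN classifier
(Euclidean distance, $k = 5$, majority vote) restricted to the selected
columns, and $\alpha = 0.8$ the accuracy weight. Any reachable fitness lies
in $[-\alpha,\, 1-\alpha]$. The two common typographic variants of this
objective — subtracting $\alpha\,\mathrm{AvgAcc}$ versus adding
$\alpha\,(1-\mathrm{AvgAcc})$ — differ by the constant $\alpha$ and induce
identical rankings, so optimizer behaviour does not depend on the choice;
the subtractive form is implemented and the equivalence is asserted in the
test suite.

The search is a binary grey wolf optimizer. A population of $N$ wolves is
initialized with independent Bernoulli(0.5) bits (all-zero masks are
re-drawn, since the fitness is undefined on an empty subset). Each
iteration every wolf moves toward the three best solutions found so far
($\alpha, \beta, \delta$ leaders): for each leader an independent
coefficient pair $A = 2a r_1 - a$, $C = 2 r_2$ with $r_1, r_2 \sim
U(0,1)^D$ is drawn, the randomized absolute distance $D_L = |C \cdot X_L -
X|$ is formed, and the continuous update is the mean of the three guide
points $X_L - A \cdot D_L$. Continuous coordinates return to bits through
the steep sigmoid $S(x) = 1/(1 + e^{-10(x - 0.5)})$ thresholded at the
fixed value $0.5$ for this whole-population phase.

The master–slave scheme distinguishes MSBGWO from the BGWO2 baseline. After
the population update, wolves are sorted in ascending fitness (stable sort;
ties keep their prior order), the top half become masters and the bottom
half slaves, paired by $S = M + N/2$ in sorted position. Each slave moves
toward its master,

$$X_n = X_M - A_4 \cdot \big(\omega\, |C_4 X_M - X_S|\big),$$

and is binarized against *per-dimension uniform random* thresholds, which
keeps this phase stochastic and exploratory. The replacement is
unconditional — no accept-if-better guard — which is what diversifies the
weaker half of the pack. The learning coefficient $\omega \in [0,1]$
(default 0.1) sets how far slaves stray from their masters.

The encircling coefficient $a$ decays from 2 to 0 over the $T$ iterations:
linearly, $a = 2 - 2t/T$, for BGWO2, and quadratically,
$a = 2(1 - t^2/T^2)$, for MSBGWO. The quadratic schedule dominates the
linear one pointwise, so MSBGWO spends more of its budget in the
exploratory regime.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `pop_size` (N) | 10 | wolves per generation; must be even for pairing |
| `iterations` (T) | 100 | search budget; fitness evaluations ≈ N·T (plus N/2·T slave re-evaluations for MSBGWO) |
| `omega` | 0.1 | master–slave learning coefficient; 0 copies the master's continuous position, 1 allows full-distance steps |
| `alpha` | 0.8 | fitness weight on accuracy; each feature costs (1−α)/D, so a feature is kept only if it buys ≥ 0.25/D accuracy at the default |
| `k` | 5 | KNN neighbours (odd avoids vote ties) |
| `folds` | 10 | stratified CV folds; every class must have ≥ `folds` members |
| `seed` | — | one seed per fit; folds, initialization and all coefficient draws derive from it in a fixed order |

## Numerical and design choices

* **Strict threshold inequality.** A bit is set iff $S(x) > \theta$;
  the measure-zero tie $S(x) = \theta$ maps to 0. With fixed $\theta = 0.5$
  this makes a coordinate of exactly 0.5 a 0.
* **Sigmoid constants.** The slope 10 and midpoint 0.5 are fixed, not
  exposed: they define the binary encoding rather than tune it. In double
  precision the sigmoid saturates to exactly 0 or 1 for $|10(x-0.5)|
  \gtrsim 37$; this is harmless because only comparisons against thresholds
  in $(0,1)$ are ever made.
* **Absolute value in distances.** The leader and master–slave distance
  terms use $|C X_L - X|$; the modulus matters because $A$ may be negative,
  and dropping it would change the geometry of steps past a leader.
* **Independent coefficient draws.** All four $A/C$ pairs are fresh
  per-wolf, per-iteration, per-dimension draws.
* **Leader bookkeeping.** Leaders are the three best solutions *ever seen*
  (best-so-far), kept fixed during a population sweep and merged afterwards;
  slave re-evaluations merge immediately so the next iteration's leaders
  reflect current fitnesses. Retaining leaders until beaten makes the
  recorded best-so-far convergence series non-increasing by construction —
  an invariant the tests assert on every trace.
* **Phase order.** Whole-population leader update first, then the
  master–slave step on the updated, re-evaluated population. Other
  orderings are plausible; this one lets the slaves learn from masters
  ranked on current positions.
* **Empty masks.** Binarization can zero a wolf mid-run. Rather than
  crash or re-draw (which would perturb the stream), the evaluator returns
  a sentinel fitness of 1 — strictly above the reachable maximum
  $1-\alpha$ — so such wolves simply lose every comparison. The sentinel is
  finite so sorting stays well-defined.
* **Deterministic KNN ties.** Equidistant neighbours resolve to the lowest
  training index (R's stable `order`), tied votes to class 1. The KNN is
  implemented directly on a per-mask distance matrix because these tie
  rules — needed for exact replay — are not controllable in off-the-shelf
  KNN routines; tests cross-check predictions against `class::knn` on
  tie-free data.
* **Pooled confusion counts.** Precision/recall/F are computed from counts
  pooled over the CV folds (each sample scored exactly once) rather than
  macro-averaged per fold; pooling matches the raw-count definitions of the
  metrics and is stable when folds hold only a few positives.
* **Global min–max normalization.** Features are scaled to $[0,1]$ on the
  full dataset *before* cross-validation. Per-fold normalization is
  statistically cleaner (no information leak from test folds into the
  scaling); the global variant is the convention in this wrapper-selection
  literature and is kept deliberately — the mild optimism affects all
  compared optimizers equally. Constant columns map to zeros with a
  warning.
* **Memoization.** Fitness reports are cached by mask bits within a fit;
  the *reported* metrics of a finished fit are recomputed with a fresh fold
  assignment, decoupling them from the cache.
* **Wilcoxon convention.** The rank-sum test uses midranks, the
  tie-corrected normal approximation and no continuity correction, which
  exposes the $z$ statistic alongside $p$; for two fully separated samples
  of 10 distinct values this gives $z = 50/\sqrt{175} \approx 3.78$. If
  both samples are constant and equal the variance degenerates and the
  test returns $p = 1$, $h = 0$. Per-run accuracies are the compared
  quantity, runs being independent (hence rank-sum, not signed-rank).
* **Per-run seeds.** In `run_experiment`, each run's seed is a pure
  function of (base seed, variant name, run index), so adding a variant or
  extending the run count never perturbs existing runs.

## What the synthetic generator emulates — and what it does not

`generate_synthetic` produces the *shape* of gene-expression classification
problems: $D \gg n$, two classes, and a handful of informative features
among pure noise. Informative columns are Gaussian with class-conditional
means $0$ and `effect` (unit variance), so `effect` is the class separation
in within-class SDs; noise columns are standard normal; columns are then
min–max normalized. Defaults (62 samples, 2000 features, 10 informative,
effect 2, balanced classes) mirror a colon-cancer-scale problem.

This is deliberately the simplest structure under which wrapper selection
with KNN is exercisable, and it omits much of what real microarray data
contains: heavy-tailed and skewed marginals, correlated co-expressed gene
blocks, batch effects, and informative features of heterogeneous effect
size. Passing the planted-recovery tests therefore demonstrates that the
optimizer finds class-informative coordinates when they exist — not that it
reproduces any particular benchmark accuracy on real tissue data.

## Problem sizes used in the tests

The test suite and the acceptance script run the full protocol at reduced
dimension so the whole suite stays interactive: the selection-quality
checks use 62 samples × 50 features with 5 planted features at effect 2
(population 10, 50 iterations, 5 replicate seeds), and the protocol-shape
check runs 10 runs × 2 optimizers at N = 10, T = 100 on the same dataset.
These sizes were chosen as the smallest at which the planted-feature
recovery question is non-trivial — the chance of a random size-5 mask
hitting ≥ 3 of 5 planted columns in D = 50 is below 1% — while a full
experiment completes in well under a minute.

## Known limitations

* Binary labels only; multi-class metrics and selectors are out of scope.
* The KNN distance-matrix evaluation is $O(n^2 S)$ per mask, fine for
  $n \lesssim$ a few hundred samples (the regime these datasets occupy) but
  not engineered for large-$n$ problems.
* Only the sigmoid transfer family is provided; V-shaped and other
  transfer functions would change exploration behaviour.
* The comparison driver implements the two grey-wolf variants; other
  binary metaheuristics (genetic algorithms, particle swarms, differential
  evolution, sine-cosine) are not reimplemented, though the experiment
  machinery would accommodate any optimizer exposing the same
  mask-in/fitness-out contract.
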