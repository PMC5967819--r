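---
title: "Incremental fuzzy c-medoids clustering of time series under DTW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental fuzzy c-medoids clustering of time series under DTW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwmedoids)
```

## The problem

Time series that share a shape rarely share a clock: heartbeats, gait
cycles or power-demand curves from the same class are stretched and
compressed relative to one another. A pointwise (Euclidean) comparison
penalises these time shifts heavily, so clustering algorithms built on it
can split a class by phase rather than by shape. Dynamic time warping
(DTW) removes this nuisance by aligning two series along an optimal
monotone warping path before accumulating their differences.

A second, independent obstacle is scale: when a dataset does not fit in
memory, or arrives as a stream, the clustering has to operate on chunks.
`dtwmedoids` combines the two ideas. Its core is a *weighted fuzzy
c-medoids* algorithm under DTW; around it sit two incremental drivers —
*single-pass*, which carries each chunk's weighted medoids into the next
chunk, and *online*, which clusters chunks independently and then
clusters the pooled medoids. Medoids (true data objects) rather than
centroids (averages) are essential here: an "average" of warped series
under DTW is not well defined, and medoids are more robust to outlying
series.

## The model

Given N series and C clusters, the algorithm minimises

$$J \;=\; \sum_{c=1}^{C} \sum_{i=1}^{N} w_i\, u_{ci}^{\,m}\, \mathrm{dtw}(x_i, v_c),$$

subject to $\sum_c u_{ci} = 1$, where $v_c$ are medoids chosen among the
data objects, $u_{ci} \in [0,1]$ are fuzzy memberships, $w_i > 0$ are
object weights (all 1 in batch use; carried medoids become heavier in the
incremental drivers), and $m > 1$ is the fuzzifier. The fit alternates
two updates until the medoid set repeats:

* **Membership update.**
  $u_{ci} = \big[\sum_{l}\,(\mathrm{dtw}(x_i,v_c)/\mathrm{dtw}(x_i,v_l))^{1/(m-1)}\big]^{-1}$.
  Weights do not appear here — they act only in the objective and the
  medoid update. If an object sits at distance zero from one or more
  medoids the formula divides by zero; we assign membership
  $1/\#\{\text{zero-distance medoids}\}$ to each of those clusters and 0
  elsewhere, the standard fuzzy c-means convention, which preserves unit
  column sums.
* **Medoid update.** Ideally $v_c = \arg\min_x \sum_i w_i u_{ci}^m
  \mathrm{dtw}(x_i, x)$ over all N objects; to keep the step linear in N
  the search is restricted to the q objects with largest membership in
  cluster c (default $q = \min(5, N)$, configurable). We additionally
  keep the cluster's current medoid in the candidate set. The design was
  genuinely open here, and the incumbent matters: with a strict top-q set
  the current medoid can drop out of contention and the "best" candidate
  can be worse than what the cluster already had, breaking the monotone
  descent of $J$ that the convergence argument rests on. With the
  incumbent included the per-cluster minimisation can never increase $J$,
  and the objective trace is provably non-increasing (and bounded below
  by 0), which the test suite asserts on every fit it runs.

Distinct medoids are enforced: clusters are processed in index order, and
a cluster whose best candidate is already taken falls back to its
next-best candidate, extending the candidate set to all objects if
necessary. Every argmin/argmax in the package breaks ties toward the
lowest object index, so a fit is a pure function of its inputs.

**Initialisation** is deterministic: the first medoid is the object with
the smallest total distance to all others (the most central object); each
further medoid is the object maximising the summed distance to the
medoids already chosen. Deterministic initialisation is what makes
repeated runs bit-identical — there is no random restart anywhere.

**Termination**: the loop stops when an iteration's medoid set equals the
previous one. Because medoid configurations are finite and $J$ descends,
this happens after finitely many steps; `max_iter` (default 100) is a
safety cap only, and hitting it flags the model as unconverged rather
than raising an error.

## The DTW kernel

The kernel follows the classic dynamic programme exactly: first row and
column are cumulative sums of the local cost, interior cells add the
local cost to the minimum of the left, upper and diagonal neighbours, and
the distance is the final cell — *un-normalised* (no path-length
division, no square root), so the distance is in the units of the local
cost. Choices worth knowing:

* **Local cost** $\delta(a_i, b_j) = |a_i - b_j|$ by default, keeping the
  distance in signal units; `step_cost = "squared"` is available. The tag
  of every distance matrix records the choice.
* **Backtracking ties** prefer the diagonal predecessor, then
  $(i, j-1)$, then $(i-1, j)$ — deterministic, and diagonal preference
  yields the shortest optimal paths.
* **No warping window**: the alignment is unconstrained, which also means
  ragged (unequal-length) pairs need no padding. Euclidean distance, by
  contrast, refuses ragged pairs with an instructive error.
* Indices are 1-based throughout; paths run from $(1,1)$ to $(S,T)$ with
  steps in $\{(1,0), (0,1), (1,1)\}$.

The recurrence is written in C++ (Rcpp) because the kernel is quadratic
per pair and sits inside an $O(N^2)$ pairwise loop; everything above it
is plain R. Correctness is pinned by an exhaustive oracle: for series of
length up to 5 the tests enumerate *all* monotone warping paths and
verify exact agreement.

## The incremental drivers

Both drivers split the data into contiguous chunks (file order is the
assumed arrival order; shuffling is available but requires an explicit
seed). After clustering a pool, each medoid is carried with weight

$$w_c = \sum_i u_{ci}\, w_i,$$

its membership-weighted share of the pool's mass. Since membership
columns sum to 1, total weight is conserved — after the last single-pass
chunk the carried weights sum to exactly N. The same formula serves both
drivers; only the pool differs:

* **Single-pass**: chunk p's pool is its own objects (weight 1) plus the
  C medoids carried from chunk p−1 (their accumulated weights). Carried
  medoids are ordinary, heavier pool members and may be reselected; a
  reselected medoid's new weight is recomputed from the merged pool —
  the old weight already enters through $w_i$, so nothing is counted
  twice. With one chunk the driver *is* the batch algorithm, and the
  tests require bit-identical results.
* **Online**: every chunk is clustered independently with unit weights
  (this stage is order-independent and could run in parallel); the M·C
  weighted medoids are then clustered once more. The final pool stage
  uses the same deterministic initialisation on the pool's distance
  matrix.

Both drivers end with a streaming second pass that recomputes the
(unweighted) memberships of all N series against the final C medoids, so
the full dataset never has to be resident at once. Per-chunk distance
matrices are computed fresh — at chunk scale (|p| + C objects) a
cross-chunk distance cache would buy nothing.

## External validity statistics

Four statistics compare a clustering against known class labels, all
computed from the class-by-cluster contingency table of the *hardened*
partition (each object assigned to its maximum-membership cluster, ties
to the lowest index — hardening is the universal bridge from fuzzy
memberships to count statistics):

* **F-Measure**: per class, the best harmonic mean of precision and
  recall over clusters, weighted by class size. 1 iff the partition
  equals the classes up to relabelling.
* **Entropy**: size-weighted average of per-cluster class-distribution
  entropies; 0 iff every cluster is pure. The log base is not fixed by
  convention; the default is the natural log with base 10 selectable,
  and the choice only rescales values.
* **Hypergeometric p-value**: for each cluster and class, the upper-tail
  probability of observing that many class members in a draw of the
  cluster's size — the same enrichment test used for GO-term analysis,
  with the class label playing the annotation's role. Computed via
  `stats::phyper` in log space; the tests verify it against exhaustive
  enumeration of all draws for N ≤ 12. A cluster's p-value is its
  *minimum over classes* (its best enrichment).
* **Clustering Score (CS)**: significant clusters (p below the 0.05
  cutoff) contribute their minimum p-value, insignificant ones the
  cutoff, averaged over clusters. Lower is better; `-log10(CS)` is the
  conventional higher-is-better report.

## The synthetic generator

`simulate_warped_series()` is the package's ground-truth instrument. It
plants clusters by drawing copies of fixed unit-amplitude prototype
shapes (sine, square, ramp, Gaussian bump, chirp, damped oscillation —
mutually dissimilar by construction) and corrupting each copy with
exactly the nuisance DTW is meant to absorb:

* **Random monotone time warp**: a piecewise-linear time map with 4
  interior knots, each displaced by up to `warp_strength` × 0.45 of a
  knot gap. The bound keeps the map strictly monotone without any
  rejection step; `warp_strength = 0` is the identity.
* **Additive i.i.d. Gaussian noise** on values (`noise_sd`, in units of
  the unit prototype amplitude). Object-level outliers — the scenario
  medoids are robust to — are a separate knob (`outlier_fraction`)
  implemented as value-shuffled series.
* **Optional length jitter** to produce ragged datasets.

Defaults are 3 clusters of 20 series, length 60, `warp_strength = 0.3`,
`noise_sd = 0.05`, equal lengths: a separable configuration in which the
planted partition is recoverable (the fitness-for-purpose tests require
mean F-Measure ≥ 0.9 over a 10-seed grid) while the warps are strong
enough that the Euclidean variant scores strictly lower on average than
DTW. Length 60 keeps the quadratic kernel cheap at these N; the tests and
the acceptance script run at N = 60 per dataset, a size chosen so the
whole suite completes in seconds while still exercising multi-chunk
runs. One RNG stream is seeded per `generate` call and consumed in a
fixed order, so generation is referentially transparent in its
configuration.

What the generator does *not* emulate: trend and seasonality mixtures,
heteroscedastic or autocorrelated noise, class-imbalanced datasets, and
the subtle between-class similarity of real archives (e.g. ECG beat
families). Passing its tests therefore demonstrates that the machinery
recovers warp-invariant shape structure, not that any particular real
dataset will cluster at a given accuracy.

## Numerical choices and degenerate inputs

* Zero distances (duplicate series, an object equal to a medoid) follow
  the membership convention above; selection handles candidate-set
  exhaustion by extension; all ties break low.
* Membership columns are asserted to sum to 1 within 1e−9 across the
  suite; the round trip through the UCR writer prints 17 significant
  digits and reproduces doubles bit-exactly.
* `NaN`/missing observations are rejected at parse time; series of
  length 1 are legal; a chunk smaller than C raises an error naming the
  chunk.
* The fuzzifier default is m = 2.3 everywhere (CLI included).
  As m → 1 memberships approach crisp assignment and the membership
  ratios become numerically extreme; m must be > 1.

## Limitations

* DTW is quadratic per pair and the pairwise stage quadratic in chunk
  size; the package targets accuracy, not speed — no FastDTW-style
  approximation, no warping window, no parallel execution.
* Univariate series only; no multivariate or derivative DTW.
* C is user-chosen; there is no automatic model selection.
* The q-candidate restriction trades exactness of the medoid step for
  speed; with small q the fit can settle in a slightly worse local
  optimum than the exhaustive update (set `candidates = N` to recover
  it).
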