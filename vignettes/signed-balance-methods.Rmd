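---
title: "Assessing structural balance in signed networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing structural balance in signed networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(signedbalance)
```

## The question

Social and biological interaction networks often carry edge signs:
friend/foe, trust/distrust, activation/inhibition. Structural balance
theory predicts that such networks avoid *frustrated* configurations -
cycles whose product of edge signs is negative. Under *strong balance*
(SB), every cycle has an even number of negative edges, which by Harary's
theorem is equivalent to a split of the nodes into two camps with positive
edges inside camps and negative edges across.

Whether a real network "shows balance" is always a statement relative to a
null model: the observed frequency of a signed pattern only means something
compared to its frequency in a randomized ensemble that preserves the
confounders you want to control. This package implements the full pipeline
- exact signed graphlet census, four randomization schemes, enrichment
statistics - together with two generative reference networks that are
balanced *by construction* and therefore serve as ground truth for judging
the null models themselves.

## Signed graphlets

We census connected three- and four-node patterns from four topology
families: `triangle`, `square` (chordless 4-cycle), `squareZ` (4-cycle plus
one diagonal) and `squareX` (K4). Assigning signs to edges and identifying
assignments related by an automorphism of the underlying topology yields
4 + 6 + 14 + 11 = 35 patterns; `pattern_catalog()` lists them with stable
ids. A pattern is balanced iff all of its cycles are, which we evaluate by
exhaustive two-colouring of the (at most 4-node) pattern; a property test
cross-checks this against direct cycle-parity enumeration for all 35
patterns.

Two counting modes exist. *Graphlet* (induced) mode assigns every node
subset to its induced topology, so a 4-cycle inside a K4 is not a `square`
occurrence. *Motif* (non-induced) mode counts all occurrences of a family's
edge set regardless of extra edges. Both modes are computed in one pass:
induced occurrences are enumerated exactly once each (edge-iterator with
sorted-adjacency intersection for triangles; per-edge common-neighbourhood
pairing for K4s and diamonds; wedge pairing anchored at the minimum node
for chordless squares), and motif counts follow by expanding each induced
K4 into its 6 diamond and 3 square edge-subsets and each diamond into its
single square. A pure-R `brute_force_census()` over all `choose(n, 3)` and
`choose(n, 4)` subsets provides an independent oracle; the test suite
checks exact agreement on ensembles of random signed graphs.

## Enrichment statistics

For each pattern we report the observed count, the null-ensemble mean and
sample standard deviation, `z = (n_obs - mean) / sd`, the fold change
`n_obs / mean`, and a one-sided empirical P value `(r + 1) / (n + 1)` with
ties counted as extreme. A result is flagged significant when `|z| > 2`
and `P < 0.01`. Conventions worth stating explicitly:

* the SD uses the usual `n - 1` denominator;
* `z` is undefined (reported `NA`) when the null SD is zero, and the fold
  change when the null mean is zero;
* the P-value tail follows the observed deviation (upper when
  `n_obs >= mean`, lower otherwise; at exact equality the upper tail is an
  arbitrary but deterministic choice), so `P` and `z` always agree in
  direction;
* no multiple-testing correction is applied; the empirical P value is
  reported alongside `z` precisely so that users need not rely on
  normality of the null counts.

## The four null models

* **rewire** - double edge swaps (`A-B`, `C-D` to `A-D, C-B` or
  `A-C, B-D`), aborting when endpoints coincide or a proposed edge exists.
  Preserves the degree sequence and total sign counts; destroys signed
  degrees and topology. The budget is 40 swap *attempts* per edge,
  aborted attempts included - abort rates are topology-dependent, so
  counting attempts (not successes) is the reproducible convention.
* **signed rewire** - the same move restricted to same-sign edge pairs,
  aborting also when a proposed edge exists with the other sign. Preserves
  each node's `(k+, k-)` exactly; destroys topology.
* **sign shuffle** - permutes the multiset of signs over the fixed edge
  set. Preserves topology and total sign counts; destroys signed degrees.
* **STP** - the maximum-entropy distribution over sign assignments on the
  *fixed* topology that matches every node's *expected* negative degree.
  Maximizing the Shannon entropy subject to these constraints gives
  independent edges with
  `P(edge ij negative) = 1 / (1 + alpha_i alpha_j)`, one multiplier per
  node, fitted by the fixed-point iteration
  `alpha_i' = (1 / k_i^-) * sum_j 1 / (alpha_j + 1 / alpha_i)` from
  `alpha = 1` until the maximum relative change drops below `1e-3`
  (at most `1e4` iterations; non-convergence is reported, never hidden).
  This is a canonical ensemble: constraints hold on average, not in every
  sample.

### Numerical treatment of the STP fixed point

Nodes with `k- = 0` (or `k- = degree`) are the divergent limits
`alpha -> Inf` (`-> 0`) of the iteration. We peel them off before
iterating: their incident edges are clamped to `p- = 0` (`p- = 1`) and
removed from the neighbours' residual constraints, cascading until no
degenerate node remains. The clamped values always coincide with the
observed edge signs, so the residual problem remains feasible. During the
iteration `alpha` is clipped to `[1e-12, 1e12]`; updates are synchronous
(all from the previous iterate), and a K-regular test case with constant
`k-` verifies the fit against an independent scalar bisection solve of
`c (alpha^2 + 1) = k`. On graphs with tens of thousands of edges the fit
converges in a few hundred iterations (seconds in vectorized R).

### Ensemble mechanics

All ensemble draws flow from one master seed; each replica uses a stream
derived from the seed and the replica index, so runs are reproducible and
insensitive to how replicas are scheduled. For the topology-preserving
nulls (sign shuffle, STP) the unsigned occurrences are enumerated once and
each replica is scored by re-reading edge signs along the cached edge-index
tuples; a memory cap (default 5e7 tuples) falls back to per-replica
recounting with identical results. The rewiring nulls change the topology
and are recounted per replica.

## Reference generators

The generators are not meant to imitate real social networks; they are
standardized benchmarks whose balance properties are known exactly, so a
null model that fails to detect balance on them is disqualified.

**Two-group configuration model (`generate_sb_reference()`).** Positive
target degrees follow a power law with exponent 2, negative ones with
exponent 3. Both sequences are sorted ascending and the positive sequence
is partially shuffled (each position exchanged with a random position with
probability 0.2) to leave a moderate positive-negative degree correlation.
After a random assignment to nodes, the first half of the nodes form camp
one, the second half camp two; positive stubs are matched within camps,
negative stubs across camps, and conflicting pairings (self-loops,
duplicates) are discarded - an erased configuration model. Every negative
edge crosses the camps, so the camp split is an exact Harary bipartition:
the network contains *zero* unbalanced cycles of any length, which the
tests assert at the pattern level.

Choices the construction leaves open, fixed here once:

* *Sampling of power-law degrees.* Degrees are drawn by inverse-CDF
  sampling of the continuous truncated power law and floored to integers.
  We prefer this over a discrete zeta distribution because it reproduces
  the documented reference statistics of the construction at
  N = 120,000 - realized edge count (~5.4e5), positive ratio (~0.82) and
  mean negative degree (~1.64 = the floored-Pareto mean) - where the zeta
  variant lands visibly low (~3.8e5 edges, ratio ~0.79).
* *Cutoffs.* `k_min = 1`; `k_max` is the natural cutoff
  `N^(1/(gamma-1))`, i.e. N for exponent 2 and sqrt(N) for exponent 3.
  Both are configurable.
* *Stub parity.* A camp's positive stub list of odd length loses one
  random stub; the two cross-camp negative stub lists are truncated to the
  shorter one. With heavy-tailed sequences realized degrees fall slightly
  below targets anyway (erasure), so these repairs are immaterial.
* The exchanged-sequence Pearson correlation is dominated by the largest
  exponent-2 values and therefore scatters widely across seeds
  (roughly 0.5 +/- 0.13 at N = 120,000); single-run values between 0.17
  and 0.7 are unremarkable.

**Edge-copying growth (`generate_ec_reference()`).** Starting from a +++
triangle, each new node attaches to a uniform existing node (positive with
probability q = 0.9), and copies each edge of that node independently with
probability P = 0.45, keeping the copied sign if the attachment is
positive and reversing it otherwise. A short induction shows the rule
preserves a two-camp structure exactly, so the grown network is strongly
balanced at every size - the tests assert zero unbalanced patterns at
N = 20,000. The "copy each neighbour independently" reading of the rule is
a choice; note that with it the edge count grows as
`E(t) = 10 t - c t^0.9` (from `dE/dt = 1 + 2 P E / t`), so at
N = 120,000 the network is still far from its asymptotic mean degree 20 -
the slow transient, not a different copying rule, explains why the
realized mean degree is about 13.8 and the positive ratio about 0.70.

`reverse_signs()` (flip every sign; turns the SB reference into a
maximally frustrated network) and `degrade_balance()` (degree-preserving
swaps with a tunable attempt fraction) provide controlled departures from
balance for power studies.

## What the tests do and do not show

The suite validates (i) exactness of the census against brute-force
enumeration, (ii) the conservation law of every null model, asserted
exactly, (iii) constraint satisfaction of the STP fit (relative residual
below 1e-2 per node on a 5,000-node edge-copying network), (iv) planted
balance recovery: on a 12,000-node two-group reference with 200 STP
replicas, the unbalanced triangle and square patterns the null can produce
are significantly depleted (z <= -2, P < 0.01), while rewire and sign
shuffle - which destroy signed degrees - misreport *balanced* patterns as
depleted on the same input, (v) self-consistency: data drawn from the STP
model and analysed against STP shows no enrichment (|mean z| < 0.5 over
20 repeats), and (vi) reproduction of the full-scale (N = 120,000)
generator statistics across 5 seeds. Problem sizes in the tests
(12,000-20,000 nodes, 100-200 replicas) are the package's chosen
desk-scale defaults; the same code runs the 120,000-node references in
seconds per network.

Passing these tests shows the machinery is correct on networks whose
balance status is known by construction. It does not show that any *real*
network is balanced; real data also bring preprocessing questions
(directionality, duplicate and contradictory reports, rating thresholds)
that the reader should check against the preprocessing report attached to
every `signed_graph`.

## Known limitations

* The STP ensemble is canonical: signed degrees are matched on average,
  not exactly per sample, so it is somewhat less powerful than an (as yet
  impractical) microcanonical exact-signed-degree shuffle.
* Five-node and larger patterns, directed or weighted signs, and per-node
  (orbit-resolved) graphlet degrees are out of scope.
* Rating-valued inputs are binarized by the arithmetic sign of the rating;
  any other threshold is the user's responsibility before import.
* Pattern ids 1-35 are stable within this package (family order, balanced
  first, lexicographic signature) but are not a community standard;
  compare across tools by signature, not id.
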