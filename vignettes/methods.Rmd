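---
title: "Fused-lasso maximum-margin clustering of copy-number profiles: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused-lasso maximum-margin clustering of copy-number profiles: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnamargin)
```

## The problem

Tumor cohorts profiled by array-CGH yield, per sample, a vector of probe-level
log2 copy-number ratios along the genome.  Recurrent copy-number alterations
(CNAs) — gains and losses shared by a subset of tumors — are the signal of
interest, but the standard pipeline (segment each sample, call each segment,
aggregate calls across samples) propagates every upstream choice into the
final answer.  `cnamargin` instead works directly on the probe-level matrix:
it looks for a *subset of samples* and a *genomic pattern* at the same time,
by learning a linear classifier of whole profiles whose weight vector is
forced to look like a CNA.

## The separator model

For a cohort restricted to one chromosome, a partition of the samples is a
linear separator $(\beta, b)$: sample $x_i \in \mathbb{R}^p$ (one coordinate
per probe) is assigned the label $\mathrm{sign}(\beta^\top x_i + b)$, ties
going to $+1$.  Given tentative labels $y_i \in \{-1, +1\}$, the separator is
fitted by constrained least squares:

$$
\min_{\beta, b} \sum_i (y_i - \beta^\top x_i - b)^2
\quad \text{s.t.} \quad
\sum_j |\beta_j| \le s_1,
\qquad
\sum_{(j-1,j)} w_{j,j-1}\, |\beta_j - \beta_{j-1}| \le s_2 ,
$$

the fused-lasso constraint pair: the first budget makes $\beta$ sparse (few
probes matter), the second makes it piecewise constant along the genome
(adjacent probes tend to share a weight, as they share a copy number).  The
fusion sum runs only over pairs of probes adjacent *on the same chromosomal
arm* — copy number has no reason to be continuous across the centromere, so
arm boundaries are never fused.  Squared-error loss keeps the problem a
quadratic program; regressing on $\pm 1$ labels in the support-vector
regression style is what makes the alternating clustering loop below behave
well.

### Distance-normalized fusion weights

High-density arrays have wildly uneven inter-probe spacing, and fusing two
probes separated by megabases is not justified.  Each fused pair is therefore
weighted by

$$ w_{j,j-1} = \min\!\left(1, \; d_{\mathrm{med}} / d_{j,j-1}\right), $$

where $d_{j,j-1}$ is the base-pair gap and $d_{\mathrm{med}}$ the median gap
over all fused pairs: full coupling up to the typical spacing, inverse decay
beyond it.  The form is monotone decreasing, bounded in $(0, 1]$ and
scale-free; it is exposed as configuration (`form`, `scale` in
`compute_fusion_weights()`), with `"uniform"` recovering the unweighted
fused lasso.

### Solving the QP

Both absolute-value budgets are linearized exactly with auxiliary variables
($a_j \ge |\beta_j|$, $t_k \ge w_k |\beta_j - \beta_{j-1}|$), giving a convex
QP with $2p + 1 + m$ variables, solved with the dual active-set method of
`quadprog` in compact constraint storage.  The least-squares Hessian has rank
at most $n + 1$, so a relative ridge of $10^{-10} \cdot \max \mathrm{diag}(H)$
makes it positive definite as the solver requires; the perturbation is far
below all tolerances used anywhere in the package.  Returned solutions are
checked against both budgets and all orthogonality constraints at $10^{-6}$;
the test suite additionally verifies objective agreement with an independent
SQP solver (`nloptr::slsqp` on a differently parameterized but equivalent
formulation) to $10^{-5}$ on random instances.  Two degenerate regimes are
handled exactly: $s_1 = 0$ forces $\beta = 0$, $b = \bar y$ analytically, and
very large budgets reproduce unconstrained least squares (verified against
the pseudoinverse solution at $10^{-4}$).

## Maximum-margin clustering

Labels are not given; `mmc_partition()` finds them by alternating
optimization (the maximum-margin clustering scheme):

1. initialize labels with 2-means on the raw profiles, best of 10 restarts
   under the given seed;
2. fit the separator to the current labels by the QP above;
3. relabel each sample by the sign of its decision value;
4. repeat until the label vector repeats.

A repeat of the immediately preceding state is a fixed point and is reported
as `converged`; a longer cycle (alternating schemes can oscillate) terminates
the loop and returns the cycle state with the lowest QP objective, flagged
`cycled` rather than `converged`, since re-running the label update on a
cycle state does move.  A labeling that collapses to one group is reported
with `trivial = TRUE` — the remedy, as with any fused-lasso budget choice, is
a larger $s_1$/$s_2$.  There is no class-balance constraint: triviality is
detected and reported, not forbidden.

### Choosing the budgets

$s_1$ and $s_2$ are platform- and cohort-dependent.  Too small and the
clustering is trivial; too large and the constraints stop binding, leaving
plain 2-means (the package tests verify both limits).  The recommended
recipe is a grid search on a sample subset, keeping the smallest budgets
that give a non-trivial clustering on every chromosome.  The defaults
($s_1 = 2$, $s_2 = 1$) sit in the middle of the region where the planted
benchmark scenarios below are recovered perfectly across the grid
$s_1 \in \{1, 2, 4\} \times s_2 \in \{0.5, 1, 2\}$; on ±1-label targets with
log2-ratio profiles of amplitude ~1, a decision-value swing of ±2 requires
roughly $\sum_j |\beta_j| \approx 2$, which is why budgets of this order are
a sensible starting point on any platform.

## Split significance

The centroid (per-probe median profile) of each group summarizes it; the
observed statistic of a split is the Euclidean distance between the two
group centroids.  Its null distribution comes from probe shuffling: in each
of `n_perm` (default 1000) iterations the probe values are shuffled, the
*frozen* separator is re-applied to the shuffled profiles, and the centroid
distance of the resulting two groups (on the shuffled data; 0 if one group
is empty) is recorded.  A normal distribution is fitted to the 1000 null
distances and the p-value is its upper tail at the observed distance.  A
degenerate null (zero variance) yields p = 0 or 1 by direct comparison,
flagged; a one-group labeling yields p = 1 directly.

### Why values are shuffled within probes

Two shuffling schemes are implemented.  The default (`"within-probe"`)
permutes each probe's values independently across samples: each probe keeps
its cohort-level value distribution, but the coherence between a sample's
probes — exactly what ties a CNA to a specific set of carriers — is
destroyed, so the classifier's assignment of shuffled profiles is unrelated
to the true carrier structure and the null describes genuinely random
groups.  The alternative (`"joint-columns"`), one shared permutation of the
probe columns, looks like the more literal reading of "shuffling probes",
but it is a coordinate permutation of $\mathbb{R}^p$: all inter-sample
distances, hence the centroid-distance statistic for any fixed groups, are
exactly invariant.  For an event spanning every probe of the chromosome the
statistic cannot change at all (measured: null = observed with zero
variance, p = 1), and arm-level events fare little better — yet
whole-chromosome gains and losses are precisely the events such a method
must detect.  The within-probe scheme has power against events of every
span and is calibrated on pure noise (measured fraction of p < 0.05 is
0.05 across 100 null cohorts with fixed arbitrary separators); the joint
scheme is retained for comparison on focal events only.

Two caveats documented deliberately.  First, when the separator being tested
was itself selected by the clustering loop, the p-values are conservative —
the centroid distance is not the quantity the QP optimizes, so optimizing
one does not inflate the other; calibration statements therefore use fixed
(arbitrary) separators, the exchangeable case.  Second, the test's power at
a fixed cohort size grows with event span: at the desk scale used in the
tests (60 samples × 200 probes) arm-level events at amplitude/noise ≈ 3 are
detected essentially always, while a 40-probe focal event at 30% prevalence
sits near p ≈ 0.1 — with hundreds of samples (the regime of real tumor
cohorts) focal events regain significance.  Monotonicity of the p-value in
event amplitude holds when the separator is held fixed ("all else fixed");
with the full clustering in the loop, sub-noise amplitudes can change which
split is found, so no monotonicity is claimed there.

## The partition tree

`build_tree()` applies the clustering recursively per chromosome.  Each
node's separator is constrained orthogonal to the separators of *all its
ancestors* (the orthogonality rows enter the QP as equality constraints), so
every level explores a new direction of variation, in the spirit of
principal components; sibling subtrees remain independent.  A candidate
split is kept only if all three stopping criteria pass:

* the group holds **more than** `min_group_size` samples (default 5);
* the split stays within `max_depth` (default 3; root is depth 0);
* the permutation p-value is at most `p_threshold` (default 0.1 — permissive
  on its face, but the statistic is conservative as discussed above).

Rejected nodes become leaves with their `stop_reason` recorded
(`too_small`, `max_depth`, `not_significant`, or `failure` if the QP or the
test errored — failures never abort sibling subtrees).  Trivial clusterings
are leaves under `not_significant`.  Per-node seeds are derived by hashing
the node path into the root seed, giving reproducible yet independent
randomness in every subtree; trees are bit-identical under a fixed root
seed.

## Calling CNAs and co-occurrence

Each cluster's centroid is summarized into discrete calls by a deliberately
simple, pluggable rule: maximal runs of at least `min_probes` (default 5)
consecutive same-arm probes all above `+amp_threshold` (gain) or below
`-amp_threshold` (loss), with the run's mean centroid value as amplitude.
The default threshold of 0.2 log2-ratio units is a typical aCGH noise floor;
both knobs are configuration, and any external centroid segmentation can
replace the rule.  Calls never cross arm boundaries, and coordinates follow
each output format's convention (BED 0-based half-open, SEG 1-based
inclusive).

Samples carry a CNA when they belong to the cluster whose centroid showed
it.  For every unordered pair of CNAs, the 2×2 table of joint membership is
tested with Fisher's exact test, one-sided for enrichment (co-occurrence
beyond background frequencies).  Degenerate margins (a CNA in all or no
samples) are reported with p = 1 and a flag.  All pairs are reported with
their p-values; no significance cutoff is imposed on the table.

## The synthetic cohort generator

`generate_dataset()` builds cohorts as additive planted events over
independent Gaussian probe noise: entry $(i, j)$ is the sum of the
amplitudes of all events carrying sample $i$ and covering probe $j$, plus
$\mathcal{N}(0, \sigma^2)$ noise.  `make_probe_map()` supplies one simulated
chromosome with the p/q boundary at the midpoint and either constant or
log-normal inter-probe gaps (median 1 kb, heavy right tail) to exercise the
distance-weighted fusion.  Named scenarios mirror the event spectrum of real
glioblastoma cohorts — focal (20% of probes), arm-level, whole-chromosome,
a two-level nested configuration, and pure noise — at the default desk
scale of 60 samples × 200 probes, amplitude 1.0, noise sd 0.3, prevalences
15–30%.

What the generator does *not* emulate, and hence what passing tests do not
show: wavy baselines and GC artifacts, tumor purity and stromal dilution
(attenuated, sample-specific amplitudes), heavy-tailed or correlated probe
noise, allele-specific signal, and cohort-level heterogeneity of array
quality.  Results on real data additionally depend on the upstream
normalization the package assumes has already happened (it consumes
lowess-normalized, quality-filtered log-ratios).

## Numerical choices, sizes, and limitations

* QP: solver tolerance is quadprog's working precision; feasibility checked
  at $10^{-6}$; ridge $10^{-10}$ relative; orthogonality sets of rank ≥ p
  are rejected as infeasible.
* Ties at decision value 0 go to +1, deterministically.
* Duplicate probe positions are rejected at read time rather than resolved
  silently; arm labels are required input, since centromere tables vary
  across genome builds.
* Missing values: probes missing in > 20% of samples are dropped, the rest
  median-imputed per probe (the QP needs complete vectors).
* Test problem sizes (60 × 200 cohorts, 200–1000 permutations, 20–100
  seeded replicates) are chosen so the full property suite exercises every
  claim at desk scale; all reported calibration and recovery numbers are
  recomputed at run time by the test suite and `scripts/acceptance.R`, and
  the README's worked example shows actual printed output.
* Known limitations: binary splits only (multi-way structure emerges only
  through the hierarchy); no multiple-testing correction across chromosomes
  or splits (per-split threshold, as in the hierarchical partitioning it
  implements); no regularization-path computation — budgets are explored by
  grid search; the permutation test at small cohort sizes is underpowered
  for very focal events.
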