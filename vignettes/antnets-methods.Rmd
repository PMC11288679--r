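---
title: "Methods: models, estimators and design choices in antnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in antnets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnets)
```

## What the package computes

`antnets` analyses the social organisation of ant colonies from automated
tracking output. The raw material is a table of tag detections (time,
identity, position, orientation, box). From it the package infers pairwise
interactions by head-capsule overlap, pools them into a weighted undirected
network, and asks three questions that recur across social-insect studies:

1. **Is the network modular, and into how many communities?** Soft
   community detection with a rewiring permutation null.
2. **How do individuals distribute across the communities?** Social
   maturity, its bimodal distribution, and division of labour.
3. **Where does the queen sit?** Strength/entropy z-scores and the hourly
   kinetics of queen–worker encounters that explain them.

A synthetic colony generator with planted ground truth accompanies every
stage, so each estimator has a parameter-recovery test.

## Interaction inference

Each ant carries a *head capsule*: a 2-D capsule (segment plus radius)
placed along the heading from the tag centre. Two ants interact in a frame
when the minimum distance between their head-capsule segments is at most
the sum of the radii (boundary inclusive). Defaults — segment from 0.3 to
0.5 body lengths ahead of the tag, radius 0.2 — approximate a typical
annotated head region and are fully configurable, because in real
deployments capsules are annotated per colony.

An *interaction event* for a pair is a maximal run of overlapping frames,
optionally tolerating interruptions of at most `max_gap_frames`
(default 0: no gap closing, since gap tolerance is a deployment choice).
Frames where either ant is undetected count as non-overlap. The network
edge weight is the number of **events**, not frames; this is a documented
convention — frame-weighted networks would up-weight long contacts, and
downstream interpretation changes accordingly.

Ants detected less than two sample standard deviations below the colony
mean detection count are excluded from all analyses, queen included. The
sample (n−1) standard deviation is used everywhere a s.d. appears.

## Soft modularity and its optimiser

With weight matrix $W$, strengths $s_i = \sum_j W_{ij}$, total weight $m$,
and a row-stochastic membership matrix $S \in \mathbb{R}^{n\times k}$,

$$Q = \sum_{c=1}^{k}\sum_{i,j}\left[\frac{W_{ij}}{2m} -
\frac{s_i s_j}{(2m)^2}\right] S_{ic}S_{jc},$$

which reduces to Newman–Girvan modularity for binary $S$ and is 0 for
uniform memberships or $k=1$.

Memberships are fitted by symmetric nonnegative matrix factorisation of
$\tilde W = W/(2m)$ as $X\Lambda X^{\top}$ (columns of $X$ and $\Lambda$
on the simplex), using multiplicative updates that monotonically decrease
the KL divergence $D(\tilde W\,\|\,X\Lambda X^{\top})$ — the static,
single-snapshot case of the soft community detection family used for
insect interaction networks. The soft membership matrix is the
row-normalised $X\Lambda$; isolated nodes get uniform memberships and a
flag. Defaults: 20 random Dirichlet restarts, tolerance $10^{-6}$ on the
objective change, 500 iterations; the restart with the highest $Q$ wins,
and the fit is deterministic given a seed. Monotonicity of the objective is
asserted during optimisation.

One numerical caveat worth knowing: the KL objective is not $Q$. On graphs
whose communities are joined by bridges, the KL optimum places bridge
nodes strictly inside the simplex, and the resulting $Q$ can sit slightly
below the best *hard* bipartition. That softness is the point — it is what
makes social maturity a continuous score — but it means $Q$ comparisons
against hard-partition maximisation are exact only when the planted
structure is clean (e.g. disjoint cliques, which the test suite uses for
the exhaustive-maximisation check).

## The permutation null

The null model preserves what degree-based confounds could explain —
the node set, the binary degree sequence and the exact multiset of edge
weights — while destroying community structure. Default strategy:
weighted double-edge swaps. Two edges $(a,b)$ and $(c,d)$ are rewired to
$(a,d),(c,b)$ with their weights travelling along; swaps creating
self-loops or landing on an existing edge are rejected (weights are never
merged). Ten accepted swaps per edge are attempted; on dense count
networks (common: most ant pairs interact at least once) the full budget
may be unattainable and the replica is returned after the attempt cap,
with a warning only when fewer than one swap per edge was possible. An
alternative `"configuration"` strategy rebuilds a simple graph with the
same degree sequence and deals the weight multiset onto it at random; it
randomises more aggressively, trading exact weight-placement preservation
semantics. Whether the original analysis preserved weights per edge or
redistributed them is not stated; both are provided.

The test statistic is $Q$ at $k=2$ and the p-value uses the add-one
estimator $p = (1 + \#\{Q_{\mathrm{null}} \ge Q_{\mathrm{obs}}\})/
(n_{\mathrm{rewires}}+1)$ with 100 rewires by default, so the smallest
attainable p is $1/101$. The same fitting budget is applied to the
observed network and every null, which is what makes the test
approximately exchangeable under the null; calibration is verified over
200 unstructured replicates in the acceptance suite.

## Social maturity and distribution statistics

For $k=2$, the forager community is the one the queen is *less* affiliated
with; maturity is each ant's membership weight in it (0 = deep in the
nurse community, 1 = deep in the forager community). An exactly tied queen
membership raises an error rather than guessing — orientation is semantic.
If the queen fell to the detection filter, orientation falls back to the
community with the higher soft-weighted mean foraging proportion, and the
report is flagged.

Colony-level statistics: division of labour is the sample s.d. across
workers of the proportion of time spent in the foraging box; the maturity
distribution is summarised by the fraction strictly inside (0.25, 0.75),
the counts above 0.9 and below 0.1, their imbalance
$(n_{>0.9}-n_{<0.1})/n_{<0.1}$, and a one-sample proportions test (with
continuity correction) of intermediate vs extremal counts against an even
split. Queens are excluded from these worker statistics but included in
within-colony z-normalisation, because queen-vs-worker comparisons are
expressed in the same z units. The "normalised entropy" used for queen
comparisons is this within-colony z-score; the original normalisation is
unstated, and this choice is flagged as an assumption.

## Home ranges on hexagons

Arenas are tessellated with pointy-top hexagons anchored at the arena's
lower-left corner. "Hexagons of two ant body lengths" is read as
*circumradius* = 2 body lengths; which hexagon dimension is meant is not
defined, so the size is a configuration knob. The 90% home range ranks
hexagons from most to least visited and accumulates them until at least
90% of the ant's detections are covered (ties broken by stable hexagon
index), reported as a proportion of the total hexagon count of the arena.
Home ranges use nest-box detections only, matching the "proportion of the
nest box occupied" reading. A hexagon belongs to the arena grid when the
rectangle point nearest its centre lies inside it; out-of-bounds
detections (tracking jitter) are clamped with a warning.

## Queen encounter kinetics

Events involving the queen are binned by **start time** into
experiment-relative hours (events spanning a boundary are not split;
clock alignment of the original analysis is unstated). Three statistics
summarise the schedule:

- *workers per hour*: mean over hours of the fraction of the workforce
  contacted; empty hours count as 0;
- *contacts per worker per hour*: mean event count over (hour, worker)
  pairs with at least one contact — zeros never enter;
- *identity conservation*: mean over hours of
  $|A_t \cap A_{t-1}|/|A_{t-1}|$, skipping hours whose predecessor set is
  empty (undefined, with a flag, if every predecessor is empty).

## The synthetic colony generator

The generator is a *stated world*, not a tuning dial: defaults encode the
regime the analysis targets and are fixed once.

- **Scale.** 100 workers plus one queen per colony. Time is scaled to 24
  scheduled hours (instead of five tracked days) and trajectories to 1
  frame/s for a configurable number of frames — rates are per pair per
  hour, so the statistical structure is unchanged while tests stay fast.
- **Maturity.** Bimodal: a planted fraction (default 0.20) strictly inside
  (0.25, 0.75); extremal values split between a low band (< 0.1) and a
  high band (> 0.9) so the high:low imbalance hits its target (default
  0.44) up to integer rounding. Species in the emulated regime vary from
  19–37% intermediate; these are free parameters, as no generative
  mechanism for the variation is known.
- **Membership.** Forager-community membership is Bernoulli with a
  logistic probability in maturity (steepness 8, centred at 0.5), so
  community sizes *emerge* from the maturity profile; `planted_split`
  applies when the block network is generated directly.
- **Edges.** Pair counts are Poisson with mean
  $\text{hours}\cdot a_i a_j q_{\text{class}}$ ($q_{\text{in}} = 2$,
  $q_{\text{out}} = 0.2$ per pair per hour), where $a_i$ are log-normal
  activity multipliers (dispersion 0.5) additionally coupled to maturity
  with coefficient −0.8 so foragers interact less. Pair rates are further
  Gamma-mixed (`pair_dispersion = 1`, i.e. negative-binomial counts,
  mean unchanged). The overdispersion is there for realism — contact
  counts from tracking are strongly overdispersed, and without it worker
  entropies collapse onto their community means, making "worker-typical"
  queen positions unattainable by construction. `pair_dispersion = Inf`
  recovers pure Poisson.
- **Foraging.** Proportion of time in the foraging box is a logistic
  function of maturity (centre 0.8, steepness 10 — foraging takes off
  only at high maturity), scaled by `foraging_scale` (default 0.5), plus
  small Gaussian noise. `foraging_scale` is the division-of-labour dial
  used by the cohort generator.
- **Queen.** One node, never in the forager community by construction.
  Archetypes: *specialist* (≈4% of the workforce as fixed partners every
  hour, total strength calibrated to the worker mean → conservation ≈ 1,
  low entropy), *hub* (worker-typical partner spread, total strength
  3 worker-s.d. above the mean), *worker_like* (a typical nurse's
  expected edge profile — activity × community rate with the same
  pair-level tilts — at worker-mean total strength). The nurse profile is
  deliberate: even a "worker-like" queen lives in the nurse community, so
  her entropy sits slightly below the all-worker mean when the forager
  community is larger; with the default imbalance this lands near −0.8 z.
- **Trajectories.** Reflected Gaussian random walks; the step scale grows
  linearly with maturity (0.2 + 2.3·maturity body lengths per frame), so
  measured 90% home ranges increase with maturity by construction. Each
  ant spends its exact foraging proportion of frames in the foraging box
  as a terminal block; box switches re-draw the position (the boxes are
  separate arenas).
- **Cohorts.** Colony configs co-vary the within:between rate ratio
  (uniform over [2, 16] on a log scale → modularity) and
  `foraging_scale` (→ DOL) with coupling `dol_modularity_slope`; slope 0
  decouples them. Gaussian noise of s.d. 0.05 on the foraging scale
  represents between-colony sampling variation.

### What a green test does and does not establish

The generator plants the *statistical* structure the analysis assumes —
block-structured counts, bimodal maturity, log-normal-ish strengths,
maturity-dependent space use, archetypal queens. It has no behavioural
mechanism: no task allocation, trophallaxis, pheromones, diel rhythm, or
spatial interaction structure (edges and trajectories are generated
independently). Recovery tests therefore establish that the estimators
measure what they claim on data of the assumed form, not that real
colonies have that form.

## Numerical and degenerate-input choices

- Errors are classed (`antnets_invalid_config`, `antnets_data_error`) so
  callers and the CLI can trap them; the CLI maps them to nonzero exits.
- Zero-strength nodes: uniform membership row, `isolated` flag; zero
  total weight: modularity errors.
- `z_normalize` refuses degenerate (constant) groups; DOL requires ≥ 2
  workers; the high:low imbalance is reported missing when no ant is
  below 0.1.
- All randomness is routed through a seed-scoped RNG helper that restores
  the caller's RNG state, so identical (config, seed) pairs give
  byte-identical outputs — including across the C++ code, which consumes
  R's own RNG stream.
- Determinism of reports is to full precision: JSON is written with
  unlimited digits.

## Known limitations

- The soft optimiser maximises reconstruction fit, not $Q$; on heavily
  bridged communities the reported $Q$ is a lower bound on the best hard
  partition's $Q$ (see above).
- Double-edge swaps mix slowly on very dense networks; the configuration
  strategy is the escape hatch, at the cost of different preservation
  semantics.
- GLMM/GAM regressions over the emitted per-ant and per-colony tables are
  intentionally out of scope; the tables are written so any statistics
  package can fit them.
- Temporal (time-sliced) networks are out of scope; data are pooled into
  one static network per colony.
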