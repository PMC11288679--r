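# antnets

Comparative analysis of ant social interaction networks from automated
tracking data.

Colonies of social insects divide labour: some workers stay in the nest and
rear brood, others leave it to forage. Automated tracking makes that
organisation measurable — every ant carries a tag, every tag is detected
several times a second, and pairwise interactions are inferred from the
overlap of annotated "head capsules". `antnets` implements the full
analysis chain that turns such detection records into colony-level
network biology, for behavioural ecologists who want the estimators
without re-deriving them:

- **interaction inference** — capsule-overlap events from detection
  tables, per-box time budgets, exclusion of poorly detected ants
  (below mean − 2 s.d. of detection counts);
- **weighted networks and nulls** — symmetric interaction-count networks;
  degree-preserving weighted double-edge-swap rewiring that preserves the
  node set, binary degree sequence and edge-weight multiset exactly;
- **soft community detection** — soft modularity
  `Q = Σ_c Σ_ij [W_ij/(2m) − s_i s_j/(2m)²] S_ic S_jc`
  maximised over row-stochastic memberships `S` by multiplicative
  KL-divergence updates (symmetric NMF, the static single-snapshot case
  of the FacetNet family), profiled over k = 2..5, with a 100-rewire
  permutation test `p = (1 + #{Q_null ≥ Q_obs}) / (n_rewires + 1)`;
- **social maturity** — membership in the forager community (the one the
  queen is less affiliated with), a continuous 0–1 score, with its
  distributional statistics (intermediate fraction, high:low imbalance,
  proportions test) and the division-of-labour statistic (s.d. across
  workers of the proportion of time outside the nest);
- **space use** — pointy-top hexagonal tessellation (circumradius two
  body lengths) and ranked-hexagon 90% home ranges;
- **queen position** — within-colony z-scores of node strength and node
  entropy (Shannon entropy of an ant's interaction-count vector, zeros
  included, natural log), plus hourly queen–worker encounter kinetics:
  workforce contacted per hour, contacts per contacted worker per hour,
  and hour-to-hour identity conservation `|A_t ∩ A_{t−1}| / |A_{t−1}|`;
- **a synthetic colony generator** — planted two-community networks with
  log-normal activity multipliers and negative-binomial counts, bimodal
  maturity profiles with exact planted band counts, maturity-driven
  trajectories and foraging budgets, three queen archetypes (specialist /
  hub / worker-like) and cohort generation with a tunable
  modularity–division-of-labour coupling, so every estimator has a
  parameter-recovery test.

## Worked example

```r
library(antnets)

cfg    <- colony_config(n_workers = 60, duration_hours = 12,
                        detection_frames = 150, seed = 42)
colony <- simulate_colony(cfg)
report <- run_colony(colony, analysis_config(n_rewires = 100, seed = 1))
print(report)
#> <colony_report> synthetic_colony_1: n=61, best k=2, Q2=0.334 (p=0.009901), DOL=0.201
report$Q
#> $`2` 0.334  $`3` 0.281  $`4` 0.250  $`5` 0.235
report$queen[c("workers_per_hour", "identity_conservation")]
#> $workers_per_hour 0.322  $identity_conservation 0.712
```

Reading the output: soft modularity peaks at two communities (`best_k =
2`) and decreases monotonically to k = 5; the observed Q = 0.334 beats all
100 degree-preserving rewired nulls, so the permutation p is its minimum
1/101 ≈ 0.0099 — the community structure exceeds what the degree sequence
explains. Division of labour (s.d. of foraging proportions across the 60
workers) is 0.201. The worker-like queen contacts 32% of the workforce per
hour and 71% of one hour's contacts repeat in the next; her z-scores
(`report$queen$queen_z_strength = 0.054`, `queen_z_entropy = −0.357`) put
her squarely among the workers, as her archetype plants. Per-ant maturity,
strength, entropy and home-range columns are in `report$per_ant`, ready
for regression.

A command-line front end covers the same pipeline
(`inst/cli/antnets`): `simulate`, `analyze`, `cohort` and `rewire-test`
subcommands with `--seed`, `--k-range`, `--n-rewires`, `--max-gap`,
`--hex-size`, `--config` (JSON) flags.

## Further reading

`vignettes/antnets-methods.Rmd` documents the models and estimators, the
synthetic generator's assumptions and the limits of what its recovery
tests establish, numerical choices (tie-breaks, degenerate inputs,
determinism) and known limitations.
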