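# ddtopo

Links individual impulsivity — delay discounting estimated from
intertemporal choices, and BIS-11 self-report scores — to the topology of
weighted white-matter structural brain networks.

The package is for researchers who have (a) choice data from a
smaller-sooner / larger-later task, (b) BIS-11 questionnaires, and (c)
per-subject tractography summaries (fiber counts and mean FA between
parcellation regions), and want a reproducible pipeline from those raw
tables to covariate-adjusted brain–behavior associations. A synthetic-data
generator with known ground truth makes the entire pipeline testable
without any imaging data.

## The model and statistics at its core

* **Hyperbolic discounting.** Subjective value `SV = A / (1 + kD)`; the
  probability of choosing the delayed option is
  `logit⁻¹(β (SV_del − SV_imm))`. `(k, β)` are fitted per subject by
  maximum likelihood (multi-start L-BFGS-B on log10 scales); subjects who
  always chose one option are excluded. `k` enters analyses as `log10 k`.
* **Connectome edge weights.** `W_ij = FN_ij × FA_ij / mean(vol_i, vol_j)`
  on the 90 cerebral AAL regions (or any node table you supply).
* **Topology.** Weighted clustering `Cp` (Onnela), characteristic path
  length `Lp`, global/local efficiency, strength and betweenness
  centrality (distances `d = 1/W`), hubs (> mean + 1 SD). `Cp` and `Lp`
  are normalized by the means over 100 degree-matched rewired null
  networks: `γ = Cp/Cp_rand`, `λ = Lp/Lp_rand`, small-worldness
  `σ = γ/λ` (> 1 indicates small-world architecture).
* **Association.** Spearman rank correlation between each behavioral score
  and each topological measure after OLS-residualizing both on age, sex,
  and education; global metrics judged at `p < 0.05`, nodal metrics at
  `p < 1/n_nodes` (= 0.011 for 90 nodes).

## Worked example

```r
library(ddtopo)

# 1. fit one simulated subject's discounting (true k = 0.0164, β = 0.005)
trials <- simulate_choices(k = 0.0164, beta = 0.005, seed = 42)
fit <- fit_discounting(trials)
#> k = 0.0160  log10k = -1.796  beta = 0.0088  ll = -2.04  conv = TRUE
```

The estimate recovers the generating rate (0.016 vs 0.0164): at 120 trials
the likelihood pins `log10 k` down to about ±0.1.

```r
# 2. small-worldness of a synthetic 90-node connectome
net <- simulate_connectome(90, mean_degree = 8, rewiring_prob = 0.1,
                           weights = "unit", seed = 7)
ens <- generate_matched_nulls(net, n_nulls = 100, seed = 8)
small_worldness(net, ens)
#> Cp=0.516 Lp=3.114 gamma=7.230 lambda=1.316 sigma=5.494
```

γ ≫ 1 (much more clustered than degree-matched random networks) with
λ near 1 (comparably short paths) gives σ ≈ 5.5: the hallmark small-world
regime a ring lattice with 10% rewiring should land in.

```r
# 3. full pipeline on a simulated cohort with a planted logk–σ link
cfg <- run_config(out_dir = "demo_run",
                  simulate = cohort_spec(n_subjects = 65,
                                         planted_rho = -0.4),
                  n_nulls = 100, seed = 1)
res <- run_pipeline(cfg)
subset(res$global, x == "log10_k" & y == "sigma")
```

The run directory contains per-subject fits and exclusions, topology
reports, the assembled cohort table, the association tables (sorted by p,
with thresholds and significance flags), and a manifest with the seed —
re-running the same configuration reproduces every file byte for byte.

A thin CLI over the same functions is installed at
`inst/cli/ddtopo.R` (subcommands: `simulate`, `fit-dd`, `score-bis`,
`build-network`, `metrics`, `associate`, `validate`, `run`).

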