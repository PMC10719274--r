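---
title: "Methods: from intertemporal choices to connectome topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from intertemporal choices to connectome topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddtopo)
```

## What the package models

`ddtopo` implements an individual-differences pipeline that asks whether a
person's impulsivity — measured behaviorally as delay discounting and by
self-report with the BIS-11 — is associated with the topology of their
weighted white-matter structural brain network. The pipeline has five
stages: discount-rate estimation, questionnaire scoring, connectome
construction, graph-metric computation with null-model normalization, and
covariate-adjusted rank-correlation testing. A synthetic-cohort generator
with known ground truth makes every stage testable end to end.

## Delay discounting

Choices between a fixed immediate reward and a larger delayed reward are
modeled with hyperbolic discounting,

$$SV = \frac{A}{1 + kD},$$

where $A$ is the reward amount, $D$ the delay in days, and $k$ the
subject's discount rate (per day). The probability of choosing the delayed
option is a logistic function of the subjective-value difference,

$$P(\text{delayed}) = \operatorname{logit}^{-1}\!\big(\beta\,(SV_\text{del} -
SV_\text{imm})\big),$$

with a free sensitivity $\beta \ge 0$ and no intercept: on this design an
intercept is not identified separately from $k$, and the choice probability
is by construction a stochastic function of the value difference alone.
$(k, \beta)$ are estimated by maximum likelihood over $(\log_{10} k,
\log_{10}\beta)$ with box constraints $k \in [10^{-6}, 10]$ per day and
$\beta \in [10^{-6}, 10^{3}]$. The surface can be multimodal for extreme
preference patterns, so the optimizer (L-BFGS-B) is launched from the
best-scoring points of an $8 \times 4$ log-spaced start grid; a grid-scan
oracle test verifies the solution attains the global maximum on small
datasets. Estimates at a box bound are flagged (`at_bound`), not excluded.

$k$ is reported as $\log_{10} k$ downstream — base 10 is the dominant
convention in the discounting literature, and since inference is rank-based
the base is immaterial. Subjects who chose the same option on every trial
carry no information about $k$ and are excluded before fitting
(`detect_degenerate`), with the reason (`always-delayed` /
`always-immediate`) logged.

The default task design mirrors a standard laboratory protocol: 120 trials,
immediate reward fixed at 10,000 (KRW), delayed rewards 11,000–48,000 in
1,000 steps, delays 2–180 days. At this trial count the estimator recovers
$\log_{10} k$ with a median absolute error well under 0.3 across the
plausible range $k \in [0.001, 0.1]$ (verified by simulation in the test
suite).

## BIS-11 scoring

The 30 items (4-point Likert) partition into attentional (8 items), motor
(11) and non-planning (11) subscales following the published scoring
standard; 11 reverse-keyed items are scored $5 - r$ before summation.
Totals range 30–120, higher = more impulsive. The key ships as an editable
CSV (`inst/extdata/bis11_key.csv`) so alternative keys can be supplied.

## Connectome construction

Each subject's network has parcellation regions as nodes (the packaged
node table uses the 90 cerebral AAL regions) and edge weights

$$W_{ij} = \frac{\mathrm{FN}_{ij} \times \mathrm{FA}_{ij}}
{(\mathrm{vol}_i + \mathrm{vol}_j)/2},$$

fiber count times mean fractional anisotropy, normalized by the average
volume of the two regions ("average volume" is read as the arithmetic
mean). The division corrects the bias by which larger regions accumulate
more streamlines. No thresholding or binarization is applied: a single
weighted network per subject is analyzed. Disconnected nodes are retained;
all path-based metrics handle them explicitly. The packaged AAL-90 table
carries *synthetic* volumes (real native-space volumes are
subject-specific); real analyses should supply measured volumes.

## Graph metrics

Weights measure coupling strength, so the topological length of an edge is
the reciprocal weight, $d_{ij} = 1/W_{ij}$ — the standard connectome
convention under which stronger connections transmit faster. Choices made
where the literature admits several definitions:

* **Clustering (`Cp`)** — Onnela-type weighted clustering: the geometric
  mean of triangle weights rescaled by the network maximum, over possible
  neighbor pairs. Per-node values stay in $[0,1]$ and the unit-weight case
  reduces exactly to binary clustering (for a ring lattice with even degree
  $K$: $3(K-2)/(4(K-1))$, an identity the tests pin down).
* **Path length (`Lp`)** — mean shortest-path distance over pairs with a
  finite path; the number of unreachable (unordered) pairs is reported
  alongside rather than folded into the mean. The harmonic-mean alternative
  is deliberately left to global efficiency, which is the measure designed
  for disconnection.
* **Efficiencies** — `Eglob` is the mean reciprocal shortest-path distance
  ($1/\infty = 0$); nodal `Eloc` is the global efficiency of the subgraph
  induced on a node's neighbors (weights retained), zero for nodes with
  fewer than two neighbors.
* **Centralities** — degree centrality defaults to strength (weight sums)
  with a `binary` mode switch, since the field's verbal definition is
  binary but the analyzed matrices are weighted; betweenness uses Brandes'
  algorithm on reciprocal-weight distances with fractional sharing of tied
  paths. Nodal values are mean-normalized (divided by the across-node mean)
  before across-subject comparison; any constant normalization factor
  cancels under mean-division, so none is applied to betweenness.
* **Hubs** — nodes exceeding the across-node mean by more than one sample
  (n−1) standard deviation of the normalized centrality.

## Null ensemble and small-worldness

`Cp` and `Lp` are normalized against an ensemble (default 100) of
degree-matched random networks: the binary topology is rewired by
double-edge swaps (default 10 attempted swaps per edge), which exactly
preserves every node's degree, and the original weight multiset is then
randomly reassigned to the rewired edges, preserving the weight
distribution. Then

$$\gamma = C_p / C_p^{\text{rand}},\quad
\lambda = L_p / L_p^{\text{rand}},\quad
\sigma = \gamma / \lambda,$$

with small-world architecture indicated by $\gamma > 1$, $\lambda \approx
1$, $\sigma > 1$. Degenerate case: a complete graph admits no legal swap;
nulls then equal the source topology and a warning is emitted. The whole
ensemble is reproducible from one integer seed.

## Association testing

For each (behavioral score, topological measure) pair, both variables are
OLS-residualized on the covariates (age, sex coded 0/1, education years —
both axes residualized, ranks taken *after* residualization on raw values),
then Spearman's rank correlation is computed with average ranks for ties.
Two-sided p-values use the $t$ approximation with $n-2$ degrees of freedom
(a permutation option exists for small samples). With no covariates the
raw values are ranked directly — centering first would perturb exact ties
by floating-point noise.

Two significance regimes are applied without further multiple-testing
correction, by design: global metrics at $p < 0.05$; nodal metrics at the
node-count-adjusted threshold $p < 1/n_\text{nodes}$ (0.011 for 90 nodes).
The top decile of nodal associations by $|\rho|$ is flagged for
supplementary reporting. Pairs whose residuals are constant (possible for
peripheral nodes in small networks) are reported with `NA` rather than
aborting the battery.

## Synthetic cohorts and the planted effect

The generator emulates the study conditions: 65 subjects; $\log_{10} k \sim
N(-1.9, 0.45)$, straddling a cohort-mean rate of about 0.0164/day;
$\beta = 0.005$; the 120-trial design grid above with trials drawn
uniformly; covariates matching a young-adult cohort (age $22.1 \pm 2.8$,
education $15.0 \pm 1.3$, sex ~43% coded 1); 90-node small-world
connectomes (ring lattice, mean degree 8, Watts–Strogatz rewiring) with
log-normal edge weights, the right-skewed shape the FN×FA/volume
construction produces.

A brain–behavior association is planted through the rewiring-probability
knob: each subject's rewiring probability is a monotone (probit) map of
$a\,z(\log_{10} k) + \sqrt{1-a^2}\,\varepsilon$ into $[0.05, 0.45]$. More
rewiring lowers small-worldness without changing degree or density, so a
negative target correlation corresponds to a positive $\log k \to$ knob
coupling. The latent coupling is $a = |\rho_\text{target}|/0.90$, where
0.90 is a calibration constant fixed by pilot simulation: the measured
transmission of the latent coupling into the realized rank correlation
across the complete chain (choice simulation, likelihood fit, file
round-trip, topology measurement, residualized Spearman); targets beyond
the attainable bound raise an error stating it. BIS
responses are generated from a latent impulsivity weakly coupled to
$\log k$ (latent $r = 0.3$ by default) with item-level Gaussian noise
discretized at fixed cutpoints.

What the generator does *not* emulate: anatomical geometry (no spatial
embedding, no hemispheric symmetry, no distance-dependent connection
probability), realistic fiber-count distributions per tract, or
item-level BIS factor structure. Passing tests therefore demonstrate that
the pipeline's statistics behave correctly under the stated generative
assumptions, not that real DTI data meet those assumptions.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through a deterministic
  splitter (`derive_seed`), so identical configurations reproduce
  byte-identical artifacts.
* Edge lists are serialized by inverting the weight formula (drawing FA,
  rounding FN to at least 1), so file round-trips reproduce intended
  weights up to fiber-count rounding.
* Likelihood evaluation uses `plogis(log.p = TRUE)` for stable log
  probabilities at extreme arguments.
* Matrix symmetry is enforced to $10^{-12}$ relative tolerance; weights
  must be finite and nonnegative with a zero diagonal.
* Zero-variance residuals, all-zero nodal vectors, empty networks, and
  rank-deficient covariate matrices raise informative errors naming the
  offending column where applicable.

## Problem sizes used in the test suite

Unit and property tests run on networks of 3–30 nodes with brute-force
oracles (Floyd–Warshall with path counting; exhaustive likelihood grid
scans) on graphs of up to 8 nodes. The end-to-end planted-effect study
uses 50 simulated cohorts of 65 subjects with 45-node networks and
20-null ensembles — sizes chosen to estimate detection power with
reasonable Monte Carlo precision while keeping the full suite quick to run
on a laptop; the 90-node, 100-null configuration of the headline
small-worldness computation is exercised directly in the acceptance
checks and `scripts/acceptance.R`.

## Known limitations

* "Degree-matched" rewiring preserves binary degree, not strength
  sequences; strength is preserved only in network-wide mean.
* The $t$ approximation for Spearman p-values is accurate for $n \ge 10$;
  the residual degrees of freedom are taken as $n-2$ regardless of the
  number of covariates, which is mildly anticonservative for many
  covariates at small $n$ (the type-I-error property test bounds the
  effect at the study's sample size).
* The pipeline starts from tractography summary tables; nothing upstream
  (tracking, registration, atlas warping) is modeled.
* With an exhaustive nodal battery and no correction beyond the two fixed
  thresholds, nodal findings are screening-level by construction.
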