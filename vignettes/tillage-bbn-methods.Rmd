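---
title: "Methods: a belief-network analysis of tillage choice for winter wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a belief-network analysis of tillage choice for winter wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillagebbn)
```

## The model

The package models one cropping season of winter wheat as a discrete
Bayesian belief network: eleven random variables connected by seventeen
directed links into a DAG, with a conditional probability table (CPT) per
node. Four variables are inputs a land manager either chooses or observes
— tillage system (no-till NT vs conventional CT), the soil (three mapped
soilscapes PDPG6/7/8, each at its native topsoil organic-carbon
percentage of 2.6/4.4/3.9% plus modeled 1/3/5/7% variants, giving a
15-state categorical), seasonal rainfall (mm) and seasonal mean
temperature (°C). Four are intermediaries that carry the soil-water-crop
mechanics: the carbon stock in soil organic matter (C-SOM, kg/ha),
available water space (AWS), precipitation interception, and crop
biomass (kg/ha). Three are the outputs the comparison is about: crop
yield (kg/ha), surface runoff (mm) and GHG-CO₂ emissions (kgCO₂eq/ha).

The edge list encodes standard agronomic causality: tillage and soil act
on C-SOM and AWS; rainfall drives biomass, runoff and AWS; temperature
drives biomass and emissions; C-SOM feeds yield, AWS and emissions; AWS
feeds biomass and runoff; biomass feeds interception and yield;
interception damps runoff. AWS ends up with the largest link count of
any node, which matches its role as the soil-water hub. The topology is
a reconstruction from qualitative statements rather than a published
edge table, so `tillage_network(links = ...)` accepts a replacement edge
list, and `read_network_spec()`/`write_network_spec()` round-trip the
whole structure through a YAML file without loss.

Joint distribution and inference are entirely standard:
\[
P(x_1,\dots,x_{11}) \;=\; \prod_v P(x_v \mid \mathrm{pa}(v)),
\]
with exact posteriors computed by variable elimination under a
min-degree elimination order and renormalized to absorb floating-point
drift (tolerance 1e-9 on all normalization checks). The 11-node network
is far inside the tractable range, so no approximate inference is
offered; the test suite holds the eliminator to full-joint enumeration
within 1e-9 on batteries of random networks.

## Parameter learning

CPTs are learned from complete discretized cases by Dirichlet/Laplace
counting with a uniform pseudo-count `prior_weight` \(w\):
\[
\hat P(s_i \mid \mathrm{pa}) = \frac{n_i + w}{N + wk}.
\]
The original analysis used a commercial tool's default "parametric
learning" for complete case files, which is counting learning; its exact
smoothing is not documented, so \(w\) is exposed with default 1, and
\(w = 0\) gives raw relative frequencies (never-observed parent rows then
fall back to uniform). Missing values are rejected rather than imputed —
the case files this mirrors are complete simulator output — and EM is
deliberately out of scope. One consequence of smoothing worth knowing:
for a row with support \(N\) and a dominant state probability \(p\), the
smoothed estimate differs from the raw frequency by \(|kp-1|/(N+k)\),
which for a near-deterministic 5-state row at \(N \approx 50\) is about
0.05–0.07. Parameter-recovery checks therefore either use \(w = 0\) or
need support well beyond 50 per row.

## Discretization

Continuous variables enter the network as ordered bands. The default
scheme is quantile banding — cut points at the \(k/n\) empirical
quantiles of the *training* data (linear-interpolation definition, R
type 7) — because it reflects the statistical distribution of each
variable; equal-width and explicit boundaries are available for
reproducing externally specified bands. Outputs always use five bands
labelled `Very low … Very high`, the axes on which the published
confusion matrices are printed; other nodes default to five but are
configurable. Intervals are half-open, `[b_{k-1}, b_k)`, a value equal
to a cut point falling in the higher band, and the last band is closed
above. Values outside the fitted range clamp to the outermost bands —
test seasons may exceed the training range, and clamping (not an error)
is the documented behaviour. Duplicate or out-of-range cut points from
heavily tied data (a runoff column that is mostly zero, say) are
collapsed with a warning into fewer bands. Each band carries a midpoint
— the within-band median of the fitting data — which is how
variance-based sensitivity treats ordered bands as real values;
midpoints are attached to the structure with `attach_midpoints()`.

## The synthetic season generator

The crop-simulation case files behind the original model are not
publicly deposited, so the package ships a seeded stochastic emulator,
`simulate_tillage_data()`, that regenerates the study grid: 15 soil
profiles × {NT, CT} = 30 experiments, each over the 48 seasons 1975–2022
(one published table says "48 years from 1974 to 2022", which is 49; the
validation splits pin the usable seasons to 1975–2022 and the generator
follows them), for 1,440 cases. It is a statistical emulator, not a crop
model: no daily time steps, no soil-layer water cascade, no phenology.
Its structural equations were chosen for sign fidelity to the model's
assumption list, with magnitudes loosely anchored to the published
per-experiment summaries:

1. the C-SOM stock decays by a per-season fraction, an order of
   magnitude faster under CT (0.01) than NT (0.001);
2. AWS increases linearly in the effective organic-carbon level, with a
   small CT compaction factor (0.97);
3. biomass = potential (14,500 kg/ha) × soilscape factor × fertility
   \((\mathrm{OC}/4)^{0.27}\) × saturating rainfall response
   (half-saturation 280 mm) × Gaussian temperature suitability
   (optimum 11 °C, width 4 °C) × noise;
4. interception rises from 0.10 toward 0.60 with biomass;
5. runoff = rainfall × coefficient (0.01) × tillage multiplier (CT 2.2)
   × AWS damping × interception damping, amplified 3.5× in
   extreme-rain seasons (above the 90th percentile of the configured
   gamma rainfall distribution);
6. yield = harvest index (0.46) × biomass × (1 − runoff stress), with a
   0.6 penalty in extreme-rain seasons on soils below 3% OC;
7. emissions = (4,000 + 0.5 × C-SOM turnover) × tillage multiplier
   (CT 1.8) × temperature factor × noise.

Noise is multiplicative lognormal with coefficient of variation 0.25
(mean one) on biomass, runoff and emissions, giving right-skewed
seasonal variation; weather is one shared series per run (a single-site
study), rainfall gamma, temperature normal. Every draw flows from the
single `sim_config()` seed, so identical configurations give
byte-identical case files.

Two calibration points fixed the free constants. First, per-experiment
mean yields must land in the published envelope (roughly 2,000–6,100
kg/ha across the 30 experiments), which set the biomass ceiling and the
fertility exponent. Second — the one genuinely subtle choice — the DAG
carries tillage to emissions *only through C-SOM*. A fitted network can
therefore only reproduce the "NT lowers emissions" direction if the
training data make high-carbon bands NT-dominated (hence the strong
decay contrast) and keep the within-tillage turnover term small against
the NT/CT base contrast (hence the small turnover coefficient). With the
defaults, observing NT shifts posterior mass up the C-SOM bands, and the
learned emission CPT — in which high-carbon rows are mostly no-till
seasons — converts that into less mass in the top emission band. The
same composition argument, reinforced by genuinely monotone structural
paths, gives the runoff-down and yield-up directions.

What passing tests on this generator do and do not show: they verify
that the engine learns and propagates the encoded dependency structure,
in the right directions and magnitudes, from data shaped like the study
grid. They cannot certify behaviour on real crop-simulator output —
the emulator has no year-to-year weather autocorrelation, no
soil-layer memory beyond the carbon stock, and independent noise across
variables. One visible consequence: with all other variables observed,
synthetic yield is predicted very well (holdout error ≈ 19% at the
default seed) while synthetic emissions are predicted poorly (≈ 80%),
because without a direct tillage edge the emission node's parents carry
little of the NT/CT contrast that dominates the emulated emissions. The
published model's error rates (29–44%) sit between these extremes, as
expected for a mechanistically richer simulator.

## Validation design

Splits are chronological, never random: holdout trains on 1975–2011
(1,110 cases) and tests on 2012–2022 (330 cases, the printed matrix
total); K-fold uses the decade blocks K1 1975–1984 … K5 2015–2022, each
of K1–K4 tested against training on all other folds, plus a final row
trained on K1–K4 and tested on K5. Banding schemes and CPTs are refit
inside every training partition — the no-leakage tests assert that test
predictions are invariant to any perturbation of test values that stays
within fitted bands. Evaluation observes all non-target variables by
default (the assumed case-testing configuration; `evidence_policy =
"inputs"` switches to inputs only). Error rates are reported to two
decimals; the logarithmic rule uses the natural log and floors the
actual-state probability at 1e-12 (flagged in the report) to keep the
mean finite. Published scoring values for the original model are
implemented and range-checked but not asserted as equalities: they
depend on per-case posteriors that were never printed.

## Sensitivity analysis

`rank_findings()` orders the other ten nodes by variance reduction
\(V(Q) - \sum_f P(f)V(Q\mid f)\) (non-negative by the law of total
variance; computed on state midpoints, so the target must carry them),
with mutual information (bits) and "variance of beliefs" alongside. The
third statistic reconstructs an undocumented report column as
\(\sum_f P(f)\sum_q (P(q\mid f)-P(q))^2\); it is isolated in one
function so it can be swapped if a definition surfaces.
`scenario_influence()` compares posterior band distributions under named
evidence presets (NT, CT, a favorable NT/high-carbon/moderate-rain
composite, an unfavorable CT/low-carbon/extreme-rain composite) against
the no-evidence baseline, in percentage points per band.

## Numerical choices and problem sizes

Normalization tolerance 1e-9 everywhere, with renormalization after
elimination; argmax ties break to the first declared state; declared
state order is authoritative in CPT rows, confusion axes and reports.
The test suite runs the full default grid (1,440 cases) for the
acceptance-style checks and a reduced 20-season grid for unit tests;
oracle-equivalence batteries use networks of up to 6 nodes and 4 states,
where the full joint is enumerable. The end-to-end pipeline
(`run_pipeline()`) on the default grid, including three-target holdout
evaluation, K-fold reports, sensitivity rankings and scenario tables,
completes in well under a minute on one CPU.

## Known limitations

Structure learning, continuous nodes, temporal/dynamic networks,
decision-theoretic (utility) nodes and EM for missing data are out of
scope. The 17-edge topology and the 15-state soil encoding are
reconstructions; both are user-replaceable through configuration rather
than code. The generator emulates one site's seasonal aggregates and
should not be read as a crop model; its published-magnitude anchoring is
qualitative. N₂O and CH₄ emissions, slope/topography effects on runoff,
and the original texture-to-stable-carbon regression are not modelled.
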