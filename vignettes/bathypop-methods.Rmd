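---
title: "Models and methods behind bathypop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bathypop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bathypop studies how four habitat-linked genetic groups of a deep-sea
limpet — three hydrocarbon-seep groups (JR, OH, KK) and one hydrothermal-
vent group (OT) — could have formed and how they exchange migrants. This
vignette documents the models, the estimators, the numerical choices, and
what the synthetic experiments do and do not demonstrate.

## Demographic scenarios

Three competing histories are encoded as pure divergence/founder models
(no gene flow between branches between events; contemporary flow is the
business of the migration module):

1. **Scenario 1** — an ancestral population (size `N_A`) splits at `TA`
   into a deeper-seep lineage (`N_JRpOH`) and the Kuroshima lineage
   (`N_KK`). A propagule of `N_KKP` larvae leaves KK at `T3`, persists as a
   founder branch until the vent group is established at `T2` (size `N_OT`
   from then to the present), and the deeper-seep lineage splits into JR
   and OH at `T1`.
2. **Scenario 2** — the deeper-seep lineage is ancestral; KK itself is
   founded by a propagule `N_AP` at `TA` (founder branch until `T4`), with
   the vent invasion as in scenario 1.
3. **Scenario 3** — the Kuroshima lineage is ancestral; the deeper-seep
   lineage is founded by `N_KKP1` at `TA` (until `T4`) and the vent group
   by `N_KKP2` at `T3`.

Times are in generations before present and ordered
`T1 < T2 < T3 (< T4) < TA`; sizes are diploid effective sizes. Founder
events are modeled as an instantaneous size change on the daughter branch
lasting from establishment back to founding. Beyond `TA` the single
remaining population has size `N_A` (scenario 1), `N_JRpOH` (scenario 2)
or `N_KK` (scenario 3), matching each scenario's notion of which lineage
is ancestral.

**Priors.** Uniform: times on [10, 100,000] generations with the ordering
enforced by rejection; branch sizes on [10, 100,000]; founder propagules
on [5, 1,000]. A propagule may not exceed the terminal size of the branch
it founds (also enforced by rejection; switchable off). These ceilings were
chosen so the upper prior edges sit just above the largest published
posterior quantiles for the corresponding parameters; the package treats
them as the reference study conditions and does not revisit them.

## Coalescent engine

The engine (`src/coalescent.cpp`) is a continuous-time structured
coalescent with piecewise-constant sizes: within a population of diploid
size `N`, `k` lineages coalesce at rate `k(k−1)/(4N)` per generation;
merge and resize events are processed in time order. Each locus is an
independent genealogy carrying **exactly one segregating mutation**.

The subtle choice is the genealogy's distribution. Placing one mutation
uniformly on each simulated tree (the classic fixed-segregating-sites
device) yields derived-allele counts with probability `E[L_i / L]`, which
over-represents singletons by ~6% and depresses high-frequency classes by
~12% at 20 lineages relative to the neutral `1/i` law. bathypop instead
samples genealogies *length-biased* — a tree of total length `L` carries a
segregating site with probability proportional to `L` in the low-mutation
limit — by rejection against an envelope of twice the running mean length
(trees beyond the envelope, about four standard deviations out, are always
accepted; the truncation is undetectable at 200,000 loci). The resulting
spectrum matches `1/i` exactly within Monte-Carlo error, and the engine's
per-group derived-copy distributions agree with an independent coalescent
simulator at the reference parameter values.

Diploids are formed by pairing consecutive lineages within each group
(Hardy–Weinberg within demes; the model has no selfing parameter). An
optional `min_maf` switch redraws loci below a pooled minor-allele
frequency, mirroring an ascertainment applied to observed SNP panels; it
is off by default and switched on where the observed data passed a MAF
filter (see the ABC section).

## GBS noise and the filtering cascade

`add_gbs_noise` decorates clean genotypes with reduced-representation
sequencing artifacts: depth `DP ~ NegBin(mean, size = 5)`; quality
`GQ = min(99, round(3 · DP · f))` with `f = 0.7` for heterozygotes (both
alleles must be sampled among the reads, so heterozygous calls are less
certain at equal depth) and `f = 1` otherwise; genotypes drop to missing
independently at a dropout rate, and always when `DP = 0`.

`apply_filters` runs seven criteria in a fixed order: (1) biallelic;
(2)–(3) genotype-level masking of DP outside [5, 200] and GQ < 20 — the
masking precedes the site-level tests, as in the usual VCF-filtering
semantics, and a regression test pins that order; (4) presence ≥ 80%;
(5) MAF ≥ 0.02 over called genotypes (ties kept — the threshold is
inclusive); (6) observed heterozygosity strictly < 0.5 (paralog guard);
(7) all SNPs discarded on any scaffold with more than nine survivors of
criteria 1–6. "Genomic locus" means scaffold throughout, the only grouping
recoverable for GBS loci mapped to a fragmented survey assembly. The
cascade is idempotent and its report is monotone.

## Genetic statistics

Per group and variant site (≥ 2 called genotypes in the group), with `p`
the alternate-allele frequency and `n_c` the called diploids:
`H_exp = 2p(1−p)`; `H_obs` the heterozygote fraction;
`π = 2p(1−p) · 2n_c/(2n_c−1)` (the unbiased pairwise-difference
correction, so `π` slightly exceeds `H_exp`); `F_IS = 1 − H_obs/H_exp`
where `H_exp > 0`, else 0 — the simple ratio definition, adopted because
the upstream tool chain does not print its exact variant. Group values are
means over variant sites; private SNPs segregate in exactly one group.

`pairwise_fst` uses the Weir–Cockerham (1984) variance components `a, b,
c` per locus, combined as `Σa / Σ(a+b+c)` (ratio of averages). The toy
two-population configuration (genotypes {0,0,1,2} vs {2,2,1,0}) evaluates
to `θ = −5/51`, frozen in the tests from an independent transcription of
the 1984 equations. Negative estimates are reported as computed, never
clipped; a pair with no segregating sites returns an explicit undefined
result rather than zero. Permutation significance shuffles individuals
between the two groups; `p = (1 + #{θ* ≥ θ}) / (B + 1)`, which is
conservative (never anti-conservative) under the null.

Nei's (1972) distance is computed per biallelic locus from
`J_x, J_y, J_xy`; loci fixed for opposite alleles give `D = ∞` and are
excluded from the mean with a reported count. The PCA imputes missing
genotypes to the per-site mean, drops monomorphic sites, standardizes by
`sqrt(2p(1−p))` and eigendecomposes the individual covariance;
coordinates are reproducible up to sign.

## Directional relative migration

For each pair of groups a hypothetical migrant pool takes the unweighted
mean of the pair's per-locus allele frequencies. Nei's multi-locus `G_ST`
(heterozygosities averaged over loci before the ratio) between a member
and the pool measures how much that member resembles the common migrant
stream: the population receiving more immigrants resembles the pool more.
Hence the differentiation between group `a` and the pool maps to migration
*into* `a`, converted by the island-model relation `N_m = (1/G_ST − 1)/4`,
and the matrix is normalized by its maximum. `G_ST` is floored at 1e−12 so
that identical groups produce equal (and after normalization, unit)
entries instead of 0/0. The defining asymmetry — an admixed group receives
more than it emits — is pinned by a deterministic fixture test. No
bootstrap significance filter is applied; the conventional 0.3 display
threshold is presentation, not computation.

## ABC

**Summary statistics** (40 for four groups): per group, the proportion of
loci with zero within-group gene diversity, mean and variance of the
nonzero diversities, and the mean over all loci; per pair, mean and
variance of per-locus WC84 `θ` over loci polymorphic in the pooled pair
(negative `θ` counts as nonzero; monomorphic-pair loci are the "zeros"),
the proportion of zero Nei distances, and the mean Nei distance over
finite loci. Empty nonzero sets are encoded as 0.

**Reference table.** Scenario ids are cycled (uniform scenario prior);
each row is a prior draw plus the statistics of one simulated dataset.
Distances are Euclidean after dividing each statistic by its table-wide
standard deviation; zero-variance statistics are dropped and recorded.
Ties at a neighborhood cutoff break by row index.

**Model choice.** Direct: scenario shares among the 500 closest rows, with
normal-approximation binomial 95% intervals. Logistic: weighted
multinomial logistic regression (Epanechnikov weights in distance) of the
scenario label on the centered, normalized statistics over the closest 1%,
evaluated at the observed point; intervals by the delta method from the
intercept covariance; complete separation is clipped into
[1e−6, 1−1e−6] and renormalized, and a single-scenario neighborhood falls
back to the direct method with a warning.

**Parameter estimation.** Beaumont-style local-linear adjustment: the
closest 1% of the table (taken among the chosen scenario's rows),
parameters logit-transformed to their prior bounds, weighted least squares
on the normalized statistics, residuals recentered at the observed point,
back-transformed, and summarized by weighted median/mean/5%/95% quantiles.
A singular design falls back to unadjusted rejection quantiles (flagged).
Degenerate priors (`lower = upper`) pass through as constants.
Posterior draws violating the scenario's ordering or founder constraints
(possible after adjustment) are rejected when resampling joint draws for
model checking.

**Model check.** PCA of prior-simulated and posterior-simulated statistic
vectors; the observed point is inside the cloud when its Mahalanobis
distance in the first two components is below the 99th percentile of the
simulated points' distances. When the observed panel is MAF-ascertained,
the reference simulations must carry the same `min_maf` — the desk-scale
analysis (`analysis/05_abc.R`) demonstrates that omitting it pushes the
observed point visibly outside the simulated cloud.

**Desk scale and its limits.** The package's reference experiment uses 10
diploids per group, 500 loci, a 20,000-row table and the closest 1%
(about 3.5 minutes of simulation on one CPU); the original analysis scale
is three orders of magnitude larger (3,000,000 rows, ~10,000 SNPs, 121
individuals). Scenario *choice* is robust at desk scale: the true scenario
wins the direct method in 20/20 replicate observed datasets, and the two
methods agree 20/20. Parameter *recovery* is not: with 500 ascertained
loci the summary statistics constrain `N_KKP` (a strong founder
bottleneck leaves a clear signature) but only weakly constrain `N_OT` and
the deeper times, so posterior medians shrink toward the prior and scatter
widely across replicate observed datasets (e.g. `TA` medians ranging
roughly 10,000–42,000 around a truth of 24,400). This is an information
limit of the reduced design, not an estimator defect: even a
random-forest regression of the parameters on the same statistics over
the full prior cannot recover a near-ceiling `N_OT` from data generated
at the reference values. Passing desk-scale tests therefore demonstrates
correctness and calibration of the machinery, not that 500 loci suffice
to reproduce narrow published posterior intervals.

## Synthetic ocean and particle tracking

The synthetic domain is a deep trough (2,500 m) elongated east–west,
ringed by a ridge with crest at 400 m, cut by three gate channels (floors
at 600, 700 and 850 m — the deepest gate is the basin's effective sill),
in an open 5,000-m ocean; grid 1/4°, 8° × 6°. The flow is a zonal jet
with Gaussian cross-section whose core speed decays as
`U(z) = U0 · e^{−z/H}` with `U0 = 1 m/s` and `H = 1000/ln 10`, so
`U(1000 m) = 0.1 m/s` — the observed decay of the regional boundary
current — plus mesoscale eddies: a Gaussian-smoothed random stream
function per level with AR(1) day-to-day persistence (10-day decorrelation,
~0.75° correlation length), scaled so the eddy RMS speed is a fraction
(default 0.3) of the local jet scale. Velocities derive from the stream
function by centred differences of the spherical relations
`u = −(1/R) ∂ψ/∂φ`, `v = (1/(R cos φ)) ∂ψ/∂λ`, which makes the
centred-difference spherical divergence vanish identically; the matching
discrete operator is exported as `field_divergence` and asserted to be
zero at machine precision. Wherever the bathymetry is shallower than a
level's depth the velocity is exactly zero (topographic constraint).
Seasonal means average the daily fields over calendar seasons, winter
taking December together with the following January–February.

Particles are released area-uniform over a geodesic disk (radius drawn as
`R√u`; mean distance from the centre is `2R/3`, pinned to 1%) and advected
horizontally at their fixed release depth — the larvae are assumed to
drift passively at depth, with no swimming behavior. The integrator is a
Dormand–Prince RK5(4) pair with per-step error control (`rtol = 1e−5`,
`atol = 1e−6` degrees), Catmull–Rom bicubic interpolation of the velocity
in space (exact for linear fields, so the solid-body-rotation oracle
isolates the solver error) and linear interpolation in time between daily
snapshots. A particle whose nearest cell is shallower than its depth
beaches terminally (no resuspension; the simplest contract consistent
with topographic blocking); leaving the grid is a terminal domain exit.
Basin accounting classifies daily positions against a polygon (even-odd
rule; self-intersection rejected) and attributes each particle's first
boundary crossing to the nearest named gate segment within 50 km, else
"other".

What the synthetic ocean does *not* emulate: real coastlines and shelf
bathymetry, vertical shear-driven dispersion, tides, and the seasonal
meander of the actual boundary current; conclusions about the real region
rest on the published reanalysis-based experiments, and the synthetic
results only demonstrate that the machinery reproduces the topographic
logic (gates passable above their floors, a basin sealed below its sill).

## Determinism and seeds

Every stochastic operation takes an `rng_seed` and restores the caller's
RNG state. Pipeline runs derive one seed per stage from a master seed via
`derive_seed` (a fixed affine hash modulo 2³¹−1), and the run manifest
records file hashes so reruns can be verified bit-for-bit for the
deterministic stages.

## Known limitations

* No recombination within loci, no selection, no migration between
  branches inside the demographic scenarios.
* The filtering cascade treats criteria in the listed order; observed
  heterozygosity is computed after the MAF filter (the source protocol
  does not state the order; this one is pinned by tests).
* The logistic model-choice intervals ignore the neighborhood-selection
  variability (as does the reference implementation's).
* Ocean fields are serialized with R's native format for caching only; no
  NetCDF round trip is provided.
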