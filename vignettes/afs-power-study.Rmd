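---
title: "Demographic inference from the allele frequency spectrum: models, engine and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference from the allele frequency spectrum: models, engine and study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afspower)
```

## The problem

For unlinked, polarised biallelic SNPs, the allele frequency spectrum
(AFS) is a complete summary of a population-genomic sample: a
P-dimensional array whose cell `[x1, ..., xP]` counts the SNPs whose
derived allele is present in exactly `x_i` of the `2n_i` chromosomes
sampled from population i.  Demographic history — size changes,
splits, migration — leaves characteristic signatures in this array, and
a practitioner planning a sequencing study needs to know how many
*individuals* (not just how many SNPs) are required before those
signatures become statistically usable.

`afspower` packages the full simulation loop needed to answer that
question: compute the expected AFS under a parameterised demographic
model, draw Poisson replicate datasets around it, re-fit competing
models by maximum composite likelihood, and score model selection and
parameter recovery as functions of sample size and event timing.

## Demographic models

Seven piecewise-exponential histories are built in (see
`demographic_model()`):

| model  | populations | parameters | history |
|--------|------------|------------|---------|
| `SNM1` | 1 | θ | constant size |
| `POSG` | 1 | θ, η_G, T | exponential growth to η_G |
| `NEGG` | 1 | θ, η_D, T | exponential decline to η_D |
| `BG`   | 1 | θ, η_D, η_G, T | instant crash to η_D, exponential recovery to η_G |
| `SNM2` | 2 | θ | one panmictic population sampled twice |
| `ISO`  | 2 | θ, s, η_1, η_2, T | split into fractions s, 1−s; no gene flow |
| `IM`   | 2 | θ, s, η_1, η_2, T, m_12, m_21 | split with continuous migration |

Units follow the field's conventions: θ = 4N_A μ L scales the expected
SNP count (N_A the ancestral effective size, μ the per-base mutation
rate, L the surveyed length; only the composite is ever represented);
sizes are relative to N_A; times are in units of 2N_A generations;
m_ij = 2N_A M_ij counts migrants into population i from j.  Two preset
parameterizations reproduce the study design: `"A"` (ancient events,
T = 0.25, strong size changes) and `"B"` (recent events, T = 0.025,
moderate changes, asymmetric migration for IM), with per-model θ chosen
so every model yields roughly equal SNP totals (about 50,000 SNPs at
100 chromosomes under A).  Two further presets probe the extremes:
`"extreme-old"` (T = 1.5) and `"extreme-recent"` (T = 0.005).

Two functional-form choices were genuinely open and are package
decisions.  First, the daughter populations of `ISO`/`IM` change size
*exponentially* from their founding fractions (s, 1−s) to their present
ratios η_i; an instantaneous change would be an equally defensible
reading, but the exponential form matches the convention of the
diffusion-based software lineage this study emulates.  Second, the
`extreme-recent` preset needs a θ: a T = 0.005 split is nearly a
panmictic constant-size history, so θ = 10,000 — the constant-size
preset, giving the same ~50,000-SNP yield at 100 chromosomes — is used.

## The diffusion engine

The expected AFS is computed from the density φ(x, τ) of segregating
variants under the neutral Wright–Fisher diffusion,

∂φ/∂τ = ½ ∂²/∂x² [ x(1−x) φ / ν(τ) ] − ∂/∂x [ m (x' − x) φ ],

with one such pair of terms per population and time measured in 2N_A
generations.  Implementation choices (the numerical details are not
fixed by the study being reproduced, only its grid protocol is):

* **Grid and stepping.**  Uniform frequency grid on [0, 1]; a
  conservative finite-volume discretisation with half-width boundary
  cells; implicit (backward-Euler) time steps, direction-split in two
  dimensions (one tridiagonal solve per row and per column per step).
  The advective migration flux uses central weighting where the cell
  Peclet number allows and first-order upwinding otherwise; the upwind
  branch is also what carries density *off* a boundary line when
  migration re-introduces an allele lost in one population.
* **Mutation influx.**  A source of strength θ/(2h²) at the first
  interior grid point (θ/h³ at the two axis points in 2-D, matching the
  1-D influx per marginal cell).  With this scaling θ/x is the *exact*
  stationary solution of the discrete operator, so the constant-size
  spectrum reproduces the coalescent closed form E[ξ_i] = θ/i up to
  sampling-quadrature error alone.  The ancestral equilibrium is
  therefore available directly rather than by burn-in integration.
* **Time step.**  dt = 0.25 · h · clamp(min ν, 0.05, 1), with the step
  count clamped to [15, 1500] in one dimension and [15, 100] in two
  (dt = T/M exactly).  The floor of 15 steps keeps the relative
  time-truncation error small for very recent events, where the freshly
  split density is still sharply peaked; without it, divergence-time
  estimates at T = 0.005 acquire a visible upward bias.  The cap bounds
  the cost of likelihood evaluations far from the optimum; because the
  error the cap admits scales with dt and dt is tied to h elsewhere,
  the Richardson step removes the leading error where the cap is not
  binding.
* **Split.**  At a population split both daughters inherit the parental
  frequency, so the 1-D density is lifted onto the diagonal of the 2-D
  grid as cell-averaged mass.  `SNM2` needs no integration at all: two
  samples from one panmictic density are a product-binomial quadrature.
* **Sampling.**  Cell k of the spectrum is the trapezoid quadrature of
  C(2n, k) x^k (1−x)^(2n−k) φ(x).  In one dimension the integration
  variable is ψ = xφ, which is finite at the divergent x → 0 boundary
  (ψ → θ at equilibrium).  In two dimensions the boundary *lines* of
  the grid hold genuine density — variants still segregating in one
  population but lost or fixed in the other — and the trapezoid
  boundary weights convert that cell-averaged mass into the `[k, 0]`
  and `[k, 2n]` spectrum classes.  Only the two corner cells
  (monomorphic in the pooled sample) are masked.
* **Richardson extrapolation.**  Each spectrum is computed on three
  grids of `2n + 10/20/30` points and extrapolated cell-wise to zero
  spacing with a quadratic in h, which removes both the O(h) terms the
  upwind/boundary handling introduces and the O(h²) quadrature error.
  Extrapolated cells are clamped at zero.

Accuracy is asserted end to end: constant-size spectra match θ/i to
better than 1%, nested models collapse onto their special cases (`BG`
with η_D = 1 equals `POSG` to machine precision; `IM` at zero migration
equals `ISO`), the no-divergence joint spectrum marginalises onto the
1-D spectrum, and spectra under decline, isolation and migration agree
with an independent structured-coalescent simulator within Monte-Carlo
error (Anscombe Poisson residuals show no systematic bias).

## The coalescent oracle

`simulate_coalescent_afs()` is an independent Monte-Carlo route to the
same expectations: genealogies under the structured coalescent with the
model's time-rescaled rates (thinning handles the time-varying sizes;
migration is an exponential race between lineages).  A branch's
descendant configuration is fixed from its birth to its coalescence, so
expected spectra accumulate per-branch lifetimes into configuration
cells and scale by θ/2 — lower variance than dropping mutations, with
the same mean.  A per-locus mutation mode (Poisson mutations with
weight θ_locus per non-recombining locus) emulates ms-style replicate
datasets; it is the mode used for cross-engine residual checks, because
mutational noise decorrelates cells that share genealogies and makes
the mean Anscombe residual a calibrated bias statistic.

## Data generation and fitting

Replicate datasets are independent Poisson draws around the expected
spectrum (`poisson_sample_afs()`), which makes the composite likelihood
exact by construction: unlinked SNPs, known polarisation, no genotyping
error — the idealisations a real dataset will violate, and the reason
passing these tests bounds only the statistical, not the bioinformatic,
difficulty of real inference.  Every replicate's seed is a stable hash
of (base seed, model, parameterization, n, replicate), so any record
can be regenerated in isolation.

Fitting maximises the Poisson composite log-likelihood Σ (k ln m − m −
ln k!) over log-transformed parameters with a bounded quasi-Newton
optimiser (`stats::optim`, L-BFGS-B), finite-difference gradients of
relative step ε = 1e−6, and the study's convergence protocol: perturb
the starting point coordinate-wise by 2^U(−fold, fold), re-optimise,
and stop once three attempts lie within five log-likelihood units of
the best; replicates that exhaust the attempt cap are recorded as
unconverged and excluded from model-selection summaries.  θ enters the
optimised vector like any other parameter, but its starting value uses
the analytic optimal-scaling shortcut (data total over unit-θ model
total), and — because the expected spectrum is linear in θ — the
gradient component in log θ is analytic and the solver caches one
unit-θ solve per shape vector.  Default starting values are the
geometric mid-range of each parameter's bounds, except the conventional
s = 0.25; bounds follow the study protocol (η_D ∈ [0.001, 1], η_G ∈
[1, 100], one-population T ∈ [0.01, 5], s ∈ [0.01, 0.99],
two-population η ∈ [0.5, 10], T ∈ [0.005, 5], m ∈ [0.1, 20]) with θ ∈
[1e2, 1e6] as a package choice, and individual bounds can be relaxed
per fit (e.g. the T lower bound for extremely recent splits), as the
original protocol did to aid convergence.

Model selection uses AIC = −2 log L + 2K and Akaike weights
w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2); AIC ties (which arise only in
degenerate synthetic cases) resolve toward the smaller K.  Parameter
uncertainty comes from the curvature of the composite log-likelihood:
a central finite-difference Hessian at the maximum, in the original
parameter space so that σ shares the parameter's units, with relative
step 1e−3 refined by one Richardson pass; 95% intervals are ±1.96 σ.
Non-concave surfaces (negative variances) and singular Hessians are
recorded failures and drop out of coverage denominators, mirroring the
study's accounting.  Note the composite-likelihood caveat: for real,
linked data these intervals would be anti-conservative; here the
generator satisfies independence by construction.

## Problem sizes

The full design (`study_design()`) is 9800 replicates: 4 one-population
models × 2 parameterizations × 7 sample sizes (2–50 diploids) × 100
replicates, plus 3 two-population models × 2 × 7 sizes (1–30 diploids
per population) × 100.  The package supports it, but the shipped tests
and the acceptance script run scaled-down cells — 10–50 replicates at
the sample sizes where the study reports its headline numbers — chosen
so the whole suite completes on a single desktop core while keeping the
Monte-Carlo error of each checked statistic within the tolerance it is
checked at.  Replicate counts per statistic are stated next to each
check; medians and proportions are compared against the study's printed
values, correlations and coverage against bands wide enough for the
reduced replication.

## Known limitations

* Spectra are unfolded only; folded spectra, per-SNP genotype matrices
  and VCF ingestion are out of scope.
* At most two populations; no selection, no linkage, no recombination
  within oracle loci, no genotyping-error model.
* The optimiser is local; the convergence protocol (not a global
  search) is the guard against local maxima, exactly as in the protocol
  being studied.  Hard misspecified fits (e.g. `BG` on decline data)
  can exhaust the attempt cap and are then excluded, as the original
  analysis excluded its non-converging replicates.
* The composite-likelihood information criteria adjustments needed for
  linked data are deliberately not implemented.
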