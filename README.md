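# afspower

How many individuals do you need to sequence before the allele
frequency spectrum (AFS) can tell demographic histories apart?
`afspower` is an R package for answering that question by simulation.
It implements the complete loop of AFS-based demographic inference —
expected spectra under parameterised one- and two-population models,
Poisson replicate datasets, composite-likelihood fitting, and
information-theoretic model selection — so that the power of model
choice and the accuracy of parameter estimates can be measured as
functions of sample size and of the timing of demographic events.

## The method

For `2n` sampled chromosomes, the unfolded AFS has cells
`xi_k` counting SNPs with `k` derived copies (`k = 1, ..., 2n - 1`;
the monomorphic corners are masked).  The package:

1. computes the **expected AFS** by solving the neutral Wright–Fisher
   diffusion for the density `phi(x, tau)` of segregating variants
   (`d phi/d tau = 1/2 d^2/dx^2 [x(1-x) phi / nu(tau)]` plus migration
   advection in two dimensions) with an implicit finite-difference
   scheme, binomial sampling, and Richardson extrapolation over grids
   of `2n + 10/20/30` points — under constant size this reproduces the
   coalescent closed form `E[xi_k] = theta / k` to better than 1%;
2. draws **replicate datasets** as independent Poisson counts around
   the expected spectrum (the unlinked-SNP idealisation that makes the
   composite likelihood exact);
3. **fits** candidate models by maximising the Poisson composite
   log-likelihood `sum(k log m - m - log k!)` over log-parameters with
   bounded BFGS, repeating from perturbed starts until three attempts
   agree within five log-likelihood units;
4. **compares** models with `AIC = -2 log L + 2K` and Akaike weights,
   and quantifies estimate uncertainty from the Hessian of the
   log-likelihood (`95% CI = mle +/- 1.96 sigma`), with RMSE and CI
   coverage aggregated over replicates.

An independent structured-coalescent simulator
(`simulate_coalescent_afs()`) cross-checks the diffusion spectra via
Anscombe Poisson residuals.

Seven models are built in — constant size (`SNM1`), exponential growth
(`POSG`), decline (`NEGG`), bottleneck-then-growth (`BG`), panmixia
sampled twice (`SNM2`), split in isolation (`ISO`) and split with
migration (`IM`) — with the study parameterizations `"A"` (ancient
events) and `"B"` (recent events) as presets.

## A worked example

Simulate a recent population decline at 50 diploids, then ask the
four one-population candidates which history produced the data:

```r
library(afspower)

truth <- model_params("NEGG", "A")      # theta = 29000, eta_D = 0.1, T = 0.25
exp_afs <- expected_afs("NEGG", truth, n_chrom = 100)
data <- poisson_sample_afs(exp_afs, seed = 42)

fits <- lapply(c("SNM1", "POSG", "NEGG", "BG"), function(m)
  fit_model(m, data, optimizer_settings(max_attempts = 20), seed = 1))
cmp <- compare_models(fits)
cmp$table[, c("name", "logL", "K", "AIC", "weight")]
#>   name        logL K        AIC        weight
#> 1 SNM1 -11838.6512 1 23679.3024  0.000000e+00
#> 2 POSG -11838.6512 3 23683.3024  0.000000e+00
#> 3 NEGG   -437.1186 3   880.2371  1.000000e+00
#> 4   BG  -1051.6679 4  2111.3359 4.680577e-268

fits[[3]]$mle
#>        theta        eta_D            T
#> 2.827786e+04 1.024669e-01 2.460424e-01
```

The decline model takes essentially all the Akaike weight (`weight`
is the proportional support among the candidates), and the estimates
sit near the simulated truth; `summarize_study()` aggregates medians,
RMSE, weight distributions and CI coverage over many such replicates,
and `run_cell()` runs the whole simulate–fit–compare loop for one
design cell reproducibly from a base seed.

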