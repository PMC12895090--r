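# domfit

Dispersal–observation models for one-dimensional stream-fish
capture–mark–recapture data.

## The problem

In a small stream, fish movement can be tracked at fine spatial grain by
tagging individuals (PIT tags) and resurveying a reach section by section.
But the raw recapture record is a biased picture of movement: a tagged
fish is seen again only if it survived, kept its tag, stayed inside the
study reach, *and* was detected by the gear. Fitting an ordinary
regression to observed displacements conflates movement with
detectability and permanent emigration.

`domfit` implements the joint dispersal–observation model that separates
the two processes. For movement replicate *i* (one capture at occasion
*t* paired with the next occasion):

- **Movement kernel.** The end location follows a heavy-tailed
  location-scale Student-t,
  `X1_i | X0_i ~ t_nu(X0_i, sigma_i)`, with `nu = 5` fixed so outlier
  movers do not dominate the coefficients.
- **Dispersion regression.** The kernel scale is log-linear in
  covariates with a log time offset:
  `ln sigma_i = beta0 + sum_k beta_k x_{k,i} + ln eta_i`,
  where `eta_i` is the elapsed days between occasions. Covariates are
  body size, distance-weighted densities of the four focal species
  (`D_s^w = sum_{s'} D_{s'} exp(-lambda d_{ss'})`, `lambda = 0.1` per
  meter, densities corrected for imperfect detection), Julian day,
  habitat refuge area and current velocity.
- **Observation process.** Recapture is
  `Y_i ~ Bernoulli(phi * z_i)`, where `phi` compounds survival,
  detection and tag retention, and `z_i` indicates whether the (possibly
  latent) end location lies inside the reach `[0, L]` (`L = 430` m).
  Unrecaptured fish still inform the fit: their likelihood term
  `1 - phi * P(0 <= X1 <= L | X0)` is marginalized in closed form (an
  explicit latent-location ("augmented") sampler is also provided and
  agrees with it).

Inference is Bayesian: weakly informative priors
(`beta0 ~ N(0, 2.5^2)`, `beta_k ~ N(0, 1)`, `phi ~ TruncNormal(0.5, 1)`
on (0,1)), an adaptive random-walk Metropolis-within-Gibbs sampler, and
split-chain Gelman–Rubin diagnostics against the R-hat < 1.1 rule.
Effects are reported as posterior medians with equal-tailed 95% credible
intervals and the posterior probability of the dominant sign (robust at
>= 0.95), plus predicted movement bands — the absolute displacement
ranges expected to cover 50% and 90% of individuals.

A self-contained synthetic-data generator emulates the study system (a
430-m reach of 43 ten-meter sections, 15 occasions about 93 days apart,
four species at realistic abundances and body sizes, heavy-tailed
movement, emigration and imperfect capture), so the whole pipeline is
testable without any field data.

## Worked example

Generate 300 movement replicates from the model at known parameters and
recover them:

```r
library(domfit)

gen <- simulate_replicates(n = 300, beta0 = log(0.3),
                           beta = c(body_size = 0.4), phi = 0.5,
                           seed = 42)
sum(gen$replicates$y)      # 134 of 300 recaptured
fit <- sample_posterior(dom_data(gen$replicates, gen$X), model_config(),
                        sampler_config(n_iter = 4000, burn_in = 1500,
                                       thin = 5, n_chains = 4, seed = 42))
summarize_coefficients(fit)
#>        parameter median  lower  upper posterior_probability robust
#> 1          beta0 -1.203 -1.366 -1.029                     1   TRUE
#> 2 beta_body_size  0.383  0.196  0.569                     1   TRUE
#> 3            phi  0.474  0.417  0.530                     1   TRUE
check_convergence(fit)$max_rhat
#> 1.0004
```

The true values — `beta0 = ln 0.3 = -1.204`, `beta_size = 0.4`,
`phi = 0.5` — sit inside every interval even though barely half the
replicates carry an observed end location. Predicted movement bands over
93 days widen with body size (the planted effect):

```r
movement_band(fit, data.frame(body_size = c(-1, 0, 1)), eta_ref = 93)
#>   body_size level q_abs
#>          -1   0.5  13.8     # half of small fish move < 14 m
#>          -1   0.9  38.9
#>           0   0.5  20.3
#>           0   0.9  56.8
#>           1   0.5  29.8     # larger fish range further
#>           1   0.9  84.4
```

## The analysis workflow

Numbered drivers under `analysis/` run the study-scale pipeline end to
end, writing tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | synthetic four-species mark–recapture campaign → `results/data/` |
| `analysis/02_fit.R` | per-species model fits, convergence checks, coefficient matrix → `results/fits/` |
| `analysis/03_recovery.R` | parameter-recovery simulation (coverage, bias) → `results/recovery/` |
| `analysis/04_report.R` | movement bands over the body-size gradient → `results/` |

Each script states what it found on stdout; all computation lives in the
package functions, so everything the scripts do is unit-tested.

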