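# bvsjm — Bayesian variable selection in joint models of longitudinal and interval-censored data

`bvsjm` fits a joint Bayesian model for studies where a continuous marker is
measured repeatedly at clinic visits and the onset time of an event (disease,
hypertension, failure) is only known relative to those same visits — before
the first one (left-censored), between two adjacent ones (interval-censored),
or after the last one (right-censored). It is aimed at biostatisticians who
want efficient joint inference for the two outcomes *and* automatic selection
among many candidate covariates in both submodels.

## Model

For subject *i* with visit times `t_i1 < … < t_im`:

* longitudinal submodel (semiparametric linear mixed effects):

  `y_ij = mu(t_ij) + X_i' theta + xi_i + u_i + eps_ij`

  with `xi_i ~ N(0, sigma_xi^2)`, `u_i ~ N(0, sigma_u^2)`,
  `eps_ij ~ N(0, sigma_eps^2)`;

* survival submodel (semiparametric normal-frailty probit):

  `P(T_i <= t | X_i, u_i) = Phi( alpha(t) + X_i' beta + u_i )`

  with `alpha(·)` an unspecified increasing transform.

The shared frailty `u_i` links the two submodels; the induced association is
`tau = (2/pi) asin(rho)` with
`rho = -sigma_u^2 / sqrt((1 + sigma_u^2)(sigma_eps^2 + sigma_xi^2 + sigma_u^2))`.
`mu(·)` is a free M-spline combination; `alpha(·)` is `r0 + sum_k r_k b_k(t)`
with I-splines and `r_k >= 0`, hence monotone. A unit-variance latent normal
per subject, truncated to a censoring-determined region, turns every full
conditional into a standard distribution, so the whole posterior is sampled
by plain Gibbs (compiled, seed-reproducible). Four prior families on
`(beta, theta)` give four samplers: Bayesian Lasso (`"BL"`), Bayesian
adaptive Lasso (`"BAL"`), spike-and-slab (`"SS"`), and general normal priors
(`"GB"`). A coefficient is *selected* when its 95% equal-tailed credible
interval excludes zero.

## Worked example

```r
library(bvsjm)

design <- simulation_design(n = 300, scenario = "I",
                            sigma_u2 = 0.25, sigma_eps2 = 1)
sim <- simulate_joint(design, seed = 42)
sim$dataset
#> joint_dataset: 300 subjects, 10 covariates, 1185 longitudinal records
#>   censoring: 130 left / 146 interval / 24 right

fit <- joint_gibbs(sim$dataset, prior_config("BL"),
                   iters = 3000, burnin = 500, seed = 42)
fit
#> jm_fit: BL sampler, 2500 retained draws (3000 iterations, 500 burn-in)
#>   data: n = 300 subjects, p = 10 covariates

sm <- summarize_fit(fit)
sm[sm$parameter %in% c("theta1", "theta2", "beta1", "beta3",
                       "sigma_u2", "sigma_eps2", "tau"), ]
#>   parameter       block   mean  lower  upper
#>      theta1       theta  1.015  0.820  1.216
#>      theta2       theta  0.177  0.000  0.358
#>       beta1        beta  0.887  0.455  1.324
#>       beta3        beta  0.133 -0.230  0.498
#>    sigma_u2    variance  0.182  0.071  0.338
#>  sigma_eps2    variance  1.034  0.942  1.136
#>         tau association -0.088 -0.154 -0.036

selection_labels(sm, "theta")
#> positive negative positive negative positive negative positive negative positive negative
selection_labels(sm, "beta")
#> positive positive negative negative positive positive negative negative positive negative
```

The true Scenario-I coefficients are `theta = (1,0,1,0,1,0,1,0,1,0)` and
`beta = (1,1,0,0,1,1,0,0,1,0)`: the posterior means sit near the truth
(`theta1 = 1.015` for truth 1), the intervals for the null coefficients
contain zero, and the selection labels reproduce both truth patterns
exactly. The Kendall's tau summary (−0.088, interval −0.154 to −0.036)
estimates the marker–event association; the generating value at these
variances is −0.117. Larger `n` tightens all of these.

Operating characteristics across replicates:

```r
study <- replicate_study(design, prior_config("BL"), reps = 50,
                         iters = 3000, burnin = 500, seed = 1)
study$report   # BIAS / RMSE / CP95 per parameter, selection size / TN / FN
```

A thin command-line interface wraps the same functions:

```sh
exec/bvsjm simulate --scenario I --n 500 --seed 7 --out data/
exec/bvsjm fit --dir data/ --prior SS --iters 5000 --burnin 1000 --out fit/
exec/bvsjm replicate --scenario II --reps 50 --prior BL --seed 1 --out oc/
```

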