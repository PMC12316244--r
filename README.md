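# symcens

Robust Bayesian linear regression for continuous outcomes that are both
**heavy-tailed** and **censored** — the situation survival times, lengths
of hospital stay and many biomarker readings put you in. Classical
least-squares (and Gaussian Bayesian regression) is distorted by outliers
and biased by censoring; `symcens` addresses both at once.

## Model

The latent outcome follows a linear model with a symmetric error family,

    y*_i = x_i' beta + eps_i,   eps_i ~ F(0, sigma),

with `F` one of Student-t(nu) (nu estimated, support nu > 2), Cauchy
(Student-t with nu = 1 fixed) or Normal (benchmark). Observations are
recorded through a censoring window (L_i, U_i): inside it you see y*_i,
outside you see the bound. The likelihood is exact — densities for
observed rows, tail probabilities F(L_i) / 1−F(U_i) for censored rows —
with priors beta ~ N(0, 10^4 I), sigma ~ half-Cauchy(0, 5),
nu ~ Gamma(2, 0.1) truncated to nu > 2.

Posterior simulation is a fully conjugate Gibbs sampler (truncated-normal
imputation of censored latents, Gamma scale mixture for the t family,
auxiliary inverse-gamma expansion of the half-Cauchy) with a single
Metropolis step for nu. Convergence is reported with rank-normalized
split-Rhat and bulk/tail ESS; models are compared with LPD, WAIC and
PSIS-LOO (Pareto-k diagnostics included). A simulation harness measures
bias, RMSE, coverage and credible-interval width of the procedure under
0–40% right-censoring.

## Worked example

Simulate the design the package is built around (n = 300,
beta = (1, 2, −1), sigma = 1, t3 errors, 10% right-censoring), fit the
Student-t model, and inspect the summary:

```r
library(symcens)

d <- generate_dataset(sim_config(n = 300, censor_rate = 0.1, seed = 5),
                      seed = 5)
fit <- run_mcmc(d, error_family("student_t"),
                cfg = sampler_config(chains = 2, iterations = 2000,
                                     warmup = 1000, seed = 2))
print(summary(fit), digits = 4)
#>     Parameter Estimate Est_Error CI_Lower CI_Upper  Rhat Bulk_ESS Tail_ESS
#> 1 b_Intercept    1.024   0.10646   0.8179   1.2300 1.004  1198.40  1573.87
#> 2        b_x1    1.693   0.13392   1.4189   1.9598 1.002   900.72  1572.00
#> 3        b_x2   -1.203   0.15496  -1.5048  -0.8985 1.001  1121.59  1482.33
#> 4       sigma    1.154   0.08177   0.9923   1.3126 1.050    35.78   114.02
#> 5          nu    4.699   1.21183   2.4685   7.2171 1.144    10.46    60.06
```

The intercept and `x2` intervals cover their generating values (1 and
−1); `x1`'s upper bound sits just below its true 2 in this particular
replicate — at a 95% level roughly one interval in twenty will miss, and
the simulation harness is what quantifies that coverage over many
replicates. `sigma` and `nu` mix slowly under Gibbs (they are strongly
coupled for t errors — note their ESS); the regression coefficients,
which are what the harness scores, mix well. Comparing fit quality:

```r
w <- waic(fit$loglik); l <- psis_loo(fit$loglik)
round(c(LPD = w$LPD, WAIC = w$WAIC, LOOIC = l$LOOIC), 2)
#>     LPD    WAIC   LOOIC
#> -506.80 1025.25 1025.33
```

A lower WAIC/LOOIC is better; on heavy-tailed censored data the Student-t
model beats the Cauchy, which beats the Normal (`compare_models()` runs
all three and writes a report). The command-line interface wraps the same
workflow: `Rscript inst/cli/symcens.R {fit|simulate|compare} --help`-style
flags, metrics as CSV/JSON, and a JSON manifest per run.

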