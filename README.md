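# drgplm

Doubly robust kernel–profile estimation for generalized partially linear
models when the outcome is missing at random.

## The problem

Epidemiological and two-stage studies often measure an expensive or
invasive outcome `Y` only on a subsample: covariates of interest `X`, a
secondary continuous covariate `Z`, and auxiliary variables `U` (a cheap
screening test, say) are observed on everyone, while `Y` is recorded only
where the response indicator `R = 1`, with selection driven by the
first-stage data. The target of inference is the generalized partially
linear model

    E(Y | X, Z) = mu( X'beta + theta(Z) )

with a known monotone link `mu`, a parametric index `X'beta`, and an
unspecified smooth function `theta` of the scalar covariate `Z`.
Complete-case analysis is biased whenever selection correlates with the
outcome. Under the missing-at-random assumption
`Pr(R = 1 | X, Z, U, Y) = Pr(R = 1 | X, Z, U)`, this package estimates
`beta` and `theta` by **augmented inverse probability weighted (AIPW)
kernel–profile estimating equations**: `theta(z, beta)` solves a
local-linear kernel estimating equation whose residual reweights complete
cases by `1/pi-hat` and augments them with a working model
`delta(X,Z,U) ~ E(Y | X, Z, U)`, and `beta` solves the corresponding
profile equation carrying the derivative `d theta-hat / d beta`. The AIPW
estimators are *doubly robust* — consistent if either the selection model
or the outcome working model is correct — and locally semiparametric
efficient when both are. Plain inverse-probability-weighted (IPW) and
unweighted complete-case (naive) variants are included for comparison,
along with sandwich variances that account for the estimated nuisance
models, plug-in pointwise variances for the curve, empirical-bias (EBBS)
bandwidth selection, a Monte Carlo evaluator of the semiparametric
efficiency bound, and a simulation harness for two-stage designs.

The intended users are biostatisticians analyzing outcome-dependent
sampling designs or registry data with missing endpoints, and
methodologists who want a tested reference implementation of the AIPW
kernel–profile machinery.

## A worked example

```r
library(drgplm)

# one draw from the package's two-stage reference design:
# Z ~ U(0,1), X | Z ~ N((Z-0.5)^2, 1), U a uniform-plus-normal composite,
# Y | X,Z,U ~ N(X + m(Z) + U, 1), selection a logistic ramp in U
sim <- simulate_gplm_data(sim_config(n = 500, seed = 7))
df <- data.frame(y = sim$data$y, x = sim$data$x[, 1],
                 z = sim$data$z, u = sim$data$u[, 1])

fit <- gplm(y ~ x, nonpar = ~ z, data = df, aux = ~ u,
            estimator = "aipw", bandwidth = 0.15)
summary(fit)
#> Generalized partially linear model with missing outcomes
#> estimator = AIPW, link = identity, bandwidth = 0.15
#> n = 500, missing outcomes = 42.2%
#>
#> Coefficients (sandwich standard errors):
#>   Estimate Std. Error z value  Pr(>|z|)
#> x   2.2523     0.2353   9.572 < 2.2e-16 ***
```

The implied marginal coefficient on `x` in this design is 2 (the direct
effect 1 plus 1 through the auxiliary composite `U`, whose conditional
mean is `3 + X + Z`); the AIPW estimate 2.25 with sandwich SE 0.24 covers
it, while the naive complete-case fit on the same data is biased
downward. `plot(fit)` draws the fitted `theta-hat(z)` — the sharp
Beta(8,8)-shaped bump on a linear trend — with pointwise 95% bands;
`coef`, `vcov`, `predict`, `fitted` and `residuals` methods behave as for
other modelling classes, and `as.data.frame(fit$theta)` exports the
curve. `run_sim_battery()` runs the full Monte Carlo comparison of
naive/IPW/AIPW under correctly specified and misspecified nuisance
models; see the vignette in `vignettes/` for the methodology, defaults
and numerical choices.

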