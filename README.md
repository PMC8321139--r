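# slme — spatial linear mixed effects models for ETDRS-grid retinal thickness

OCT retinal thickness is reported on the nine-subfield ETDRS grid: a
central subfield (CS) plus four inner and four outer annulus sectors.
A study eye is therefore a nine-vector on a small spatial lattice, many
patients contribute two eyes, and the clinically interesting contrasts —
does a diagnosis group's mean profile differ in *level*, and does it
differ in *shape* (the diagnosis-by-sector interaction)? — depend
critically on how the within-eye spatial correlation and the
between-eye/within-patient correlation are modelled. Ignoring either
misstates standard errors: confidence intervals for patient-level risk
factors can cover far below nominal, and shape tests lose power.

`slme` is for biostatisticians and vision researchers analysing
sector-summarised retinal imaging (or any small-lattice measurements
with nested clustering). It fits the spatial linear mixed effects (SLME)
model

    y_ij = X_ij b + b_i + u_ij + e_ij,
    b_i ~ N(0, s_b^2),  u_ij ~ N(0, s_u^2),
    e_ij ~ N(0, s_s^2 * Lambda C(gamma) Lambda)

for patient i and eye j, where `C(gamma)` is a one-parameter spatial
correlation over sector-centroid distances — autoregressive-by-lag
`gamma^delta`, Gaussian `exp(-gamma d^2)`, exponential `exp(-gamma d)`,
spherical `1 - (3 gamma d - gamma^3 d^3)/2` (clamped), or independence —
and `Lambda` holds optional per-group residual SD ratios
(heteroscedasticity by diagnosis). Estimation is profiled ML/REML via
quasi-Newton optimisation with all linear algebra through Cholesky
factorisations; fixed effects are GLS with model-based covariance
`(X' H^-1 X)^-1`; random effects are BLUPs. Wald and likelihood-ratio
tests, AIC/BIC, top-down model selection, a Monte-Carlo
coverage-and-power harness, and a synthetic clinical-data generator are
included. The methods vignette (`vignettes/slme-methods.Rmd`) documents
every modelling and numerical choice.

## Worked example

Generate a synthetic screening-study dataset (three diagnosis groups,
two eyes per patient, nine sectors, exponential residual correlation,
heteroscedastic by group) and fit the full two-level model:

```r
library(slme)

cfg  <- clinical_sim_config(n_healthy = 30, n_m0 = 60, n_m1 = 60, seed = 7)
dat  <- generate_clinical(cfg)
spec <- slme_spec(thickness ~ age + group + sector,
                  random      = c("patient", "eye"),
                  correlation = corr_spec("exponential"),
                  weights_by  = "group", weights_reference = "M1")
fit <- slme_fit(dat, spec)
summary(fit)
#> Spatial linear mixed effects model (REML)
#>   Fixed:       thickness ~ age + group + sector
#>   Random:      patient + eye
#>   Correlation: exponential
#>   N = 2440  logLik = -10316.64  AIC = 20669.29
#>   Converged: TRUE
#>
#> Fixed effects:
#>             Estimate Std.Error z value Pr(>|z|)
#> (Intercept) 306.3166    6.9701  43.947  < 2e-16 ***
#> age          -0.4884    0.1133  -4.311 1.62e-05 ***
#> groupM0       3.6075    3.9322   0.917    0.359
#> groupM1       5.5921    4.0071   1.396    0.163
#> sectorSI     36.4623    1.0634  34.290  < 2e-16 ***
#> ...
#>
#> Variance components (SD scale):
#>   patient: 17.138  eye: 1.94  residual: 23.217
#>   kernel gamma: 1.3784
#>   residual SD ratios:
#>      M1 healthy      M0
#>  1.0000  0.4571  0.5617
```

The fit recovers the generator's anchors (between-patient SD 18.34,
residual SD 23.8 with group ratios 0.459/0.537/1, decay rate 1.4487 per
mm) to within sampling error at this modest size; `age` recovers its
-0.2 um/year slope less precisely (SE 0.11). A joint Wald test of the
diagnosis main effects:

```r
wald_test(fit, c("groupM0", "groupM1"))
#> wald-chisq test: statistic = 1.9477  df = 2  p = 0.3776
```

The shape effect — whether profile *form* differs by group — is the
joint test of the interaction coefficients of a model containing
`group:sector`, e.g. `wald_test(fit2, pattern = "group.*:sector")`.
Likelihood-ratio tests (`slme_lrt`), BLUPs (`predict_blups`),
information criteria (`information_criteria`) and staged model selection
(`top_down_select`) follow the same fitted-object interface. A thin
command-line wrapper is installed as `exec/slme`
(`slme fit|simulate|make-fixtures`).

## Monte-Carlo calibration study

`run_scenario()` reproduces a three-scenario simulation design (n = 200
participants, one eye each, 70/30 group split, true beta1 = -0.3,
beta2 = 6.1) comparing the spatial model with ordinary linear
regression under no, moderate (gamma_e = 0.5) and high (gamma_e = 0.1)
exponential residual correlation, reporting mean estimates, mean model
SEs, Monte-Carlo SDs, 95% coverage and shape-effect power per approach:

```r
s <- run_scenario(scenario_config(scenario = 3, seed = 1), n_reps = 200)
print(s)            # coverage table; non-spatial CP for beta1 collapses
render_mc_tables(s, csv_path = "scenario3.csv")
```

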