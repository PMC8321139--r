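---
title: "Spatial linear mixed effects models for sector-lattice retinal thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial linear mixed effects models for sector-lattice retinal thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Optical coherence tomography summarises macular thickness on the ETDRS
grid: a central subfield (CS) surrounded by four inner and four outer
annulus sectors (ring radii 0.5, 1.5 and 3.0 mm). A study eye therefore
contributes a nine-vector of thickness values, many patients contribute
two eyes, and the scientific questions — does a diagnosis group differ in
mean thickness, and does the *shape* of its sector profile differ — are
questions about a small spatial lattice observed under two levels of
clustering. Analyses that treat the nine sectors (or the two eyes) as
independent misstate the precision of exactly the contrasts of interest.

`slme` implements a spatial linear mixed effects (SLME) model for such
data: nested random intercepts for patient and eye-within-patient, plus
a spatially correlated within-eye residual process over the sector
lattice, with optional heteroscedastic residual scale by diagnosis group.

## Model

For patient $i$ and eye $j$, the observed thickness vector satisfies

$$
y_{ij} = X_{ij}\beta + b_i + u_{ij} + \varepsilon_{ij}, \qquad
b_i \sim N(0, \sigma_b^2),\;
u_{ij} \sim N(0, \sigma_u^2),\;
\varepsilon_{ij} \sim N(0, \sigma_s^2 \Lambda_{ij} C_{ij} \Lambda_{ij}),
$$

independently across patients. $C_{ij}$ is the kernel correlation over
the sectors observed in that eye and $\Lambda_{ij} = \mathrm{diag}(\lambda_{g})$
carries per-group residual SD ratios ($\lambda = 1$ for the reference
group; identity when homoscedastic). The fixed-effects design follows the
usual partition for this setting: intercept, patient-level covariates
(age, ...), eye-level covariates (diagnosis, visual acuity, ...), sector
main effects with CS as the baseline, and sector-by-covariate
interactions. The joint test of all diagnosis-by-sector interaction
coefficients is the *shape effect*: whether the profile's form, not just
its level, differs between groups.

### Spatial kernels

Four one-parameter families restrict the $9 \times 8/2$ free correlations
to a single rate $\gamma$ acting on the Euclidean distance $d$ between
sector centroids (or on the integer lag $\delta$ under a fixed sector
ordering):

| family | form | admissible $\gamma$ |
|---|---|---|
| autoregressive (lag) | $\gamma^{\delta}$ | $(0,1)$ |
| Gaussian | $\exp(-\gamma d^2)$ | $>0$ |
| exponential | $\exp(-\gamma d)$ | $>0$ |
| spherical | $1 - \tfrac12(3\gamma d - \gamma^3 d^3)$ for $d < 1/\gamma$, else $0$ | $>0$ |

$\gamma$ is a *rate* (larger = faster decay); `rate_to_range()` converts
to the geostatistical range convention $\exp(-d/\rho)$. The spherical
polynomial is clamped to zero beyond its support $1/\gamma$, its standard
variogram form. Assembled correlation matrices are checked for positive
semi-definiteness: a minimum eigenvalue below $-10^{-8}$ is an error,
slight indefiniteness (possible for the spherical and AR families on
irregular lattices) is repaired by eigenvalue clipping at $10^{-10}$ with
diagonal renormalisation. The exponential and Gaussian kernels are
positive definite on any point set and skip the safeguard.

### Grid geometry

Only the ring radii of the ETDRS grid are standardised, not a
representative point per sector, so `etdrs_grid()` places centroids at
the annulus mid-radii: CS at the origin, inner-ring sectors at
$(0.5+1.5)/2 = 1$ mm, outer-ring sectors at $(1.5+3)/2 = 2.25$ mm, at
angles 90/270 degrees (superior/inferior) and 0/180 degrees
(nasal/temporal, mirrored between lateralities). Distances are kept in
millimetres: rates near 0.1–1.5 per mm then produce the "moderate" to
"high" correlation levels that are scientifically meaningful on this
lattice, whereas micrometre distances would underflow the kernels.
Centroid distances are reflection-invariant, so left and right eyes
share one distance matrix; laterality matters only for anatomical
interpretation. The AR lag ordering defaults to ring-then-angle
(CS, SI, NI, II, TI, SO, NO, IO, TO) and is configurable — the AR family
is offered as a candidate structure, not because a canonical sector
ordering exists. Both the centroid radii and custom lattices
(`sector_grid()`, CSV import) are supported.

## Estimation

With $\theta$ collecting the variance parameters, the marginal
log-likelihood is the sum of per-patient multivariate-normal
log-densities with covariance blocks
$H_i = \sigma_b^2 J + \mathrm{blockdiag}_j(\sigma_u^2 J + \sigma_s^2
\Lambda C \Lambda)$; the additive constant $-(N/2)\log 2\pi$ is included.
REML maximises the restricted likelihood, which adds
$-\tfrac12 \log |X' H^{-1} X|$ and removes the fixed-effects degrees of
freedom; the identity
$l_R(\theta) = l(\hat\beta(\theta), \theta) - \tfrac12\log|X'H^{-1}X| +
\tfrac{p}{2}\log 2\pi$ holds exactly under the package's constant
conventions and is asserted in the tests. Given $\theta$, the fixed
effects are generalised least squares with model-based covariance
$(X'H^{-1}X)^{-1}$; random effects are predicted by their conditional
expectations (BLUPs), which reduce to shrunken residual means.

Numerically, everything runs through Cholesky factorisations — log-determinants
from the factor, triangular solves, no explicit inverses. Patients with
identical block structure (same eye layout, observed sectors and weight
group) share one factorisation per parameter value, and their stacked
responses and design columns are whitened in single matrix operations,
so a 200-patient fit costs a handful of $9\times9$ factorisations per
objective evaluation.

The optimiser works on transformed parameters — $\log(\sigma_b/\sigma_s)$,
$\log(\sigma_u/\sigma_s)$, $\log\gamma$ (logit for the AR $\gamma$), and
$\log\lambda_g$ — with the residual scale $\sigma_s$ profiled out in
closed form. A BFGS quasi-Newton search with numerical gradients
(objective tolerance $10^{-10}$, default three starts: one at
method-of-moments initial values, the rest jittered with SD 0.5 on the
transformed scale) is used rather than a pure Newton-Raphson iteration:
near-boundary fits (a variance ratio tending to zero, a decay rate
tending to infinity) are common in this model class and quasi-Newton
steps are robust there. Initial values: $\sigma_s$ from the OLS residual
SD, the patient ratio from the intraclass correlation of OLS residual
patient means, $\gamma_0 = \log 2 / \mathrm{median}(d)$. The `converged`
flag requires both optimiser convergence and a small final numerical
gradient; transformed parameters beyond $\pm 6$ (a ratio below
$e^{-6} \approx 0.0025$) raise a `boundary` flag rather than an error.

Degenerate cases behave sensibly: with no random effects, an
independence structure and equal weights, the fit reduces exactly to
OLS (REML residual variance with divisor $n-p$, ML with divisor $n$);
missing sectors simply select the principal sub-matrix of the kernel
correlation; rows with missing covariates are dropped with a message —
imputation is deliberately out of scope.

## Inference and model selection

Single coefficients get Wald $z$ tests; coefficient sets get the
chi-square form $\hat\beta' V^{-1} \hat\beta$ on $q$ df, or an F form
with a coarse between-within denominator df at the eye level. The exact
finite-sample df for fixed-effect tests in this model class is not
settled; the chi-square reference is the default and the choice is
documented rather than claimed optimal. Pairwise group comparisons are
reported unadjusted (a Holm adjustment can be applied by the user to the
returned p-values). Likelihood-ratio tests require matching estimation
methods, refuse REML comparisons across different fixed-effects designs,
clip the statistic at zero, and flag the boundary caveat when variance
components differ — the naive chi-square reference is then conservative,
which the tests verify empirically.

`information_criteria()` uses $\mathrm{AIC} = -2l + 2p$ with $p$ counting
fixed effects plus variance parameters, and
$\mathrm{BIC} = -2l + p\log n_{\mathrm{eff}}$ with
$n_{\mathrm{eff}} = n$ (ML) or $n - p_{\mathrm{fixed}}$ (REML). A
`bic_doubled_penalty` switch doubles the BIC penalty ($2p\log n$), a form
that appears in some presentations of the criterion; the standard
penalty is the default so that model rankings match the wider
literature. `top_down_select()` implements the usual top-down strategy:
saturated fixed effects under working independence, then the random
structure (REML), then the correlation family (REML), then fixed-effect
simplification (ML), with a full audit trail.

## The Monte-Carlo study

`scenario_config()` / `run_scenario()` reproduce a three-scenario
calibration study: $n = 200$ participants, one eye each, 70% without and
30% with maculopathy, true risk-factor coefficient $\beta_1 = -0.3$ and
diagnosis main effect $\beta_2 = 6.1$, with residual correlation absent,
moderate ($\gamma_e = 0.5$) or high ($\gamma_e = 0.1$). Each replication
is fitted by the spatial model (random participant intercept plus
exponential correlation, REML) and by ordinary linear regression, and
the study reports mean estimates, mean model SEs, Monte-Carlo SDs, 95%
interval coverage, and the shape-effect rejection rate.

The generator's remaining settings are package choices of plausible
clinical magnitude: baseline 283 um, an age-like truncated-normal risk
factor $N(54, 15^2)$ on $[20, 86]$, sector offsets between 0 and 18 um,
residual SD 10 um, and a +2 um maculopathy-by-inner-sector interaction
so that the shape-effect power is defined (set it to zero for a type-I
study). The participant intercept SD defaults to **zero**: the reference
design places all within-participant dependence in the residual
correlation, which is what makes the two approaches coincide — both
correctly specified, coverage at the nominal 95% — when no spatial
correlation is present, and isolates the effect of ignored spatial
correlation in the other two scenarios. The fitted spatial model still
estimates the intercept variance. With a sizeable true intercept SD the
non-spatial comparator's coverage for patient-level coefficients
collapses in *every* scenario and the comparison stops being about
spatial correlation at all.

Replication $r$ uses seed $\texttt{seed} + r$, so runs are exactly
reproducible; failed replications are dropped with a count and more than
5% failures abort the run. At 200 replications the binomial Monte-Carlo
error of a 95% coverage probability is about 1.5 percentage points; the
package's acceptance script uses 300 replications per scenario (about
half a minute each on one core), and the test suite 200 — sizes chosen
to keep the Monte-Carlo error well below the effects being checked.

What passing calibration does and does not show: the generator draws
from the fitted model's own family (Gaussian effects, exponential
correlation, exact 70/30 split), so nominal coverage here demonstrates
internal consistency of the estimation and SE machinery, not robustness
to kernel misspecification, non-Gaussian thickness distributions, or
informative missingness in real scans.

## The synthetic clinical generator

`clinical_sim_config()` / `generate_clinical()` produce nested two-eye
datasets in the shape of a maculopathy screening study: three groups
(healthy / M0 / M1, assigned at patient level), up to two eyes per
patient, nine sectors per eye, truncated-normal age with a $-0.2$
um/year slope, completely-at-random sector missingness, and the full
two-level covariance with heteroscedastic residual ratios. Default
variance components are anchored to fitted values of this model class
on real screening data ($\sigma_b = 18.34$, $\sigma_u = 1.45$,
$\sigma_s = 23.8$ for the reference maculopathy group, ratios 0.537/0.459,
$\gamma_e = 1.4487$ per mm); mean profiles follow the typical macular
topography (inner ring thickest, CS thinnest) with the maculopathy
profile uniformly +4.5 um above healthy and the healthy profile between
the two diabetic groups. Real per-sector group means are not published,
so the profiles are package choices consistent with the published
central-subfield summaries.

A genuine statistical limitation worth knowing: at these anchors the
eye-within-patient SD (1.45 um) contributes ~0.4% of the per-cell
variance, and its REML estimate at 500 patients has a sampling SD larger
than the component itself — point recovery of $\sigma_u$ to tight
relative error is not achievable at that design, while $\sigma_b$,
$\sigma_s$, $\gamma_e$ and the group ratios recover to a few percent.
(With a larger true $\sigma_u$, say 10 um, the same fit recovers it
accurately, which is how the tests separate machinery defects from
information limits.)

## Known limitations

* No nugget effect, anisotropic kernels or Matern family; no random
  slopes or crossed random effects.
* Model-based SEs only (no sandwich correction, no Kenward-Roger df).
* Heteroscedastic weights act on the residual scale only, per cell by
  the eye's group, not on the random-effect variances.
* Missingness is handled by likelihood on the observed cells (valid
  under missing-at-random); no imputation.
* AIC/BIC values are comparable only within this package's constant
  conventions.
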