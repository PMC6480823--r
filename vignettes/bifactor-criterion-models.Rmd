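---
title: "Bifactor models with criterion variables: estimation, nonidentification, and alternatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifactor models with criterion variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifactorid)
```

## The models

The package works with three families of covariance-structure models for a
multifaceted construct (the bundled example: three intelligence facets —
number series *NS*, verbal analogies *AN*, figural unfolding *UN* — each
measured by two test halves) optionally extended with criterion variables
(two ordinal school grades, mathematics and English).

**Correlated first-order model.** One factor per facet; indicators load on
their facet factor only; the factors covary freely. With the bundled data
the two test halves per facet come from an odd–even split, so within-facet
loadings are fixed to 1 and each factor's variance is free (the Mplus-style
default scaling).

**Bifactor model.** An orthogonal general factor $G$ common to all
indicators plus one specific factor $S_k$ per facet,
$Y_{ik} = \lambda^g_{ik} G + S_k + E_{ik}$. With all loadings fixed to 1
this reduces to $Y_{ik} = G + S_k + E_{ik}$.

**Bifactor(S-1) model.** The specific factor of a chosen *reference facet*
is omitted; the reference facet's factor plays the role of the common
factor, the remaining specific factors are residualized with respect to it
and may correlate. Under the constraints used here (reference loadings
fixed to 1, equal free loadings of the non-reference indicators on the
reference factor, free specific covariance) the model is an exact
reparameterization of the first-order model, and the package verifies that
the two fits coincide to $10^{-8}$.

Criterion extensions come in two equivalent forms: *covariance mode* (free
factor–criterion covariances) and *regression mode* (a latent multiple
regression of the criteria on the factors, with a free residual covariance
between the criteria). Criteria are treated as unit-variance
latent-response variables — the continuous variables underlying the ordinal
grades under the usual thresholded-normal model — so their diagonal moments
are fixed at 1 and not counted as data. This is the delta-style convention;
it reproduces the degrees of freedom of every published fit exactly
(6 continuous + 2 ordinal variables give $36 - 2 = 34$ nonredundant
moments).

## The nonidentification result

The scientific core of the package is a diagnosis: *the equal-loadings
bifactor model extended with criterion variables is not identified.* With
equal loadings, the covariance of every indicator with a criterion $C$
decomposes as
$$\mathrm{Cov}(Y_{ik}, C) = \mathrm{Cov}(G, C) + \mathrm{Cov}(S_k, C),$$
the same two-component sum for every indicator of facet $k$. Shifting
$\mathrm{Cov}(G,C) \mapsto \mathrm{Cov}(G,C)+\delta$ and
$\mathrm{Cov}(S_k,C) \mapsto \mathrm{Cov}(S_k,C)-\delta$ for all $k$
therefore leaves every implied moment unchanged —
`nonidentification_family()` constructs this family explicitly (in both
modes; in regression mode the shift is $\beta_G + \delta/\mathrm{Var}(G)$,
$\beta_k - \delta/\mathrm{Var}(S_k)$ with the residual covariance
recompensated), and the tests confirm $\Sigma$-invariance to machine
precision. `local_identification_rank()` finds the same structure
numerically: rank deficiency exactly 2 (one dimension per criterion), with
null directions proportional to $(+1, -1, -1, -1)/2$ on
$\{\mathrm{Cov}(G,C), \mathrm{Cov}(S_k,C)\}$.

The practical consequence, reproduced from the bundled matrix: fixing
$\mathrm{Cov}(S_k,C)=0$ yields a well-fitting model in which only $g$
predicts the grades ($r \approx 0.57$ with mathematics), while fixing
$\mathrm{Cov}(G,C)=0$ yields an equally well-fitting model in which only
the specific factors do — two arbitrary, opposite conclusions from the
same data. Freeing the $g$ loadings restores local identification, but the
estimated loadings are nearly equal, so the model sits close to the
singular set and the factor–criterion standard errors are so large that no
parameter is significant. The simulation module turns that mechanism into a
study: `se_inflation_study()` shows the median factor–criterion SE at
loading spread 0.05 is several times the SE at spread 0.5.

## Estimation: what is matched and what is approximated

Published analyses of this kind use WLSMV on raw data. From a printed
summary the raw-data weight matrix is unrecoverable, so the package fits by
**unweighted least squares** on the assembled hybrid moment matrix
(Pearson covariances among continuous indicators, polyserial-scaled cross
entries, polychoric grade correlation), with DWLS (user or normal-theory
diagonal weights) and normal-theory ML as options. On the bundled matrix
the ULS point estimates track every published parameter within about 0.005,
well inside the package's stated tolerance of ±0.03.

Standard errors are delta-method GLS,
$(J^\top W J)^{-1} J^\top W \Gamma W J (J^\top W J)^{-1}/(n-1)$, with a
normal-theory $\Gamma$ evaluated at the fitted moments. These approximate
the published WLSMV standard errors: the significance *pattern* is
reproduced (none of the 8 factor–criterion parameters of the free-loading
extended bifactor model reaches $|z| \ge 1.96$; the constrained variants
give strongly significant estimates and the SE of the $g$–mathematics
covariance drops to less than half), but individual SEs can differ by
~0.02. One borderline case is known: the unfolding-specific–English
covariance in the free-loading variant with $\mathrm{Cov}(G,C)=0$
(published as significant at $r = 0.183$) comes out at $z = 1.84$ here.
Chi-square values are reported as unscaled $(n-1)F$ and are not comparable
to mean-and-variance-adjusted statistics; degrees of freedom are.

Numerical choices: minimization by `nlminb` from data-informed starts
(loadings 1, factor variances half the mean indicator variance, error
variances half the indicator variance, covariances 0), a 5-restart
seeded-jitter schedule, then Gauss–Newton polishing to a gradient
$\infty$-norm of $10^{-8}$ (with a $10^{-10}$ ridge so that polishing
remains defined on the rank-deficient models, whose minimum is a manifold).
Negative variance estimates (Heywood cases) are warnings, not errors: the
pathological models must remain fittable to demonstrate the pathology.
Jacobians are central finite differences with relative step $10^{-6}$;
analytic columns for covariance-type parameters agree with them to
$10^{-6}$ and are used as a cross-check in the tests. Rank decisions use
the SVD with threshold
$\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max} \cdot 10^{3}$,
evaluated at 25 random admissible points (variances $\sim U(0.5, 2)$,
covariances rescaled to keep $\Phi$ positive definite); the full singular
spectrum is reported so nearly nonidentified models can be audited.

## Ordinal correlations

`polychoric()` and `polyserial()` are two-step estimators: thresholds from
marginal cumulative proportions by inverse normal, then a one-dimensional
likelihood search over the latent correlation (bounded on
$(-1+10^{-6},\, 1-10^{-6})$, tolerance $10^{-8}$). Rectangle probabilities
use an internal bivariate-normal CDF (Gauss–Legendre quadrature of the
standard single-integral reduction, absolute error below $10^{-7}$; tested
against the closed form $P(X<0,Y<0)=\tfrac14 + \arcsin\rho/2\pi$ and an
independent numerical integration). Empty margin categories are merged
into the adjacent category toward the median and logged; boundary estimates
are clamped at $\pm(1-10^{-6})$ and flagged. The published analysis may
have used full-information rather than two-step estimation — the package
assumes two-step, and all checks involving this module are
simulation-based.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` draws factors and criterion latent responses jointly
multivariate normal with the model-implied latent covariance, builds
indicators as loading-weighted factors plus normal errors, and discretizes
the criterion latents at thresholds taken from the *printed grade category
proportions* of the bundled example (Math: 0.123/0.311/0.297/0.174/0.096,
Eng: 0.059/0.393/0.338/0.174/0.037, renormalized). Default population
parameters for the studies are the fitted first-order estimates of the
bundled matrix; replication counts default to 200 at $n = 500$, a
desk-scale setting at which bias in the recovered factor–criterion
correlations stays below 0.02.

The generator is exactly multivariate normal below the thresholds. Real
test-half scores are bounded counts with possible floor/ceiling effects,
grades may violate the proportional latent-normal assumption, and raw data
would allow the WLSMV weight matrix that the package deliberately does not
emulate. A green recovery test therefore establishes that *the estimators
recover the stated population under the model's own assumptions* — not
that those assumptions hold for any particular empirical dataset.

At $n = 100{,}000$ the sample mixed matrix agrees with the population
moments to 0.01 on the correlation metric; on the covariance metric the
sampling error of a variance near 5 is itself about 0.025, so agreement is
asserted on correlations.

For the SE-inflation study the population general-factor loadings follow
the pattern $1, 1-s, 1, 1-s, 1, 1-s$ for spread $s$ (the first loading is
the model's scaling constraint and stays at 1), factor variances 1, all
factor–criterion correlations 0.2, criterion–criterion 0.3 — a moderate,
positive-definite world chosen once. Spread 0 is the nonidentified limit
and is rejected by the gate rather than fitted.

## Design decisions that were genuinely open

* **Criterion scaling.** Whether the latent responses carry unit total
  variance (delta) or unit residual variance (theta) is not stated in the
  source analysis; unit total variance is assumed because the printed
  matrix reports grade *correlations*. All published df values reproduce
  under this choice.
* **Equal reference loadings in the S-1 model.** The printed S-1 table
  shows one non-reference loading (0.781 for the second unfolding half)
  that contradicts its within-facet partner (0.457) despite the stated
  equality constraint, while the standardized values are consistent; the
  package treats the unstandardized print as a typo, keeps the
  equal-within-facet constraint, and reproduces the standardized pattern.
* **Config format.** Model configurations are JSON (the environment has no
  YAML parser); the dialect is declarative — facets, criteria, structure,
  mode, loading directives, `fix_zero` constraints — because the model
  variants differ only in such directives.
* **Identification reporting.** Deficiency is reported with labeled null
  directions, which in the equal-loadings case separate cleanly by
  criterion (one deficiency per criterion), matching the analytic family.

## Limitations

* Point estimates are least-squares on an assembled hybrid matrix; with
  raw data a weighted estimator would differ in the third decimal here and
  possibly more elsewhere. SEs are normal-theory approximations.
* No mean/threshold structures, no multi-group models, no categorical
  measurement models for the indicators, no global-identification proofs —
  local rank is the implemented notion.
* The scaled chi-square difference testing of the source analysis is out
  of scope (requires raw data).

## A worked run

```{r, eval = FALSE}
t1 <- table1_moments()
fit <- fit_model(make_paper_model("fig2b"), t1)
standardize(fit)$factor_corr["AN", "Math"]   # 0.401
local_identification_rank(make_paper_model("fig1b_equal"))$deficiency  # 2
```
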