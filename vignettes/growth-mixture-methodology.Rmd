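---
title: "Growth mixture modelling of prevalence trajectories: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth mixture modelling of prevalence trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The problem

Country-level prevalence indicators — here the percentage of children
under five who are underweight (weight-for-age more than two SD below the
WHO reference median) — are observed annually over decades. Most countries
improve, but not at the same pace, and policy analysis often wants a small
number of *trajectory types*: which countries started badly but improved
fast, which improved slowly, and so on. trajmix implements the growth
mixture model (GMM) used for exactly this kind of question: a finite
mixture of linear latent-growth curves over a units-by-years panel.

## Model

For unit $i$ in latent class $k$, observed at time score
$\lambda_t$ (by default $\lambda_t = \text{year} - \text{first year}$, so
the intercept is the level in the first panel year):

$$y_{it} = \alpha_{i0} + \alpha_{i1}\lambda_t + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \theta),$$

$$(\alpha_{i0}, \alpha_{i1})^\top \sim
N\big((\alpha_{00}^k, \alpha_{10}^k)^\top,\ \Psi\big).$$

$\alpha_{00}^k$ is the class mean level at $\lambda = 0$ (percent) and
$\alpha_{10}^k$ the class mean annual change (percent/year). Marginalizing
the unit-level growth factors gives the class-conditional distribution
$y_i \sim N(\Lambda\mu_k, \Lambda\Psi\Lambda^\top + \theta I)$ with
loading rows $(1, \lambda_t)$, and the observed-data likelihood is the
$\pi_k$-weighted mixture of these multivariate normals. Missing occasions
are handled by restricting the implied moments to the observed
coordinates (the MVN marginalization identity), so units with gaps
contribute exactly the information they carry.

Two structural choices follow the parsimonious convention of the
mainstream latent-trajectory software, because published class-mean/SE
tables rarely identify more: the growth-factor covariance $\Psi$ and the
residual variance $\theta$ are shared across classes (a `classwise_psi`
switch frees $\Psi$ per class), and $\theta$ is homoscedastic across
occasions with no residual autocorrelation. Covariate effects on class
membership or growth factors are out of scope.

## Estimation

The likelihood is maximized by multi-start EM:

* **E-step** — posterior class memberships by Bayes' rule over the
  class-marginal MVN densities; all density arithmetic is in log space
  with log-sum-exp mixing, so widely separated classes cannot underflow.
* **M-step** — class weights are mean posteriors; class means are
  posterior-weighted GLS regressions of each trajectory on $(1, \lambda)$
  under the current implied covariance; $\Psi$ and $\theta$ are then
  updated by posterior-weighted expected-moment formulas using the
  conditional moments of the latent growth factors. The variance updates
  are taken at the *refreshed* means after an internal E-pass, which makes
  the full sweep a multicycle ECM: every iteration provably does not
  decrease the observed log-likelihood, and the fitted trace is checked
  against that guarantee in the tests.
* **Multi-start** — `n_starts = 50` random-partition initializations
  (plus one deterministic k-means-on-OLS-coefficients start) are run for
  `short_iter = 30` sweeps; the best `n_final = 10` continue to
  convergence (`tol = 1e-8` relative change, `max_iter = 500`); the
  highest log-likelihood wins. Classes are then relabelled by descending
  intercept so that "class 1" is always the highest-prevalence class at
  the start of the panel. A start in which a class's posterior mass drops
  below one unit-equivalent is discarded as degenerate; if all starts
  degenerate the fit aborts with advice to lower `K`. The residual
  variance is floored at `1e-6` to keep implied covariances positive
  definite. All randomness flows from one explicit integer seed.

Initialization variances come from per-unit OLS lines: $\Psi$ starts
diagonal at the coefficient variances, $\theta$ at the pooled residual
variance. Single-class fits need no random partitions and use one start.

## Class enumeration

`enumerate_classes()` fits $K = 1..K_{\max}$ and tabulates:

* **AIC** $= -2\ell + 2p$, **BIC** $= -2\ell + p\log n$,
  **SSBIC** $= -2\ell + p\log((n+2)/24)$, with $n$ the number of units
  (countries), not unit-year observations, and $p = 3K + 3$ under the
  shared variance structure.
* **Relative entropy**
  $1 - \sum_{ik} (-p_{ik}\log p_{ik}) / (n \log K)$: 1 when posteriors
  are 0/1, 0 when uniform.
* **Bootstrap likelihood-ratio test** of $K$ vs $K-1$: the LR statistic
  $2(\ell_K - \ell_{K-1})$ is compared with its distribution over `B`
  panels simulated from the fitted $(K-1)$-class model, each refitted
  under both hypotheses; $p = (1 + \#\{LR_b \ge LR_{obs}\})/(B+1)$, so
  $p$ can never be smaller than $1/(B+1)$. The naive $\chi^2$ p-value is
  also reported but labelled invalid: the null hypothesis sits on the
  boundary of the parameter space, which is precisely why the bootstrap
  reference distribution is the primary. Which analytic LRT correction
  (e.g. Lo–Mendell–Rubin) the commercial software applies in any given
  published table is typically unstated and its adjustment is weakly
  documented, so no analytic correction is attempted here.

The selected $K$ is the largest one whose own test rejects at level
$\alpha$ (default 0.10, a deliberate concession to small-$n$ panels)
while the $(K+1)$-vs-$K$ test does not; if nothing qualifies the
selection falls back to one class and is flagged. The full index table is
always returned so BIC-style selection remains available (`lrt = FALSE`
switches to it directly).

Bootstrap replicates use deliberately reduced search settings — a warm
start at the generating estimates plus two random starts, one finalist,
at most 50 EM sweeps and a 15-sweep exploratory phase — mirroring the
reduced-starts convention mainstream software uses for bootstrap draws.
Observed-data fits always get the full multi-start budget. The size of
the resulting test was checked by simulation: over 50 one-class panels
the 2-vs-1 test at $\alpha = 0.10$ rejected in 8% of cases, inside the
binomial sampling band.

## Standard errors

`standard_errors()` offers a parametric bootstrap (simulate from the
fitted model, refit, match classes back by minimal squared distance over
all label permutations, take SDs over replicates — the default,
`B = 200`) and an observed-information method (numeric Hessian of the
mixture log-likelihood on an unconstrained parameterization: means direct,
weights multinomial-logit, $\Psi$ log-Cholesky, $\theta$ log). The two
agree within a factor of two on well-identified instances, which the test
suite asserts on a 12-unit, 4-occasion example.

## The synthetic-data generator

`asia_underweight_spec()` encodes the package's reference scenario: 39
units over 1987–2016 in three classes of 10/20/9 units with intercepts
32.73/10.76/54.26 percent and slopes −0.64/−0.29/−0.93 percent/year —
the published three-class clustering of Asian countries' under-five
underweight prevalence that motivated the package. The variance
components are *not* published anywhere and are package choices, flagged
as such in every run log: $\Psi = \mathrm{diag}(9, 0.01)$ (intercept SD
3, slope SD 0.1, no covariance) and residual SD 2. Under these values the
class lines at $\lambda = 0$ are separated by more than five residual
SDs, which is the regime in which near-unity entropy and tight parameter
recovery (slopes within ±0.10, intercepts within ±2) are reproducible.
One consequence is worth stating plainly: with slope SD 0.1, the sampling
SE of a class's mean slope is about $0.1/\sqrt{n_k} \approx 0.02$–$0.03$,
an order of magnitude below the published slope SEs of 0.11–0.17. Those
published magnitudes imply a within-class slope heterogeneity (SD around
0.4 percent/year) under which individual class means could no longer be
pinned down to ±0.10 on a 39-unit panel. Tight recovery and published-scale
SEs are mutually exclusive for this generator; the package prioritizes the
former and reports whatever SEs the chosen variances imply.

`simulate_panel()` runs the model forward with fixed class sizes (a fixed
country list, not a multinomial draw), clips values to the [0, 100]
percent scale and reports the number of clipped cells, and can mask cells
at a configurable missing rate without ever dropping a unit below the two
observations needed to identify its line.

What the generator does *not* emulate: real-world shocks and
autocorrelated residuals; country-specific measurement error;
the floor effect — because the slowest-declining class ends the panel
near 2–3% prevalence, a few percent of generated cells (typically 2–6%)
touch the 0% floor and are clipped, so the generated low-prevalence
trajectories are very slightly flatter than their nominal lines. Passing
recovery tests therefore demonstrate correctness of the estimator under
the stated Gaussian linear regime, not robustness to everything real
panels do.

## Numerical choices and degenerate inputs

* Likelihood arithmetic in log space throughout; Cholesky factorizations
  shared across classes and units with a common missingness pattern.
* Exact posterior ties in `classify()` break toward the lowest class
  index and are flagged.
* Class matching in recovery tests demands a unique optimal permutation
  and errors on ties rather than guessing.
* A singular restricted covariance (possible only when both variance
  components are pushed to zero) aborts with advice to floor $\theta$.
* `descriptive_stats()` uses the sample SD ($n-1$) and midpoint medians;
  published descriptive tables rarely state these conventions, so they
  are fixed here and documented.

## Problem sizes used in the shipped checks

The test suite and the acceptance script work at the reference scale
(39 units, 30 years): single fits, a 50-seed classification sweep, an
enumeration sweep to $K_{\max} = 5$ with $B = 99$ bootstrap draws per
test, a 50-panel size simulation at $B = 49$, and $B = 200$ bootstrap
SE replicates. Oracle-equivalence checks run on 100 miniature instances
($n \le 5$, $T \le 4$, $K \le 3$) against a brute-force
determinant-and-inverse MVN implementation kept deliberately separate
from the package's Cholesky code path.

## Known limitations

* Linear trajectories only; no quadratic or spline growth.
* No covariates on membership or growth factors.
* The bootstrap LRT inherits Monte-Carlo granularity ($p \ge 1/(B+1)$).
* Entropy is undefined at $K = 1$ (the package errors rather than
  returning a conventional 1).
* With very short panels ($T \approx 4$) the variance components are
  weakly identified and EM converges slowly — a property of the
  likelihood surface, not of the implementation; the observed-information
  SEs are the fragile ones there and the bootstrap is preferred.
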