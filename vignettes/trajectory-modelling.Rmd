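---
title: "Censored-normal trajectory modelling of youth sports participation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored-normal trajectory modelling of youth sports participation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parents of school-age children are prompted once a week by SMS: *how many
times did your child take part in organised leisure-time sport last week?*
The answer is an integer from 0 to 7, with 8 coding "more than seven". Over
five school years this yields a long, irregular panel per child — an open
cohort where children enter at different ages (roughly 5–13), leave at any
time, and are never prompted over Christmas or the six-week summer break.
The scientific questions are (i) whether the population decomposes into a
small number of distinct developmental *trajectories* of weekly sports
participation over ages 6–16, and (ii) whether baseline motor performance
predicts which trajectory a child follows.

`sporttraj` implements the full pipeline: aggregation of the weekly
reports to a monthly panel, a censored-normal group-based trajectory model
(GBTM) fitted by EM, model-selection diagnostics, motor-performance
composites, and a multinomial association model — plus a synthetic-cohort
generator used to validate every stage, since the real cohort is not
publicly available.

## The observation model

For child $i$ in latent group $j$, the monthly outcome $y_{it}$ (average
weekly sessions, in $[0, 8]$) is modelled as a censored normal: a latent
value $y^*_{it} = \beta_j^\top x(a_{it}) + \varepsilon_{it}$,
$\varepsilon_{it} \sim N(0, \sigma^2)$, observed exactly inside the limits
and piled at 0 and 8 otherwise. Here $x(a)$ is a cubic polynomial basis in
age, and the age axis is affinely mapped from the observed range to
$[-1, 1]$ before powers are taken — a cubic in raw ages 6–16 is numerically
ill-conditioned, the scaled basis is not. The likelihood contribution of an
observation is

* $\log \Phi\!\big((0-\mu)/\sigma\big)$ at the floor,
* $\log \big(1 - \Phi((8-\mu)/\sigma)\big)$ at the ceiling,
* the normal log density in between,

evaluated with log-scale tail probabilities so that means 30–40 SDs beyond
a limit remain finite. Group membership is multinomial with probabilities
$\pi_j = \mathrm{softmax}(0, \theta_2, \dots, \theta_G)$; the marginal
log-likelihood sums $\log \sum_j \pi_j L_{ij}$ over children, where
$L_{ij}$ multiplies the censored densities over a child's non-missing
months. Missing months simply drop out of the product, which is the
maximum-likelihood treatment under the missing-completely-at-random
assumption the design implies (non-response is driven by the prompting
mechanics, not by the activity level that week).

One residual SD is shared by all groups and ages. With cubic curves this
gives $k = 4G + (G-1) + 1 = 5G$ free parameters — the bookkeeping used by
the information criteria below.

## Fitting

`fit_gbtm()` runs EM with multiple starts:

* **E-step** — posterior membership probabilities
  $w_{ij} \propto \pi_j L_{ij}$, computed via log-sum-exp.
* **M-step** — $\pi_j = \frac1n \sum_i w_{ij}$ in closed form; the
  coefficients and shared $\log\sigma$ maximise the posterior-weighted
  censored-normal regression by warm-started BFGS with analytic gradients
  (the inverse-Mills-ratio terms at the limits). Because the inner
  optimiser starts from the previous parameters and only improves the
  expected complete-data objective, the observed-data log-likelihood is
  non-decreasing across iterations; the fitter asserts this.
* **Starts** — the first start partitions children by k-means on their
  mean outcome and fits per-cluster least squares; the rest perturb a
  pooled fit at random. The seed is recorded in the fit.
* **Convergence** — improvement below $10^{-6}$ on three consecutive
  iterations, capped at 500 iterations (the inner BFGS is capped at 40
  updates per M-step, which makes early EM iterations cheap without
  affecting the fixed point).
* **Labelling** — groups are relabelled in increasing order of the mean
  fitted curve, so "group 1" is always the least active; modal assignment
  breaks posterior ties toward the lowest group index.

Curves are reported on the observed scale via the censored-normal mean
$E[\mathrm{clip}(Y^*, 0, 8)]$, which keeps every displayed trajectory
inside $[0, 8]$ even when the latent polynomial escapes the range. The
95% point-wise bands use the delta method on $(\beta_j, \log\sigma)$ with
the numerically inverted observed information of the full mixture.

## Choosing the number of groups

`selection_table()` reports, per candidate $G$: the parameter count $5G$;
AIC $= \ell - k$ and BIC $= \ell - \frac{k}{2}\ln n$ in the
larger-is-better convention of the trajectory-modelling software
tradition, with $n$ taken both as observations and as children; the
average posterior probability of assignment (APPA, mean posterior among
the children modally assigned to a group; target $> 0.7$) and the odds of
correct classification (OCC, posterior odds over prior odds using the
estimated $\pi_j$; target $> 5$); the smallest modal group; and
child-level cross-validation.

Cross-validation splits *children* (never observations) into $k$ folds
with one random split, refits on each training set, and scores a held-out
child's months by the posterior-weighted mean absolute distance between
the observed value and the trained group curves, the posteriors coming
from the child's own data under the trained model. This reduces to
$|y - \hat{\mu}_j|$ when assignment is certain. Modal and marginal
($\pi$-weighted) variants are available behind the `method` argument; the
posterior weighting is the default because it uses exactly the quantities
the fitted model claims to know about a new child. Leave-one-out is the
$k = n$ special case and has no seed sensitivity.

`choose_group_count()` encodes the decision rule: the smallest $G$ whose
CV distance is within 2% of the best achieved while APPA, OCC and the
minimum-group-size flags all pass. AIC/BIC are reported but deliberately
not used as the primary criterion — in long panels they keep rewarding
extra groups long after the CV curve has flattened.

## Motor-performance composites

The six baseline tests (KTK backward balance, precision throw, hand grip,
vertical jump, 5×5 m shuttle run, Andersen intermittent run) are oriented
so larger is better (the shuttle-run time is multiplied by −1), then
z-standardised within sex × age-category strata (sample SD, $n-1$). The
default age bins are the two-year bands 6–7, 8–9, 10–11, 12+ — a
conventional choice for school-age fitness references; the bins are a
configurable argument. Composites are unweighted means of member z-scores:
health-related (grip, Andersen), coordination-related (jump, shuttle,
balance, throw), total (all six). Tertiles cut at the order statistics
$x_{(\lceil n/3 \rceil)}$ and $x_{(\lceil 2n/3 \rceil)}$ with ties
assigned downward — an explicit rule, because with tied composites *some*
tie policy is unavoidable and an undocumented one is not reproducible.
Composites over partially missing tests are computed over the available
members and flagged; complete-case filtering is the caller's choice.

## Association model

Trajectory group membership (modal assignment, reference group 1) is
regressed on sex, school type and motor tertiles by maximum-likelihood
multinomial logit; exponentiated coefficients are relative risk ratios. In
a univariable model with one categorical predictor the RRRs coincide with
the contingency-table cross-ratios — a saturated-model identity the test
suite exercises on a printed-table fixture. Standard errors use a
cluster-robust sandwich $A^{-1}\big(\frac{M}{M-1}\sum_c s_c s_c^\top\big)
A^{-1}$ with scores summed within schools (class-level clustering is a
matter of passing different ids); the bread $A$ is the analytic multinomial
information. The small-sample factor $M/(M-1)$ is a documented convention.
The overall test is the likelihood-ratio chi-square against the
intercept-only model; a Wald variant is easy to assemble from the same
pieces but the LR form is the default because it is invariant to
parameterisation. The two-stage approach (fit trajectories, then regress
hard assignments) ignores classification uncertainty; with APPA near 1 —
the regime the adequacy thresholds enforce — the attenuation is
negligible.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the *structure* the analysis assumes: an
open cohort (~1,500 children by default, entry ages 5–13, 15% entering
late, geometric dropout), a prompt calendar with 44 weeks/year (Christmas
and six summer weeks suspended), integer weekly counts obtained by
rounding and clipping a latent normal around group-specific cubic age
trends, static one-or-two-sport sets per child, non-response at a
configurable rate, and six motor tests driven by one latent fitness factor
with group-specific shifts (shuttle run loaded negatively). Default group
shares (13.5%, 27%, 29%, 22%, 8.6%) and curve shapes (a stable near-zero
group, a low decreasing one, and three increasing at different rates,
easing after ~14) mimic the published five-group pattern; response rate
(0.8/week) and dropout hazard (0.005/month) are not reported anywhere and
are the package's own plausible defaults, exposed as arguments.

`generate_model_faithful_panel()` instead draws monthly values *exactly*
from the censored-normal model (no rounding): this is the right instrument
for parameter-recovery claims, because the realistic generator's
round-and-clip observation process is deliberately *not* the fitted model.
Passing recovery tests therefore demonstrates correctness of the
estimator, not robustness to everything real data can do: the simulators
have no seasonal participation waves, no informative missingness, no
sport-switching dynamics, and a single shared σ. The recovery experiments
use 600 children × 60 monthly points with three well-separated groups
(means 2.5–3 SD apart) over five seeds — large enough that failures
indicate bugs rather than sampling noise, small enough to run routinely.

## Numerical choices and degenerate inputs

* Tail probabilities always via `pnorm(log.p = TRUE)`; inverse Mills
  ratios as `exp(dnorm(log=TRUE) - pnorm(log.p=TRUE))`.
* The M-step objective guards against non-finite proposals (the BFGS line
  search can overshoot $\log\sigma$); $\pi_j$ is floored at $10^{-8}$.
* A fit in which censoring is never active collapses to ordinary weighted
  least squares; the test suite checks the $G = 1$ case against the
  closed form to $10^{-6}$.
* Children with all months missing are an error at the likelihood level —
  the exclusion rule upstream must remove them.
* Empty modal groups make APPA (and OCC) undefined for that group; they
  are reported as `NA` and fail the adequacy flags rather than being
  dropped silently.
* `APPA = 1` yields an infinite OCC, reported as `Inf`.

## Problem sizes

The bundled analysis scripts run the simulate → aggregate → select →
associate chain on 400 children with 2-fold CV over $G = 1..6$; the test
suite uses 600 × 60 panels for recovery and ~250 children for the CV-curve
experiment. These sizes were chosen so the whole pipeline re-runs in
minutes on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances; every generator argument scales up unchanged.

## Known limitations

* No time-varying covariates and no group-specific residual SD.
* Trajectory shapes are polynomials of degree ≤ 3; no splines.
* The association stage is two-stage by design; joint estimation of
  trajectories and covariate effects is out of scope.
* CV refits use fewer random starts than the headline fits; with very
  poorly separated groups a fold could land in a local optimum, which
  would inflate the CV distance for large $G$ rather than favour it.
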