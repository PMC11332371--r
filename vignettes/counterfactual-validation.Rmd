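---
title: "Counterfactual validation of predictions under interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual validation of predictions under interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An interventional prediction model estimates, for a person with baseline
predictors $X$, the risk of an event within a horizon $\tau$ **if they were to
follow a given treatment strategy**: $R^{\bar a}(\tau \mid X) = \Pr(T^{\bar a}
\le \tau \mid X)$, where $T^{\bar a}$ is the counterfactual event time under
the static, deterministic strategy $\bar a = (a_0, a_1, \ldots)$ — for
example *never treated* ($\bar a = 0$) or *always treated from time zero*
($\bar a = 1$). Such predictions support decisions like organ allocation,
where the relevant comparison is between a patient's risk with and without
the intervention.

Validating these predictions is harder than validating ordinary prognostic
models: in an observational validation cohort only some people followed the
strategy of interest, and which people did is confounded — often by
time-dependent covariates that both drive treatment decisions and predict
the outcome. Simply comparing predictions with outcomes in the subset who
happened to follow the strategy (the *subset approach*) is prone to
selection bias. `cfvalid` implements *counterfactual performance*
estimators: what calibration, discrimination and prediction error would have
been observed had **everyone** in the validation data followed the strategy.

## Artificial censoring and inverse probability weighting

The validation data are longitudinal: visits $k = 0, 1, \ldots$ with
time-dependent covariates $L_k$ and treatment status $A_k$, and a
continuous event/censoring time. Two steps create a pseudo-population in
which everyone follows $\bar a$:

1. **Artificial censoring.** Each subject is censored at the first visit
   $C_a$ at which their observed treatment deviates from $a_k$ (possibly
   visit 0). Writing $\tilde T = \min(T^*, C_a)$, the retained event
   indicator is $\tilde D = I(T^* < C_a)\, D$ — strict inequality, so an
   event occurring exactly at the deviation visit counts as censored.
   Subjects deviating at visit 0 stay in the set with zero follow-up so the
   visit-0 treatment model still sees them.
2. **Reweighting.** Remaining person-time is weighted by the inverse
   probability of remaining adherent given covariate history,
   $$G_a^{-1}(t \mid L) = \prod_{k=0}^{\lfloor t \rfloor}
     \frac{1}{\Pr(A_k = a_k \mid \bar A_{k-1} = \bar a_{k-1}, \bar L_k)},$$
   a step function constant on $[k, k+1)$. Its left-hand limit at integer
   $t$ drops the factor at $k = t$. Standard (non-artificial) censoring is
   assumed covariate-free and handled by the reverse Kaplan–Meier estimate
   $G_c(t) = \Pr(C > t)$; the combined weight is $G_{ac}^{-1}(t \mid L) =
   G_a^{-1}(t \mid L)\, G_c^{-1}(t)$.

The adherence probabilities are estimated by a pooled discrete-time logistic
regression across visits, fitted **in the validation data** on the adherent
risk set. Visits with a deterministic outcome (for instance continuation
visits under an absorbing treatment, where everyone who has started stays
treated) are handled outside the regression with probability 1. The
adjustment set defaults to the time-dependent covariate history (the
`formula` argument exposes it; baseline prognostic variables that do not
affect treatment need not enter). Validity rests on conditional sequential
exchangeability, consistency, positivity, and correct specification of this
model — none of which the data can verify, which is why the package also
ships violation scenarios (below).

## The performance measures

All estimators live on the censored set $V_a$ and reduce exactly to their
standard unweighted analogues when everyone is adherent and uncensored
(this is tested):

* **Mean calibration**: observed counterfactual risk from a Kaplan–Meier
  estimator in which each subject contributes their time-varying weight
  $G_a^{-1}(t \mid L)$ to risk sets and event counts, divided by the mean
  predicted risk over **all** $n$ validation subjects (O/E ratio).
* **Grouped calibration**: predictions cut into $G$ equal-sized groups
  (default 10, stable ordering for ties); weighted-KM observed risk per
  group against the group's mean prediction.
* **c-index up to $\tau$**: weighted concordance over comparable pairs
  ($\tilde T_i < \tilde T_j$, $\tilde T_i \le \tau$, $\tilde D_i = 1$) with
  pair weight $G_{ac}^{-1}(\tilde T_i{-} \mid L_i)\, G_{ac}^{-1}(\tilde T_i
  \mid L_j)$ — left limit for the case, value at the case's event time for
  the comparator. Prediction ties earn zero by default (the estimator's
  indicator is a strict inequality); `tie_credit = TRUE` gives the
  conventional half credit. Simultaneous events are not comparable.
* **Cumulative/dynamic AUC at $t$**: cases have events by $t$, controls are
  event-free beyond $t$; the control weight is evaluated at $t$. The exact
  weight placement for controls is our reconstruction by analogy with the
  c-index weights; it reduces to the usual IPCW AUC without artificial
  censoring.
* **Brier score at $t$**: weighted mean squared error with event
  contributions weighted at their event time and survivor contributions at
  $t$; censored-before-$t$ subjects contribute zero, the divisor is $n$.
  The scaled Brier score benchmarks against a null model that assigns
  everyone the weighted counterfactual event proportion; we estimate that
  proportion by the Horvitz–Thompson sum of weighted event indicators
  (weights at the subjects' own event times — the estimator unbiased under
  the same assumptions as the event term of the Brier score itself).

The **subset comparator** (`subset_approach_metrics()`) evaluates the same
measures without the artificial-censoring weights, treating artificial
censoring as if it were ordinary covariate-free censoring (reverse KM on
$(\tilde T, \tilde D)$). That is what a naive analysis would do, and it is
biased exactly because this censoring is informative. Its O/E denominator
and calibration groups are restricted to subjects who enter $V_a$ with
positive follow-up, whereas the counterfactual versions average over all
$n$ subjects.

```{r}
library(cfvalid)
tab <- read_longitudinal("validation.csv", "schema.yaml")
preds <- read_predictions("predictions.csv")
report <- counterfactual_metrics(tab, preds, never_treated(), tau = 5)
report
plot_calibration(report)
```

## The simulation framework

`scenario_config()` defines a confounded longitudinal generator emulating
the canonical time-dependent-confounding graph:

* $P \sim U(0,1)$: baseline prognostic variable (affects the hazard, not
  treatment);
* $L_0 \sim TN(0, 1)$ truncated to $[-2, 2]$; $L_k \sim TN(\rho L_{k-1} +
  \theta_A A_{k-1}, 0.6)$ with $\rho = 0.8$ and $\theta_A = -0.5$:
  a sticky severity marker that treatment pushes down;
* treatment initiation $\Pr(A_k = 1 \mid A_{k-1} = 0) =
  \mathrm{expit}(-1.7 + 0.8 L_k)$, absorbing by default — about half the
  subjects initiate by the horizon, and sicker ones initiate sooner (the
  confounding);
* hazard, constant on each interval $[k, k+1)$: additive family
  $h = 0.12 + 0.035 L_k - 0.04 A_k + 0.08 P$ (positive over the whole
  covariate support — the truncation of $L$ guarantees this, and the
  constructor refuses coefficient sets that violate it), or a log-linear
  proportional-hazards family;
* six visits ($k = 0..5$), administrative censoring at $t = 6$, horizon
  $\tau = 5$; optional exponential loss-to-follow-up via `censoring_rate`
  (off by default, so standard censoring plays no role before $\tau$ unless
  requested);
* event times by exact inverse-CDF sampling of the piecewise-exponential
  cumulative hazard.

These values were chosen once as a realistic regime — event risk around
50% by $\tau$, material confounding so the subset approach is visibly
biased at $n = 1000$ — and every coefficient is configurable. All
randomness is drawn up front from a single seed, and the truncated-normal
innovations use inverse-CDF sampling, so `simulate_perfect()` with the same
seed produces each subject's **counterfactual twin** under a forced
strategy from identical draws: a subject who happens to follow the strategy
in the observational data has *exactly* the event time of their twin.
Consistency therefore holds by construction, and the perfect datasets give
the ground-truth performance that the counterfactual estimators are
compared against.

What the generator does *not* emulate: irregular visit schedules,
covariate-dependent loss to follow-up, measurement error in $L_k$ beyond
the scenario-3 baseline error, competing risks, non-absorbing treatment
(supported in the generator, but the bundled development model requires
absorbing treatment). Passing tests therefore demonstrate correctness of
the estimators under the stated assumptions, not robustness to everything
real data can do.

### The development model

`develop_model()` is deliberately simple plumbing for the simulation study:
a marginal structural hazard model fitted with stabilized
inverse-probability-of-treatment weights, one hazard fit per visit interval
(additive fits are small convex maximum-likelihood problems solved with
`nlminb`, since an identity-link hazard is not a GLM family; proportional
fits are weighted Poisson regressions). The linear predictor uses baseline
$\{L_0, P\}$, current treatment **and treatment duration** — without the
duration term, always-treated risks are systematically overpredicted
because sustained treatment keeps lowering the confounder path. Predictions
integrate the fitted hazard along the fixed treatment sequence. We verified
the predictions against Monte-Carlo ground truth
(`true_counterfactual_risk()`) at reference covariate points.

The development sample defaults to $n_{dev} = 5000$ while validation uses
$n_{val} = 1000$: with a small development sample the developed model is
itself a few percent miscalibrated in the mean (prediction noise passes
through the concave $1 - e^{-H}$ transform), which is a property of the
model, not of the validation estimators — both the perfect-data and
counterfactual evaluations agree on it. A larger development sample keeps
scenario 1 a clean test of estimator unbiasedness.

### Scenarios

1. development = validation: estimators should be unbiased and the
   calibration curve on the diagonal;
2. development baseline hazard 1.5× the validation one: O/E below one,
   calibration below the diagonal, negative scaled Brier scores;
3. predictions computed from an error-prone $L_0$ (additive Gaussian error,
   SD 1): lower c-index/AUC, risks too extreme (bottom decile observed
   above predicted, top decile below), mean calibration intact;
* `exch` (hidden binary confounder in treatment and hazard), `pos`
  (treatment model steepened threefold, squeezing adherence probabilities
  toward 0/1) and `wmisspec` (the confounder omitted from the fitted
  weight model) deliberately violate the identification assumptions; they
  produce visible bias in the counterfactual estimates. The violations are
  applied to the validation process only, so the bias is attributable to
  the validation method rather than to degraded predictions.

```{r}
res <- run_scenario("1", reps = 100, scenario_config(), seed = 1)
res$summary
```

## Numerical choices and conventions

* Weighted KM ties: events before censorings at the same time (standard);
  the weight used at an event time $t$ is the step-function value at
  $\lfloor t \rfloor$, matching the index range of the weight product.
* Calibration KM uses $G_a^{-1}$ only by default — covariate-free standard
  censoring is handled natively by the KM risk sets — with
  `component = "combined"` exposed as a switch.
* The pair-weight evaluation past a subject's last recorded visit carries
  the last value forward (no further treatment decisions can occur there).
* Weight truncation (`truncation` percentile) is available but off by
  default: the estimators are defined with unstabilized, untruncated
  weights.
* Fitted adherence probabilities below `prob_floor` (default 0.01) trigger
  a positivity warning naming subjects; probabilities are never modified.
* Degenerate situations abort with explicit messages rather than returning
  NaN: no comparable pairs (the extended positivity condition), no cases or
  no controls at $t$, a zero null-model Brier score, a zero mean predicted
  risk.
* Missing covariate values are rejected outright; the weight models need
  complete histories and silent imputation would be worse than an error.

## Problem sizes used in the bundled checks

The test suite runs scenarios 1–3 at 100 replicates and the violation grid
at 50 replicates, with $n_{val} = 1000$; `scripts/acceptance.R` recomputes
the same quantities at 50/25 replicates. Monte-Carlo standard errors at
these sizes are roughly 0.002–0.005 for the discrimination measures, which
is why the unbiasedness checks use a tolerance of 0.01 (0.02 for the scaled
Brier score, whose replicate distribution is noticeably wider).

## Known limitations

* Static deterministic strategies only; dynamic regimes and grace periods
  are out of scope (strict adherence from visit 0 — for "always treated"
  this means treatment must start exactly at visit 0, a user-visible
  choice).
* Covariate-dependent standard censoring is not supported.
* No confidence intervals; bootstrap internal validation is future work.
* The development-model helper requires absorbing treatment; it exists to
  exercise the validation machinery, not as a general MSM fitter.
* Visits must sit on the integer grid; real data must be discretized first.
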