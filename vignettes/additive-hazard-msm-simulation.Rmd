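---
title: "Simulating from additive-hazard marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating from additive-hazard marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmsim)
```

## The problem

Longitudinal observational data on a time-varying treatment, time-varying
covariates and a time-to-event outcome are subject to *time-dependent
confounding*: a covariate (say a biomarker) predicts who gets treated next,
is itself affected by earlier treatment, and affects survival. Standard
regression adjustment fails here, and the usual remedy is a marginal
structural model (MSM) for the counterfactual hazard under an assigned
treatment regime, fitted with inverse-probability-of-treatment weights
(IPTW).

Evaluating such methods by simulation requires generating data so that the
*correct form of the MSM is known*. That is not trivial: data are naturally
generated sequentially from *conditional* models, while the MSM is a
*marginal* model, and marginalizing a hazard model changes its form. The key
property this package exploits is the collapsibility of the additive (Aalen)
hazard model: when the conditional hazard given treatment history
$\bar A$, confounder history $\bar L$ and an individual frailty $U$ is
additive,
$$\lambda(t \mid \bar A_{\lfloor t\rfloor}, \bar L_{\lfloor t\rfloor}, U) =
  \alpha_0(t) + \alpha_A(t) A_{\lfloor t\rfloor}
  + \alpha_L(t) L_{\lfloor t\rfloor} + \alpha_U(t) U,$$
the implied MSM is additive too,
$$\lambda_{T^{\bar a}}(t) = \tilde\alpha_0(t)
  + \sum_{j=0}^{\lfloor t\rfloor} \tilde\alpha_{Aj}(t)\, a_{\lfloor t\rfloor - j},$$
with main effects of the whole treatment history: even though the
conditional hazard depends only on *current* treatment, earlier treatments
act on the marginal hazard through the covariate path, so lagged terms
appear after marginalization. On $0 < t < 1$ the lag-0 coefficient equals
the conditional one ($\tilde\alpha_{A0} = \alpha_A$); at later times all
coefficients differ from their conditional counterparts. A conditional Cox
model, by contrast, does *not* imply a marginal Cox model — the marginal log
hazard ratio becomes a time-varying function (frailty attenuation), which
the package's Cox oracle demonstrates numerically.

## The reference generator

Visits are at $k = 0, \dots, K$ with $K = 4$ and administrative censoring at
$K + 1 = 5$; event times are continuous. Per person:

1. frailty $U \sim N(0, 0.1^2)$ — an unmeasured individual effect on the
   biomarker and the hazard, deliberately *not* a confounder (it never
   enters treatment assignment);
2. $L_0 \sim N(U, 1)$;
3. $A_k \sim \text{Bernoulli}(\text{expit}(-2 + 0.5 L_k + A_{k-1}))$ —
   higher biomarker and previous treatment raise the propensity;
4. events on $[k, k+1)$ from the conditional hazard
   $0.7 - 0.2 A_k + 0.05 L_k + 0.05 U$ by inverse transform
   ($T^* = -\log V / \lambda$, event iff $T^* < 1$, strictly);
5. for survivors, $L_k \sim N(0.8 L_{k-1} - A_{k-1} + 0.1 k + U, 1)$ —
   the biomarker drifts upward with time and frailty and is lowered by
   treatment.

All constants are exposed through `additive_hazard_spec()`,
`covariate_process_spec()` and `treatment_model_spec()` and were fixed once
as the package's reference conditions. Hazard coefficients may be
`piecewise_constant()` functions, in which case event times come from the
piecewise-exponential inverse transform (`draw_event_time_piecewise()`).

Numerical conventions worth stating explicitly:

* **Negative hazards** (possible under any additive model with continuous
  covariates) are floored at zero at evaluation time; the number of floored
  evaluations is recorded on the returned panel. At the reference
  parameters flooring is a measure-zero event in practice.
* **Interval boundary**: a drawn $T^*$ exactly equal to the interval length
  counts as surviving the interval (strict inequality).
* **Random-number discipline**: one master seed spawns named substreams
  (frailty, covariate, treatment, event, censoring), so switching one model
  component off does not shift the draws of the others; the test suite
  relies on this coupling.

## Weights and estimation

Stabilized weights $SW_k = \prod_{j \le k} p^{num}_j / p^{den}_j$ use pooled
logistic regressions for the probability of the *observed* treatment: the
numerator conditions on previous treatment only, the denominator adds the
current confounder. At visit 0 no previous treatment exists, so the
numerator is intercept-only and the denominator uses $L_0$ alone — the
natural degeneration of the printed model forms, and the choice this
package documents as its convention. One pooled fit covers visits
$1, \dots, K$ (common coefficients across visits) plus a separate pair at
visit 0. Weights are constant within each interval $[k, k+1)$, including
the event subinterval, and are not truncated (an explicit design choice:
the reference analysis uses untruncated stabilized weights; truncation
would bias a correctly specified analysis).

The weighted additive MSM is fitted by least-squares increments: at each
distinct event time,
$\Delta\hat B = (X^\top W X)^{-1} X^\top W\, dN$
over the at-risk set (left-limit convention, $t_{start} < t_e \le t_{stop}$),
cumulated into right-continuous step functions. Right continuity at event
times is the package's convention for evaluating cumulative coefficients at
integer times. The history-form fit runs interval by interval with design
dimension $k + 2$ on $[k, k+1)$, since lag-$j$ terms do not exist before
visit $j$; lag-$j$ cumulative coefficients are structurally zero on
$[0, j]$. Ties in event times (possible only through floating-point
coincidence) are processed as a single time with a multi-event $dN$, with
rows ordered by person id for reproducibility. A singular $X^\top W X$ at
some event time — possible late in follow-up when few treatment histories
remain at risk — falls back to the Moore–Penrose pseudo-inverse with a
warning by default; a strict mode turns it into an error.

Counterfactual survival follows from the cumulative coefficients as
$\hat S^{\bar a}(t) = \exp\{-\hat B_0(t) - \int_0^t g(\bar a; d\hat B_A)\}$.
Additive fits can yield $\hat S > 1$; values are reported as computed, with
an optional clamp for presentation only. Variance estimation for the
increments is deliberately out of scope: precision is summarized
empirically across study replications.

## Two independent routes to the truth

True MSM parameter values are not available in closed form (the
marginalization integrals are intractable), so the package computes them
two ways and cross-checks:

* **Intervention trials** (`compute_truth()`): replicate randomized trials
  with $m = 1000$ persons assigned to each of the $2^{K+1} = 32$ regimes,
  analysed with the *unweighted* history-form MSM. Within a replicate the
  baseline draws — the frailty and the realized $L_0$ — are shared across
  regime arms, while post-baseline confounder innovations and event draws
  are fresh per arm (sharing those too would leave the pooled fit with only
  $m$ independent event histories instead of $32m$ and inflate the truth's
  Monte-Carlo error several-fold). The reference description of this
  construction shares $L_0$ across arms but is silent about $U$; since
  $L_0$'s mean *is* $U$, sharing realized $L_0$ without $U$ would be
  ill-defined, and the package shares both — documented here as its
  interpretation. Survival proportions computed directly from the trial
  arms are reported alongside as a cross-check.
* **Monte-Carlo g-formula oracle** (`marginal_survival_mc()`,
  `marginal_hazard_mc()`, `implied_additive_msm()`): simulate covariate
  paths under the regime, evaluate the conditional hazard analytically on
  each path (no event simulation), and average the interval survival
  products $Q(t) = \prod_j e^{-\lambda_j \Delta_j}$. Hazards are floored at
  zero inside $Q$ exactly as in the simulator, so both routes target the
  same law. Marginal hazards use the ratio estimator
  $\sum_i \lambda_i Q_i / \sum_i Q_i$.

An *additivity diagnostic* accompanies the implied MSM: the maximum
absolute two-way interaction contrast of $-\log S$ across single-visit
regime pairs. Whether the implied MSM is exactly additive in treatment
history at lags $\ge 2$ is not assumed; the diagnostic measures it. A
finding from this package's own analysis: with the linear AR(1) confounder
process and no flooring, the treatment-dependent part of each path's
cumulative hazard is deterministic given the noise stream, so the implied
MSM is *exactly* additive here — the diagnostic vanishes to machine
precision under common random numbers (and its influence-function SE
degenerates with it). Nonlinear covariate processes or non-negligible
flooring would break this exactness, which is why the diagnostic is
computed rather than asserted.

## Study harness and problem sizes

`run_simulation_study()` chains the full pipeline — simulate, fit weight
models, weight, expand to counting-process form, weighted Aalen fit,
survival transform — across replicates, catching and counting (not
propagating) replicate-level failures, and summarizes bias, empirical SE
(SD across replicates) and Monte-Carlo SE of the bias (empirical SE
$/\sqrt{R}$) against a supplied truth table. With a single replicate the
SEs are reported as missing and the bias is still computed.

The package's own validation runs use $R = 200$ replicates for the truth
(the estimand grid $t \in \{1, \dots, 5\}$, $m = 1000 \times 32$ arms,
about six minutes on one core) and $R = 200$ replicates of $n = 5000$ for
the estimator study (about two minutes); the test suite uses smaller sizes
for the property checks. These sizes were chosen so that Monte-Carlo SEs
on the truth are below 0.005 for every estimand, and all empirical results
quoted anywhere in the documentation are produced by the shipped tests and
the acceptance script at exactly these sizes.

## What the generator does and does not emulate

The generator captures the canonical time-dependent confounding structure:
confounder-driven treatment, treatment-responsive confounder, frailty-driven
heterogeneity, continuous event times with interval-constant hazards, and
administrative censoring (plus optional covariate-dependent random
censoring with inverse-probability-of-censoring weights). It does *not*
emulate irregular or per-person visit schedules, multiple confounder
processes (supported structurally, but no defaults are provided),
continuous treatments, competing risks, or measurement error. Passing tests
therefore demonstrate correctness of the estimation machinery under regular
visits and correctly specified models — not robustness to the
irregularities of, say, electronic health records.

## Known limitations

* The Cox MSM (weighted partial-likelihood fitting) is intentionally not
  implemented; `msm_design("cox")` fails loudly. The Cox *generator* and
  its marginal oracle exist precisely to show why that MSM would be
  misspecified.
* Aalen increment variances are not estimated analytically.
* Positivity is assumed, not enforced: extreme propensities surface as
  large weights (logged), and zero denominators raise positivity errors.
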