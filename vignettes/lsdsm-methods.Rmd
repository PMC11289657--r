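---
title: "Methods: joint state-space modelling of longitudinal and survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint state-space modelling of longitudinal and survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsdsm)
```

## The model

`lsdsm` implements a joint model in which a discrete-time linear-Gaussian
state space model tracks the *true* (noise-free) biomarker values of each
patient, and a proportional-hazards model driven by the hidden states governs
the time-to-event process:

$$
x_{i,j+1} = A x_{i,j} + w_{i,j}, \qquad
y_{i,j} = C x_{i,j} + v_{i,j},
$$
$$
h_i(t_{i,j}) = \exp\{\gamma^\top \omega_i + \alpha^\top H x_{i,j}\},
\qquad
S_i(t) = \exp\Big\{-\int_0^{t} h_i(s)\,ds\Big\},
$$

with disturbances $w_{i,j} \sim N(0, W)$, measurement errors
$v_{i,j} \sim N(0, V)$, baseline covariates $\omega_i$, and an analyst-chosen
association matrix $H$ (default: the current biomarker value).

The latent process is an AR($M$) model in *canonical form*: with $m_y$
biomarkers the state stacks the current and $M-1$ lagged true biomarker
vectors ($m_x = M\,m_y$), the observation matrix is fixed at $C = [I\;0]$,
the transition matrix is the companion form $A = [\bar A;\, I\;0]$ with only
its top block free, and the disturbance loads only on the leading block,
$W = G \breve W G^\top$ with $G = [I\;0]^\top$. These constraints make the
parameterization identifiable; the estimable parameters are
$\theta = \{\bar x_1, \bar W_1, \bar A, \breve W, V, \gamma, \alpha\}$.

Four assumptions shape the estimation: (A.1) the latent process is Markov;
(A.2) longitudinal and survival data are conditionally independent given the
states; (A.3) visit times and censoring are non-informative; and (A.4) the
state is constant within a grid interval, so the survival function becomes
piecewise exponential with per-interval exposures $\tau_{i,j}$ and at most
one interval event indicator $\bar\delta_{i,j} = 1$.

## Discretization

Irregular visit times are binned on a regular grid with step `dt` (a
modelling hyperparameter; in the motivating application six months, chosen
to match the median visit interval so that roughly half the grid cells carry
data). Interval $j$ covers $[(j-1)\Delta t, j\Delta t)$, an observation at
time $t$ belongs to interval $\lfloor t/\Delta t \rfloor + 1$, multiple
observations in one interval are averaged (configurable to first-only), and
empty intervals are missing data, not dropped rows. A patient with
event/censoring time $T$ contributes $m = \lceil T/\Delta t\rceil$ intervals
with exposures $\tau_j = \Delta t$ for $j < m$ and
$\tau_m = T - (m-1)\Delta t$, so that $\sum_j \tau_j = T$ exactly. (The
source material prints the last exposure as $T - m\Delta t$, which is
negative under $m = \lceil T/\Delta t \rceil$; we use the conservation-of-
follow-up form.) If $T$ falls exactly on a grid point no zero-length interval
is created, and an event is always attributed to interval $m$.

## Estimation

The observed-data likelihood integrates the latent paths out of the product
of the survival, measurement and transition densities. Maximization uses an
EM algorithm whose E-step requires the posterior moments of the states given
*both* the longitudinal record and the survival information.

**Survival-corrected filtering.** The forward pass is a Kalman filter whose
per-interval correction multiplies the Gaussian measurement likelihood of
the observed biomarker components by the interval survival factor
$\exp\{\bar\delta_j(\gamma^\top\omega + \alpha^\top H x) -
\tau_j e^{\gamma^\top\omega + \alpha^\top H x}\}$. The corrected posterior is
approximated as a Gaussian at its mode (found by damped Newton-Raphson
started from the exactly-conditioned Gaussian mean) with covariance the
inverse negative Hessian — a Laplace approximation. When $\alpha = 0$, or an
interval has no exposure and no event, the update *is* the exact Kalman
update; the test suite asserts this to $10^{-10}$ and checks the 1-D mode
and curvature against an independent quadrature oracle to $10^{-6}$.

**Smoothing.** The backward pass is an unmodified Rauch-Tung-Striebel
recursion on the survival-corrected filtered/predicted beliefs; the smoother
gain is computed from the survival-corrected predicted covariances (required
for internal consistency; the source leaves this implicit). Lag-one
cross-covariances $\hat\Sigma_j J_{j-1}^\top$ feed the transition
expectations. Missing measurement components are handled by the standard
conditional-Gaussian correction operator
$\nabla = I - V\,\Omega^{(O)\top}(V^{(O,O)})^{-1}\Omega^{(O)}$, which
vanishes on fully observed steps.

**M-step.** The state-space parameters have closed-form updates (the initial
moments from the first-step smoothed moments; the free transition block as a
generalized regression of the leading "starred" states on the lagged full
state; the disturbance and measurement covariances from the corresponding
residual expectations, each using the freshly updated mean parameter). The
hazard coefficients maximize

$$
f(\gamma, \alpha) = \sum_{i,j} \bar\delta_{i,j}(\gamma^\top\omega_i +
\alpha^\top H\hat\mu_{i,j}) - \tau_{i,j}\, e^{\gamma^\top\omega_i}\,
\exp\{\alpha^\top H \hat\mu_{i,j} + \tfrac12 \alpha^\top H \hat\Sigma_{i,j}
H^\top \alpha\}
$$

by damped Newton-Raphson with analytic gradient and Hessian (verified
against finite differences to $10^{-5}$ relative in the tests); the
expectation of the exponential hazard term is the Gaussian
moment-generating-function formula, exact for the Gaussian posterior
approximation. EM stops when the maximum absolute elementwise change across
all parameter arrays drops below `tol` (default $5\times10^{-4}$), with a cap
of 600 iterations.

### Initialization and the flat ridge

The originating procedure does not state its initialization. This matters
more than usual here: the EM surface for noisy AR(2) dynamics has an
extremely flat ridge along which the persistence is split between the two
transition coefficients and between disturbance and measurement variance.
Runs started far from the optimum crawl along this ridge for hundreds of
iterations, and — because the survival coefficients equilibrate against the
current smoothed states — the elementwise stopping rule can fire at ridge
points with visibly inflated hazard coefficients. Runs started at the
generating values converge in a few tens of iterations, the iteration counts
the original simulation study reports. Consequently:

* `initialize_params()` (the default for real data) anchors the initial
  state moments at the first observed measurements, starts the transition
  block at a pooled least-squares AR regression on complete lag windows
  (shrunk to spectral radius $<1$; a stable persistence form 0.9/0.05 is the
  fallback), splits the pooled variance of first differences evenly between
  $\breve W$ and $V$, and zeroes the hazard coefficients.
* `sim_study()` — the parameter-recovery driver, where the generating values
  are known by construction — initializes at those values (`init = "truth"`,
  switchable to `"default"`), reproducing the published convergence
  behaviour.

Degenerate inputs are guarded rather than silently absorbed: cohorts with no
events leave the hazard coefficients at their starting values with a
warning; diverging survival coefficients (|coef| > 50) stop the inner search
with a warning; numerically non-positive-definite matrices receive an
escalating diagonal jitter ($10^{-8}$ up to $10^{-2}$) before failing; the
log-hazard is clipped at $\pm 50$ (with a warning) so transient extreme
Newton proposals cannot overflow.

## Dynamic prediction

`predict_survival()` computes the conditional survival of one patient from a
landmark $t_s$ (a grid multiple of `dt`; off-grid landmarks are floored with
a warning) to a horizon $t_h$. The recursion starts from the
survival-corrected *filtered* belief at the landmark and repeats, per future
interval: (1) a time update; (2) a Laplace re-approximation of the state
given survival of the interval (the filter correction with the measurement
term absent); (3) accumulation of the one-step conditional survival
increment. The increment integral
$\int N(x;\mu_p,P_p)\, e^{-\tau c\, e^{a^\top x}}dx$ is itself approximated
by the Laplace normalizing constant
$e^{\phi(\hat x)} / \sqrt{1 + \tau c\, e^{a^\top \hat x} a^\top P_p a}$,
which is exact when $\alpha = 0$ and reduces the curve to the constant-hazard
closed form. The tests compare the whole recursion against a forward-
sampling Monte-Carlo oracle (sampling latent futures and averaging their
piecewise-exponential survival) within three Monte-Carlo standard errors,
and check that chaining two shorter predictions through the carried belief
reproduces a single long one.

## The simulator: a stated world

`simulate_cohort()` reproduces the simulation study's generating process,
with defaults that *are* that study's stated conditions, not tuning knobs:
a single biomarker followed by an AR(2) latent process with
$\bar A = [1.46, -0.48]$, $\breve W = 0.04$ (sd 0.2), $V = 0.25$ (sd 0.5),
initial state $N((10,10)^\top, I)$; hazard intercept $2.5$, one
standard-normal baseline covariate with coefficient $-0.75$, current-value
association $\alpha = -1.25$; event times by Walke's inverse-transform
sampler on the piecewise-exponential survival of the latent path; censoring
$\min(30, U(10,50))$ (ties event/censoring resolved as censored);
missingness removes longitudinal measurements independently with the
configured probability and never touches outcomes. Separate named RNG
substreams drive initial states, disturbances, measurement errors, event
uniforms, censoring, and missingness, so varying one component leaves the
others bit-identical under the same seed.

What the simulator does *not* emulate: informative visiting or censoring
(assumption A.3 holds by construction), multi-biomarker presets, covariate
effects on the longitudinal process, or heterogeneity in the dynamics across
patients beyond the disturbance term. A green simulation test therefore
establishes correctness of the inference machinery *under the model's own
assumptions*, not robustness to their violation.

## Evaluation metrics

The landmark/horizon metrics follow the standard
inverse-probability-of-censoring-weighted cumulative/dynamic definitions
(the source defers its exact formulas to supplementary material, so this is
a documented interpretation): censoring weights come from a Kaplan-Meier
estimate of the censoring distribution on the at-risk set, cases weigh
$1/\hat G(T_i^-)$, controls $1/\hat G(t_h)$, tied risk scores count one
half, and the risk score is one minus the predicted conditional survival at
the horizon. Tracking error is summarized by RMSE pooled over all
patient-time points (a per-patient-first variant is exposed via
`pool = "patients"`); the published tracking table corresponds to *online*
(filtered) tracking with the expected-hazard (Gaussian-moment) survival
curve, which is what `track_cohort()` computes by default — smoothed
tracking, which is genuinely more accurate in reconstruction error, is
available as an option.

## Known limitations

* The Gaussian (Laplace) posterior approximation is least accurate for
  unobserved event intervals, where the true posterior is skewed; the test
  suite quantifies this on 1-D cases.
* A constant baseline hazard is assumed; time variation enters only through
  the states.
* A single population dynamics matrix is shared by all patients;
  individualization comes from the disturbances and the per-patient filter.
* `dt` is global and constant; left truncation and competing risks are out
  of scope.
* EM convergence is declared on parameter change, not on the (intractable)
  observed likelihood; with the documented flat ridge, remote starts can
  stop at visibly different points — the initialization policy above is part
  of the method.
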