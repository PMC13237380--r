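---
title: "Modelling the learned value of safety in active avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the learned value of safety in active avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safeval)
```

## The scientific problem

In two-way active avoidance (2AA), an animal learns that shuttling to the
opposite chamber during a warning signal (WS) both terminates the signal
and prevents the footshock. The moment of successful avoidance — WS offset
after a timely shuttle — defines an *action-derived safety* state, and the
behavioural and neural analyses this package implements all revolve around
one question: how much motivational value does that safety state acquire
over training, and how is it encoded?

`safeval` provides the complete analysis chain for such experiments:

* a Rescorla–Wagner model of the avoidance-probability curve with
  group-level least-squares fitting,
* subject-level bootstrap standard errors and label-permutation tests on
  fitted parameters,
* a hierarchical Bayesian individual-subject model with split-R-hat
  diagnostics and parameter-recovery auditing,
* the fiber-photometry processing chain (isosbestic detrending, dF/F,
  peri-event alignment, baseline z-scoring, trapezoid AUC, dual-sensor
  peak offsets),
* behavioural metrics (avoidance rate, progressive-ratio breakpoint) and
  ex vivo EPSC scalar metrics,
* and synthetic-data generators so every stage can be validated against
  known ground truth without any animal data.

## The avoidance-learning model

The latent probability of avoidance evolves across trials as

$$p_a(t+1) = p_a(t) + \alpha\,\bigl(\beta - p_a(t)\bigr), \qquad p_a(1) = V_1,$$

where $\alpha \in [0,1]$ is the learning rate, $\beta \in [0,1]$ the
asymptotic *value of safety*, and $V_1$ the initial avoidance probability.
Two properties of this update matter for everything downstream:

1. **It is outcome-free.** The recursion contains no outcome term, so the
   trajectory is deterministic given $(\alpha, \beta, V_1)$ and has the
   closed form $p_a(t) = \beta + (V_1-\beta)(1-\alpha)^{t-1}$
   (`rw_closed_form()`), which the package tests against the iteration to
   $10^{-12}$. A sensitivity variant that updates only after avoidance
   trials is available (`simulate_agent(outcome_feedback = TRUE)`) but off
   by default.
2. **Outcomes are generated through a softmax.** Simulated trial outcomes
   are Bernoulli with
   $P(\text{avoid}) = \mathrm{logistic}\!\bigl(\tau\,(2p_a - 1)\bigr)$,
   the two-option softmax over action values $(p_a, 1-p_a)$ with inverse
   temperature $\tau = 0.8$ by default. This is the simplest two-action
   reading of a softmax outcome rule; the mapping is centred so that
   $p_a = 0.5$ always yields a fair coin.

### What the least-squares fit estimates

`fit_group()` fits $(\alpha, \beta, V_1)$ to the empirical per-trial mean
avoidance curve of a group by least squares, comparing the *raw* latent
trajectory to the empirical mean (no link function) — the curve being fit
is itself a probability. Sessions are concatenated into a single trial
axis, matching how group learning curves are displayed.

One consequence deserves emphasis. When outcomes pass through the softmax
link, the expected empirical curve is
$q(t) = \mathrm{logistic}(\tau(2p_a(t)-1))$, not $p_a(t)$, so the fit is
consistent for the *link-distorted projection* of the generating
parameters: for $\beta = 0.8$, $\tau = 0.8$ the asymptote of $q$ is
$\mathrm{logistic}(0.48) \approx 0.62$. Recovery tests therefore use the
fit to the exact softmax-mapped trajectory as the estimand; with the link
disabled (`link = "identity"` in `simulate_agent()`), the fit recovers the
raw parameters and that invariant is tested separately. On real data no
such subtlety arises — the model is simply a three-parameter description
of the observed curve.

The optimiser is multi-start: SSE is evaluated on a $5^3$ grid of starts
over $\{0.05,\dots,0.95\}^3$, the best three starts are refined by
Nelder–Mead simplex search on the logit scale (which confines parameters
to the unit cube without constraint handling), with small-step polish
restarts; ties are broken by lowest SSE, then smallest $\alpha$. A flat
fitted trajectory ($|\hat\beta - \hat V_1| < 10^{-4}$) makes $\alpha$
unidentifiable and is flagged rather than silently reported.

### Resampling inference

Within-group uncertainty uses an ordinary nonparametric bootstrap at the
**subject** level (resample subjects with replacement, rebuild the mean
curve, refit; 1000 draws at full scale): the group curve is a subject
mean, so the subject is the exchangeable unit. Between-group differences
use a label-permutation test: subjects are pooled and reassigned to groups
preserving group sizes, both groups are refit, and the two-sided p-value
is $(1 + \#\{|\Delta_\text{perm}| \ge |\Delta_\text{obs}|\})/(1 +
n_\text{perm})$ — the $+1$ correction keeps p-values away from zero at
finite $n_\text{perm}$ (5000 at full scale). The permutation statistic is
computed for all three parameters; the learning-rate and safety-value
contrasts are the focal ones in this experimental design.

```{r fit-example}
sched <- make_schedule("standard_2aa", sessions = 5, seed = 7)
cohort <- simulate_cohort(cohort_spec(
  groups = list(control = list(n = 8, params = agent_params(0.3, 0.8, 0.1))),
  schedule = sched, seed = 42))
fit <- fit_group(empirical_group_curve(cohort, "control"))
tidy(fit)
```

## The hierarchical Bayesian model

Individual-subject fitting uses, for subject $i$ in group $g$:

$$y_{it} \sim \mathrm{Bernoulli}(p_{it}), \qquad
\mathrm{logit}(\theta_{ik}) = z_{ik} \sim \mathcal N(\mu_{gk}, \sigma_{gk}),$$
$$\mu_{gk} \sim \mathcal N(0, 1.5), \qquad \sigma_{gk} \sim
\text{half-}\mathcal N(1),$$

with $\theta_i = (\alpha_i, \beta_i, V_{1i})$ and $p_{it}$ the
Rescorla–Wagner trajectory. The likelihood uses the latent probability
directly — the model's state *is* the probability of avoidance — with a
softmax-link variant available for sensitivity analysis. The priors are a
deliberately weakly-informative stand-in with full support on $(0,1)$
after the logit transform; they are the package's own choice and no
equivalence to any particular prior used elsewhere is claimed.

### The sampler

`sample_posterior()` runs an adaptive Metropolis-within-Gibbs scheme of
the package's own construction:

* component-wise random-walk Metropolis on each subject's logit-scale
  parameters during early warmup, with proposal scales adapted toward a
  0.44 acceptance rate;
* from 30% of warmup onward, **joint** per-subject proposals using the
  Cholesky factor of the empirical covariance of the chain history —
  $\alpha$ and $V_1$ are strongly correlated (they trade off in shaping
  the early curve), so component-wise proposals mix poorly. One proposal
  in ten is scaled up fivefold, a mixture that reaches the heavy tails of
  ridge-shaped subject posteriors (when $\alpha$ is small, $\beta$ is
  pinned only from below);
* conjugate Gibbs updates for each group-level location $\mu_{gk}$ and
  log-scale Metropolis updates for $\sigma_{gk}$;
* an interweaved non-centred move (ancillarity–sufficiency interweaving):
  holding the standardised effects $(z - \mu)/\sigma$ fixed, $(\mu, \log
  \sigma)$ are proposed jointly and the subject parameters dragged along.
  This breaks the funnel geometry that stalls centred updates when a
  parameter (typically $\alpha$) is weakly identified by binary data.

Each stored iteration performs `sweeps` (default 16) rounds of the full
update cycle — the counterpart of a Hamiltonian sampler's internal steps
per iteration. Chains are run sequentially with seeds derived from one
master seed, so every run is bit-reproducible. Default desk-scale
settings are 4 chains × 2000 iterations with 1000 warmup; full-scale
settings (4 × 20000/10000) are a parameter change.

Convergence is assessed with split-half $\widehat R$ (`split_rhat()`),
computed exactly as: halve each chain, $W$ = mean within-half variance,
$B = n \cdot \mathrm{Var}(\text{half means})$,
$\widehat R = \sqrt{((n-1)/n\,W + B/n)/W}$. Any parameter with
$\widehat R \ge 1.01$ flags the run; the pipeline marks such bundles
non-converged. Effective sample sizes use Geyer's initial-positive-
sequence estimator on split chains.

### Validation strategy

Three independent oracles check the sampler: prior-only runs against the
analytic prior pushforward; a one-subject toy (with $\alpha$ fixed)
against dense 2-D grid quadrature; and simulate–refit parameter recovery
(`parameter_recovery()`), which reports 95% credible-interval coverage
and the truth-vs-posterior-mean rank correlation per parameter. Recovery
simulates outcomes directly from the latent probability (the model's own
likelihood), because recovery is an audit of the inference machinery, not
of the outcome link. With 150 binary trials per subject, $\beta$ is well
recovered (rank correlation typically > 0.9); $\alpha$ and $V_1$ are only
weakly identified at this scale, which the wide credible intervals report
honestly.

## The photometry chain

The processing conventions, stated once and used everywhere: half-open
windows $[t-\text{pre}, t+\text{post})$, nearest-sample event snapping,
1-based trial indices, 0-based sample indices within a window.

1. **Isosbestic detrending.** The signal channel (473 nm) is regressed on
   the isosbestic channel (405 nm) by ordinary least squares over the
   *entire session* (a per-trial option exists), giving
   $F_\text{fitted405} = a F_{405} + b$.
2. **dF/F** $= (F_{473} - F_\text{fitted405}) / F_\text{fitted405}$,
   pointwise. The computation errors (with sample indices) if the fitted
   control crosses zero. dF/F is invariant to joint positive rescaling of
   both channels and identically zero for artifact-only sessions.
3. **Alignment** to named events with window length
   $\mathrm{round}(\text{rate} \cdot (\text{pre}+\text{post}))$ samples;
   events with incomplete coverage are excluded *and reported*.
4. **Baseline z-scoring** per trial against the 5 s pre-event segment
   $[-5, 0)$; zero-SD trials are excluded and counted.
5. **Trapezoid AUC** over configurable pre/post windows (defaults
   $[-5,0)$ and $[0,5)$ — post-event window lengths vary between
   experimental figures, so they are configurable per event), in z·s.
6. **Subject averaging**: trials are averaged within subject first, then
   across subjects (unweighted), so trial counts do not weight subjects.
7. **Peak offsets** between two sensors (e.g. acetylcholine vs dopamine):
   per-trial global maximum within the post-event search window; maxima
   on the window boundary are rejected as "no peak" since the question
   being asked (which transient comes first) is meaningless without an
   interior peak. Trial-averaged offsets are available by averaging the
   per-trial table.

A red-sensor channel (560 nm) is processed identically against the same
405 nm reference.

## The synthetic-data generators

`make_schedule()` reproduces the task protocols: standard 2AA (30 WS of
up to 15 s per session, 0.6 mA footshock up to 7 s on failure, ITI
uniform 30–40 s, 5 sessions), extinction with and without response
prevention, the probabilistic surprise-omission session (20-trial
reliable baseline, then exactly five surprise omissions separated by
5–10 intervening trials), head-fixed avoidance (50 trials/session, WS up
to 10 s, air puff up to 5 s), and the progressive-ratio test (25 cm
starting requirement, 5 cm increments after two consecutive successes,
breakpoint = longest distance achieved).

`simulate_agent()`/`simulate_cohort()` generate trial records with known
$(\alpha, \beta, V_1, \tau)$; avoid-trial latencies are drawn from an
exponential truncated to $(0, \text{WS}_\max)$ — a modelling convenience
(real avoid-latency distributions are not described by the task
definition), used only for latency-sorted displays. Escape trials take
the full WS duration and have no shuttle/safety timestamps.

`generate_photometry()` builds two-channel sessions at 20 Hz (we emulate
demodulated signals; hardware modulation frequencies are out of scope):
the 405 channel carries baseline × exponential bleach, shared brief
motion artifacts, and white noise; the 473 channel is an affine image of
the systematic 405 component (coefficients recorded as ground truth) plus
event-locked double-exponential transients scaled so their downstream
dF/F peak equals the specified amplitude, plus independent noise.

What the generators deliberately do **not** emulate: slow hemodynamic or
pH drifts, sensor nonlinearity, correlated (non-white) noise, latency-
dependent behavioural confounds, or any outcome feedback into the
learning update. Passing tests therefore demonstrate that the analysis
chain is correct and well-calibrated under its stated assumptions, not
that those assumptions exhaust real data.

## Numerical and design choices

* Per-subject seeds derive from the master seed as
  $(\text{seed} \cdot 1000003 + i) \bmod (2^{31}-1)$, keeping streams
  disjoint and every derived seed a valid 32-bit integer.
* Fit tolerances: simplex f-tolerance down to $10^{-16}$ with polish
  restarts; noiseless self-fits reproduce parameters to $10^{-3}$ and SSE
  below $10^{-10}$.
* Likelihood probabilities are clipped to $[10^{-9}, 1-10^{-9}]$.
* Problem sizes used in the validation suite — chosen as desk-scale
  stand-ins for the full-scale analyses: 8-subject cohorts × 150 trials
  for group fits; 200 simulated experiments × 500 permutations for null
  calibration (5000 permutations at full scale); 12 subjects for Bayesian
  recovery at 4 × 2000/1000 sampler settings (4 × 20000/10000 at full
  scale); 1000 random seeds for schedule-constraint checks.
* The progressive-ratio session-termination rule (six consecutive
  failures) is validated, not enforced, so truncated real sessions can
  still be scored.

## Known limitations

* The group-level fit treats the per-trial mean as homoscedastic; no
  weighting by per-trial subject counts is applied (ragged groups are
  rejected instead).
* $\alpha$ and $V_1$ are weakly identified from single-subject binary
  outcome data at realistic trial counts; only $\beta$ supports strong
  individual-level claims at this scale.
* The permutation test assumes subject exchangeability under the null;
  when groups differ in one parameter, tests on the *other* parameters
  are approximate (their null is not exactly exchangeable).
* When a group curve has little curvature over the observed trials (a
  compressed dynamic range, e.g. under a weak outcome link), the
  asymptote $\beta$ is an extrapolation: noise can flip the least-squares
  fit into a "still rising" solution (small $\hat\alpha$, large
  $\hat\beta$), fattening the tails of resampled estimates. Power
  analyses of the safety-value contrast are therefore run at the effect
  scale the fitted parameters actually face.
* Peak-offset analysis reports sample-resolution offsets; sub-sample
  interpolation is not attempted.
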