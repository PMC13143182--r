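---
title: "Unified neural-network Hodgkin-Huxley models with random effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified neural-network Hodgkin-Huxley models with random effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhmix)
```

## The problem

Voltage-gated potassium (K~v~) channels are classically described by
Hodgkin–Huxley (HH) gating models: each channel carries a small number of
independent gates $m_i$ relaxing toward a voltage- and temperature-dependent
steady state,

$$\frac{dm_i}{dt} = \frac{m_{i,\infty}(V,T) - m_i}{\tau_i(V,T)},
\qquad m_{i,\infty} = \frac{\alpha_i}{\alpha_i+\beta_i},
\qquad \tau_i = \frac{1}{\alpha_i+\beta_i},$$

with the observable normalized current

$$\frac{I(t)}{I_{max}} = \frac{(V(t)-E)\prod_i m_i^{n_i}(t)}{(V_{max}-E)},$$

in which the maximal conductance cancels ($V_{max} = 80$ mV, the largest
activation command). Two practical difficulties motivate this package: the
functional forms of $m_{i,\infty}$ and $\tau_i$ differ between channel
types and are laborious to hand-craft, and cells expressing genetically
identical channels still show substantial kinetic variability that a single
parameter set cannot represent.

`hhmix` addresses both with a *unified* model: the gating functions are
small multilayer perceptrons shared across all cells and channel types,
individualized through *random effects* in the nonlinear mixed-effects
(NLME) sense. Each cell $n$ carries a latent vector
$\eta_n \in \mathbb{R}^{8+1}$ (two effects per gating function plus a
temperature effect) entering the networks as extra inputs; a covariate
*augmentation network* maps the channel-type indicator $c_n$ and the
normalized temperature to an offset $\eta^\dagger_n$, so that the effective
effects are $\eta_n^* + \eta^\dagger_n$. With $\eta = 0$ the model is the
population model for a channel type; with estimated effects it is an
individualized cell model.

## Model components

**Gating networks.** Each of the four gating functions (two gates ×
steady state / time constant) is an MLP with two hidden layers of 5 tanh
units taking $(V/100,\; \bar T + \eta_{temp},\; \eta_a,\; \eta_b)$. The
steady-state head is a sigmoid (range $(0,1)$); the time-constant head is a
softplus (range $(0,\infty)$), multiplied by a fixed output scale of 50 ms.
The scale is pure conditioning: physiological time constants span roughly
1–300 ms while the L1 prior keeps pre-activations of order one; without the
scale the softplus argument would need to reach hundreds. Voltage is scaled
by 1/100 so the −90…+80 mV protocol range maps to order-one inputs;
temperature is normalized as $\bar T = (T-25)/10$, so the three standard
recording temperatures (15, 25, 35 °C) map to −1, 0, +1.

**Temperature effect.** $\eta_{temp} \sim \mathcal N(0,1)$ models the
recording temperature as a noisy label. It perturbs the temperature input
of both the augmentation network and the gating networks (the latter is
config-exposed, `eta_temp_in_gating`), because a mislabeled bath
temperature affects every temperature-dependent pathway identically.

**Priors.** Network weights and biases carry a Laplace prior equivalent to
L1 regularization with $\lambda = 10^{-4}$; random effects carry a
multivariate normal prior with covariance $\Omega$, initialized to the
identity.

## Estimation

Stage 1 maximizes the conditional MAP objective

$$\log p(\Theta) + \sum_n \big[\log p(y_n \mid \Theta, \eta_n) +
  \log p(\eta_n \mid \Omega)\big]$$

jointly over all fixed effects (network weights, $\log\sigma$) and all
per-cell effects, with $\Omega$ frozen at the identity so that the prior
keeps penalizing extreme effects while the networks learn. One *epoch* is
one quasi-Newton (L-BFGS) iteration over the full data; parameters are
checkpointed every 15 epochs, each checkpoint is scored by mean per-sweep
RMSE on validation cells (whose effects are re-estimated by empirical
Bayes), and the best-scoring saved checkpoint is returned.

Gradients are analytic throughout. Because the voltage commands are
piecewise constant, each gate has the exact per-segment solution
$m(t) = m_\infty + (m_0 - m_\infty)e^{-(t-t_s)/\tau}$; a compiled kernel
evaluates the trajectories and accumulates the reverse-mode sensitivity of
the squared-error loss with respect to every per-segment $m_\infty$ and
$\tau$, and those coefficients are pulled back through the networks with
batched matrix backpropagation. The same closed form is the default
integrator of `simulate_sweep()`; an adaptive solver (`method = "lsoda"`,
rtol $10^{-6}$, atol $10^{-8}$, restarted at every voltage step) is kept as
an independent cross-check and agrees to better than $10^{-4}$ in the test
suite. The L1 prior is smoothed as $\sqrt{\theta^2 + 10^{-10}}$ so the
quasi-Newton steps see a differentiable objective.

Stage 2 freezes everything except $\Omega$ and maximizes a first-order
conditional (FOCE/Laplace-at-the-mode) approximation of the marginal
likelihood: for each cell the integral over $\eta$ is expanded at the
empirical Bayes estimate with Gauss–Newton curvature
$H = J^\top J/\sigma^2 + \Omega^{-1}$ (ridge $10^{-6}$ if needed). For
linear-Gaussian models this approximation is exact, which the tests exploit
as an oracle ($|\Delta| < 10^{-6}$ against the closed-form marginal). The
$\Omega$ update is expectation–maximization rather than direct quasi-Newton
ascent: each of the (default 10) iterations re-estimates every cell's mode
and curvature and sets each prior variance to the mean posterior second
moment $\overline{\hat\eta_j^2 + (H^{-1})_{jj}}$. The fixed point of this
update is a stationary point of the Laplace marginal, and the update is
insensitive to the small numerical noise that the inner mode searches leave
in the objective (which defeats finite-difference line searches). A
frozen parametric model with random effects on designated parameters is
supported through the same interface (`classical_hh_model()`,
`fit_random_effects_only()`), where only $\sigma$ and the per-cell effects
are estimated.

## Voltage-clamp protocols and preprocessing

The four protocol families are built exactly: every sweep starts with the
100 ms baseline (40 ms at −80 mV, 10 ms at −90 mV, 50 ms at −80 mV) and
ends with 100 ms at −80 mV; activation holds 18 voltages (−90…+80 mV,
500 ms), deactivation holds +70 mV for 300 ms then 12 tail voltages
(−80…+30 mV, 200 ms), inactivation holds 12 voltages (−40…+70 mV, 1500 ms)
then +30 mV for 100 ms, and recovery separates two +50 mV pulses by a
−80 mV gap of 50…2300 ms in 150 ms increments. Segments are half-open
$[t_s, t_e)$: a step at $t$ takes the new value at $t$, which makes
evaluation at discontinuities deterministic. The protocol description and
the downsampling description disagree on the recovery test-pulse length
(200 vs 150 ms); the builder uses 200 ms and the downsampler bins whatever
length is present, with the alternative available via
`overrides = list(recovery_test_ms = 150)`.

The processing pipeline applies, in order: repetition selection (activation
repetition 2, every other protocol repetition 1 — later repetitions suffer
rundown), cross-protocol consistency filtering, DCT smoothing, baseline
subtraction (mean of the first 40 ms), normalization by the +80 mV
activation peak $I_{max}$, rescaling of the other protocols by their
matching activation peak, deletion of points below −0.01 (fast negative
step artifacts cannot be produced by the model and should not penalize it),
and extrema-preserving M4 downsampling to the published per-window counts
(9 baseline points; 120/72+48/360+24/360+3+48 protocol points; 3 tail
points).

### Numerical choices in the consistency filter

The filter compares a deactivation/inactivation/recovery sweep against the
matching activation sweep via the mean absolute percentage error (MAPE,
threshold 0.05) after peak scaling. Several robustness choices matter at
finite signal-to-noise ratio and deserve an explicit record:

* **Admissibility.** The percentage error at a near-zero reference point is
  unbounded noise, so points below 30% of the compared window's peak are
  excluded from the average (an absolute floor of $10^{-6}$ always
  applies). Decaying traces settle close to any lower floor, where the
  ratio degenerates to noise/floor; placing the floor well inside the
  signal range keeps the statistic shape-driven.
* **Window-based peak scaling.** Peaks are taken over the compared window,
  not the full sweep; a full-sweep peak can come from a different segment
  (the inactivation sweep's +30 mV test pulse) and would introduce a
  systematic scale mismatch between physically identical traces.
* **Heavy smoothing inside the check only.** The compared copies are
  smoothed with a much larger kernel than the data path (factor 144 vs 1.0
  in `denoise()`); the same kernel hits both traces, so shared shape
  distortion cancels while independent noise drops by an order of
  magnitude. Kinetic inconsistencies live at far coarser time scales and
  survive.
* **Offset alignment and trimming.** The two copies carry independently
  estimated baselines whose small errors are amplified by the peak-ratio
  scaling, so the median pairwise offset is removed before the percentage
  errors are formed; the largest 2.5% of percentage errors are trimmed so
  a brief step artifact (about 1 ms in a 300–500 ms window) cannot decide
  a whole-sweep exclusion.
* **Eligibility.** A sweep whose window peak is below 25% of the +80 mV
  activation peak is kept unchecked: after scaling, its comparison is
  noise-dominated, and a sweep carrying no measurable current also cannot
  mislead the fit.
* **Recovery endpoint.** The end-of-hold current (1500 ms post-baseline) is
  read as the median of the smoothed trace over 1590–1599 ms — just before
  the voltage step, out of reach of step artifacts — and a sweep is
  excluded when it deviates from the per-cell median by more than
  max(SD across sweeps, 3 × estimated noise SD). The noise floor matters:
  for an iid sample the bare one-SD rule flags roughly a third of
  perfectly consistent sweeps, because about 32% of any sample lies more
  than one SD from its median; the rule only has specificity when either
  outliers inflate the SD or a noise floor protects the homogeneous case.
* **Cell exclusion.** A cell is dropped when its +80 mV activation peak
  does not exceed 5 × the estimated noise SD; the idealized rule
  "$I_{max} \le 0$" can never fire on noisy data since the maximum of a
  noisy trace is almost surely positive.

## The synthetic population generator

The generator defines the package's standing study conditions. Channel
archetypes play the role of channel types: two gates with Boltzmann steady
states $1/(1+e^{-(V-V_{1/2})/k})$ (negative $k$ gives inactivation),
bell-shaped time constants $\tau_{base} + \tau_{amp}
e^{-((V-V_{peak})/w)^2}$ and per-gate $Q_{10}$ scaling
$\tau(V,T) = \tau(V,25)\,Q_{10}^{-(T-25)/10}$ ($Q_{10} = 2$ for the slow
gate, 4 for the fast gate — within and slightly above the 2–4 range
conventional for channel kinetics). The default archetypes are a fast
activator with pronounced inactivation (A-type-like) and a slow activator
with slow shallow inactivation (delayed-rectifier-like); further templates
add a non-inactivating rectifier and a fast-inactivating slow activator.
Cells drawn from an archetype shift each $V_{1/2}$ by $\mathcal N(0, 5\ \mathrm{mV})$
and scale each $\tau_{amp}$ log-normally (SD 0.2) — variability of the
order seen across cells expressing the same channel gene. Recordings are
simulated at 0.1 ms sampling with Gaussian observation noise (SD 0.02 in
units of the typical peak), per-sweep baseline offsets (SD 0.05), a
log-normal per-cell amplitude, negative spike artifacts at voltage steps
(probability 0.1 per step, ~1 ms decay), and kinetically inconsistent sweep
replacements (time constants × 4, $V_{1/2}$ + 12 mV, probability 0.05 per
eligible sweep) that the MAPE filter must reject. Inconsistencies are only
injected into sweeps carrying measurable current in the compared window
(≥ 25% of the +80 mV peak for both the clean and the distorted version):
a kinetic distortion of a near-zero trace is unobservable in principle and
would make the ground-truth label meaningless.

What the generator does **not** emulate: capacitive transients and series
resistance artifacts beyond the stylized negative spikes, rundown within a
repetition, correlated (1/f) noise, leak currents, endogenous background
conductances, and liquid-junction drifts. Passing the round-trip tests
therefore shows the pipeline implements its rules correctly and separates
the modeled artifact classes at the stated SNR, not that it would keep
every clean sweep of a real recording.

## Identifiability and known limitations

A voltage-clamp protocol only informs a gating parameter where the channel
conducts. With the default archetypes both channel types inactivate almost
completely during the 300 ms +70 mV deactivation pre-pulse, so the
deactivation tails carry nearly no current and the fast gate's time
constant at hyperpolarized voltages is essentially unconstrained by the
data; similarly the slow gate below −40 mV is probed only at −80 mV (the
recovery gap). Fitting at desk scale (18 training cells, 300 epochs,
roughly three minutes on one CPU) recovers the steady-state curves to a
mean absolute error near 0.05 on the full −90…+80 mV × {15,25,35} °C grid,
while the time-constant curves reach tens of percent in well-probed regions
but several hundred percent where no protocol pins them down — the network
extrapolates smoothly but has no reason to extrapolate correctly. The
acceptance script reports both numbers (`minf_recovery_mae`,
`tau_recovery_rel_error`) computed per cell against the known truth, with
gate labels matched over the two permutations (with unit gating exponents
the product $m_1 m_2$ is symmetric in the labels, so the assignment is a
gauge choice). Any use of the fitted $\tau$ surfaces outside the
protocol-probed region should be treated as extrapolation.

Other known limitations: the two-stage procedure is not full marginal
maximum likelihood (the conditional stage can trade prior mass against fit
in ways stage 2 only partially corrects); $\Omega$ is estimated as a
diagonal; the VPC interpolates sweeps onto a common uniform grid (61–101
points) before computing quantiles; and the Wilcoxon comparison uses the
exact distribution only up to n = 25 without ties, the
continuity-corrected normal approximation otherwise.

## Problem sizes used by the tests and the acceptance script

The packaged experiments use 2 archetypes × 3 temperatures × 3 cells
(18 cells, ~15,500 downsampled points per cell) for stage-1 fitting with a
6-cell validation population; 200 cells × 8 observations for the
linear-toy variance recovery; 200 replicate populations for the VPC; and a
20-cell population (18 live + 2 dead) for the QC round trip. These sizes
were chosen so the full workflow — generation, preprocessing, fitting,
diagnostics — runs end to end in minutes on a single CPU while leaving
every estimator in its asymptotically meaningful regime.

## A minimal session

```{r example, eval = FALSE}
ds <- simulate_population(population_config(seed = 1))
pp <- run_pipeline(ds)
train <- prepare_fit_data(pp$dataset)
model <- deep_gating_model(n_onehot = 1)
fit <- fit_stage1(model, train, train, epochs = 300, checkpoint_every = 15)
st2 <- fit_stage2(fit$model, train)

funcs <- population_gating_functions(fit$model, channel_index = 1)
q10_gate2 <- q10_curve(funcs, seq(-40, 60, 10), Temp = 15, gate = 2)
```
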