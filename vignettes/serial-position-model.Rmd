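---
title: "A synaptic account of serial position effects in sequential working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A synaptic account of serial position effects in sequential working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swmcann)
```

## The model

`swmcann` simulates a continuous attractor neural network (CANN) of rate
neurons arranged on an orientation ring, augmented with Tsodyks–Markram
short-term plasticity (STP), and uses it to study why recall accuracy in a
sequential working-memory task depends on an item's position in the
presented sequence — the serial position effect.

Excitatory neurons are labelled by their preferred orientation
$\theta \in [-\pi/2, \pi/2)$ (orientation is $\pi$-periodic).  The synaptic
input $h_E(\theta, t)$ obeys

$$\tau \frac{\partial h_E}{\partial t} = -h_E
  + \rho \int J(\theta, \theta')\, u x\, r_E\, d\theta'
  - J_{EI} r_I + I_{ext} + I_0 + \sigma_0 \eta,$$

with a smoothed threshold-linear rate
$r_E = \alpha \log(1 + e^{h_E/\alpha})$, a translation-invariant
truncated-cosine connectivity
$J(\theta,\theta') = J\cos[B(\theta-\theta')]$ inside the range where this
exceeds the floor $J_0$, and a single global inhibitory pool driven by the
summed excitatory rate ($J_{IE}$, $J_{EI}$).  The inhibitory pool enforces
competition: at most one activity bump is expressed at a time.

Each connection carries STP state: the release probability $u$
(facilitation, decaying with $\tau_f$) and the available transmitter
fraction $x$ (depression, recovering with $\tau_d$),

$$\dot u = -u/\tau_f + U_0 (1-u) r_E, \qquad
  \dot x = (1-x)/\tau_d - u\, x\, r_E,$$

in the facilitation-dominant regime $\tau_d \ll \tau_f$.  The instantaneous
synaptic efficacy $J u x$ of the neuronal group encoding an item is the
*activity-silent* memory trace: after a stimulus is removed, firing decays
to silence within tens of milliseconds, while the facilitated $u$ of the
stimulated group persists for seconds.

## The task

`task_protocol()` implements a cued delay-recall paradigm: $M$ items
(orientations) are presented sequentially for $T_{encode}$ each, separated
by $T_{gap}$; after a maintenance period $T_{maintain}$ (clocked from
last-item offset) a weak, spatially imprecise cue centred on the probed
item's orientation is shown for $T_{recall}$.  The first item is uniform on
the ring, later items are offset by the task's discrete orientation
differences (17–80° for two items, 12–84° for three, both signs).  The
response is decoded from the population vector of the rate profile,
averaged over the first half of the recall window, with angle doubling for
the $\pi$-periodic feature.

## Why the serial position effect arises

When items are encoded, each group's $x$ is depleted and $u$ facilitated.
Right after the last item, the *earlier* item has had time for $x$ to
recover, so its efficacy $J u x$ is higher: cueing the later item more
often fails or swaps — the **primacy** effect.  As maintenance lengthens,
$x$ of all groups recovers fully and the traces differ only through
$u \propto e^{-t/\tau_f}$, which favours the *later* item — the
**recency** effect.  The crossover time of the efficacy difference
$\Delta Jux(t) = Jux_2(t) - Jux_1(t)$ has the closed form (`tc_exact()`)

$$T_c' = \tau_d \log\frac{(1-x_0)\left[1 - e^{-t^*/\tau_d - t^*/\tau_f}\right]}
  {1 - e^{-t^*/\tau_f}},$$

with $t^* = T_{encode} + T_{gap}$ the inter-item stride and $(u_0, x_0)$
the STP state at stimulus offset.  `delta_jux_two()` builds the contrast
constructively from the per-group relaxation `jux_group()`, and the package
verifies the closed form against brute-force root finding.  $T_c'$
increases with $\tau_f$ and $\tau_d$ and decreases with $t^*$
(`theory_grid()`).  For three items the shift relation
$Jux_i(t) = Jux_j(t + (j-i)t^*)$ makes the pairwise crossovers copies of
each other separated by $t^*$ (`tc_three_items()`).

In the full network, the recall read-out realises this comparison
dynamically: the weak cue drives all groups, and the group whose efficacy
is highest ignites a transient bump first, typically 40–200 ms after cue
onset (the cue-response bias $t_b$ of `tc_simplified()`).  Errors arise in
three ways, all graded by the efficacy difference: ignition of the wrong
(stronger) group (swap errors), complete failure to ignite (scored as a
uniform guess), and attraction of closely spaced bumps during encoding.

## Calibration

The operating point was calibrated with `calibrate_network()` under three
constraints that the task imposes:

* an encoding stimulus ($a_{encode} = 40$, $B_{encode} = 8$) must evoke a
  clear bump;
* the network must return to silence after stimulus offset — the memory is
  activity-silent, so no persistent attractor state is allowed.  This
  bounds the recurrent strength $J$ from above (bisection in
  `calibrate_network()` places the bound near $J \approx 2.0$ at the
  defaults, and $J = 1.6$ is used for margin under noise);
* the recall cue must be able to re-ignite a bump from the facilitated
  trace.  `calibrate_network()` verifies reactivation with a cue at
  $a_{encode}/10$; the task itself uses $a_{recall} = 3.5$, deliberately
  placed in the stochastic ignition-threshold regime so that retrieval
  succeeds or fails according to the trace strength.  A much stronger cue
  retrieves every item perfectly (the task becomes trivial); a weaker one
  retrieves nothing.

The kernel width ($B = 12$, interaction range $\approx \pm 7^\circ$) and
stimulus sharpness were chosen so that bumps of items separated by the
smallest task differences (12–17°) overlap as little as the 128-neuron
ring allows; with broad kernels the second item's stimulus re-facilitates
the first item's group and destroys the efficacy ordering.  The cue is
spatially imprecise ($B_{recall} = 1$, support the whole ring) so that a
non-target group can win the ignition competition — with a narrow cue no
swap errors exist and the serial-position contrast vanishes.

Neuronal groups use a half-width of 10°, which covers the stimulated core
of a bump while staying below the smallest item separation; with wider
groups the group averages $(u_0, x_0)$ are diluted by unstimulated neurons
and no longer parameterize the reduced theory consistently (the
single-exponential crossover computed from diluted means is ~30% below the
crossover of the actual mixture of per-neuron relaxations; at 10° the two
agree to better than 1%).

Defaults: $N = 128$, $\tau = 10$ ms, $dt = 0.5$ ms, $\rho = N/\pi$,
$U_0 = 0.3$, $\tau_f = 4$ s, $\tau_d = 0.3$ s (centres of the studied
ranges $[2,8]$ s and $[0.1,0.4]$ s), $\alpha = 1.5$, $I_0 = -6$ (resting
rate $\approx 0.007$, so the silent state barely perturbs the STP
relaxation), $\sigma_0 = 0.1$.  The Euler–Maruyama step is validated by a
pure-R reference step and by a $dt$-halving convergence check.

## Read-out and statistics

The decoded response window is the **first** half of the recall period.
The response is the first ignition burst; once a group has answered, its
resources are depleted and later re-ignitions within the cue period
alternate between groups in a way that reflects facilitation (always
favouring the most recent item) rather than the efficacy comparison at cue
onset.  Averaging the late window therefore corrupts the read-out;
averaging the early window captures the decision.  Trials whose window
never exceeds a rate of 5 (cue-driven activity alone peaks near 0.35,
bumps above 30) are scored as uniform guesses: the network failed to
retrieve anything.

Recall performance is quantified per item by the *normalized target
probability*: a maximum-likelihood von Mises mixture
(`fit_response_mixture()`) over doubled response angles with components at
the target, at each non-target, and a uniform guessing floor, sharing one
concentration $\kappa$; $P_i$ is the mean posterior probability of the
target component.  Circular variance and kurtosis of the (doubled) errors
provide two further accuracy measures, and all three yield their own
transition estimate.  Per-run $P$ contrasts are compared with a two-sided
paired Wilcoxon test and mapped to the conventional significance
categories.  The transition time $T_c$ is read off the contrast-vs-
$T_{maintain}$ curve by linear interpolation of the zero crossing, and the
simulated crossover $T_c'(\mathrm{SIM})$ by the first zero crossing of the
trial-averaged $\Delta Jux(t)$.

## Experiment scale

Desk-scale defaults are 10 runs ("participants") of 60 trials at five
maintenance durations bracketing the theoretical crossover
($T_c' \times \{0.4, 0.7, 1, 1.5, 2.5\}$ for two items); the
paradigm's full scale (50 runs of 300–500 trials, an 11-value maintenance
grid up to 10 s) is available by passing the corresponding plan
(`t_maintain_full_grid()`, `n_runs = 50`, `n_trials = 300`).  A complete
desk-scale two-item experiment takes about two minutes on one CPU; sweep
grids default to a handful of points per axis against the full-scale 21.

For three items the gap defaults to 0.15 s instead of 1 s: every pairwise
crossover is shifted earlier by one stride, so the first-vs-second
crossover only exists inside the maintenance period when
$\tau_d \log[(1-x_0)/(1-e^{-t^*/\tau_f})] > t^*$.  The three-item
maintenance bracket also extends further down
($\{0.15, 0.5\} \times T_{c,12}'$) because encoding interactions between
three closely spaced items pull the simulated first-pair crossover below
its reduced-theory value.

## Numerical choices

* $u, x$ are clipped to $[0,1]$ after every Euler step (the continuous
  system preserves the bounds; the discrete one can overshoot).
* Background noise enters as $\sigma_0\sqrt{dt}/\tau\,\eta$ per step;
  stimulus pixel noise is redrawn every step.
* All ring differences are wrapped to $[-\pi/2, \pi/2)$; circular moments
  are computed on doubled angles and reported errors are un-doubled.
* The mixture EM caps $\kappa$ at $5\times10^3$ (more concentrated samples
  are numerically point masses); a non-convergent fit falls back to the
  flagged nearest-item assignment proportion.
* Zero crossings are located by linear interpolation on the sampled grid;
  when a curve does not change sign, `NA` marks the out-of-range result.
* Child seeds are derived deterministically from the root seed per (run,
  trial), so any subset of trials can be reproduced independently and
  execution order is irrelevant.

## What the simulations do and do not show

The generator reproduces the qualitative and quantitative structure of the
modelled task: transient bump encoding, activity-silent maintenance,
cue-triggered retrieval, a primacy-to-recency transition whose time agrees
with the closed-form crossover to within ~15–20% at desk scale, and the
predicted parameter dependencies.  Known limitations:

* At the closest item separations (12–24°) bumps interact during encoding:
  the later item's stored orientation is attracted toward the earlier
  item's, and the measured group efficacies deviate from the
  non-interacting theory.  The paradigm's separation sets include such
  pairs, which adds a maintenance-independent error component.
* At maintenance durations beyond roughly $2 T_c'$ the traces approach the
  re-ignition threshold and retrieval failures dominate; the informative
  cue makes surviving trials look accurate, so the recency contrast decays
  faster than in the underlying efficacies (behavioural versions of the
  paradigm show
  the same qualitative weakening of recency at long delays).
* Human data involve attention, context and inter-trial effects that the
  model does not represent; passing tests validate the synaptic mechanism,
  not a fit to any behavioural data set.
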