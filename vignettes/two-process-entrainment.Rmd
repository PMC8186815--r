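---
title: "Minimum-time circadian entrainment with the two-process model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-time circadian entrainment with the two-process model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(circentrain)
```

## The model

`circentrain` simulates and optimally steers a hybrid model of human
circadian rhythm and sleep regulation built from three coupled pieces.

**Process L (retinal light transduction).** Light of intensity $I$ (lux)
activates retinal photoreceptors at rate
$\alpha(I) = \alpha_0 \big(I(1-\beta)/I_0\big)^p$; the used fraction
$n$ relaxes as
$$\dot n = 60\,\big(\alpha(I)\,(1-n) - \gamma n\big),$$
and the neural drive forwarded to the pacemaker is
$u = G\,\alpha\,(1-n)$.  The sleep state $\beta \in \{0,1\}$ gates light
off completely during sleep ($\alpha = 0$ when $\beta = 1$): closed eyes
decouple the clock from the environment, which is one of the structural
features that make this control problem hard.  Under constant light the
stage settles quickly at $n = \alpha/(\alpha+\gamma)$,
$u = G\gamma\alpha/(\alpha+\gamma)$ — this closed form gives
$u = 0.1731$ at 1000 lux and $u = 0.2208$ at 10000 lux and is used to
translate between lux and drive units throughout the package.

**Process C (core body temperature oscillator).** A van der Pol-type
second-order oscillator in $(x, x_c)$ with a compressive light
modulation $(1-0.4x)(1-k_c x_c)$ and intrinsic frequency
$24/(0.99729\,\tau_x)$; its free-running period is 24.2 h.  A scalar
phase can be read off as $\theta = \operatorname{atan2}(-x_c, x)$.

**Process S (sleep homeostat).** $H$ rises toward 1 while awake with
time constant $\tau_r = 18.2$ h and decays toward 0 during sleep with
$\tau_d = 4.2$ h.  Sleepiness combines both processes,
$B = H - A_c x$ (or $H - A_c\cos\theta$ in the phase-reduced model).
Under the *spontaneous* schedule the subject falls asleep when $B$
reaches $H_m = 0.67$ and wakes when it drains to $L_m = 0.17$
(hysteresis); under the *controllable* schedule sleep and wake times are
decision variables constrained to $0.67 \le B(T_{sleep}) \le 0.77$ and
$0.17 \le B(T_{wake}) \le 0.27$, with no wake interval longer than 18 h.

Three variants are implemented: the full model `S+C3`
($n, x, x_c, H$), the reduced `S+C2` ($x, x_c, H$; Process L replaced by
its steady state), the phase model `S+C1` ($\theta, H$;
$\dot\theta = \omega_0 + f(\theta)u$ with an empirically tabulated phase
response curve), and a sleep-free `C-only` variant
($n, x, x_c$) for the classical circadian-only problem.

All parameter defaults in `two_process_params()` are the published
values of the underlying models; none of them is fitted by this package.

## Reference cycle, entrainment and the terminal condition

The environment is the square zeitgeber $I_{ref}$: 1000 lux for 16 h
from 6 am, darkness for 8 h.  Simulated under this light with the
spontaneous automaton, every interior initial state converges to a
24-h periodic trajectory $Y_{REF}$ — the entrained reference — whose
spontaneous sleep runs from about 11:10 pm to 7:30 am.
`compute_entrained_cycle()` finds it by iterating 24-h simulations from
the fixed interior state ($x = 1$, $x_c = 0$, $n = H = 0.5$, awake)
until the 24-h return map moves by less than $10^{-8}$ (max-norm;
typically ~70 days of model time, well under a second of CPU), then
stores one dense period on a 0.01-h grid.  Entrainment of a displaced
subject is declared at the first time
$$\lVert z - z_{ref}(t+\Delta_{init})\rVert_2^2 \le \mathrm{tol},$$
where $z$ collects $(x, x_c, H)$ for `S+C3`/`S+C2` (the fast state $n$
is excluded), $(\theta, H)$ with a wrapped angle difference for `S+C1`,
and $(x, x_c)$ for `C-only`.  The published source of this condition
does not state its tolerance; the package default is
$\mathrm{tol} = 0.01$ on the squared norm, exposed in
`terminal_spec()`.  The headline recovery times reproduced in the test
suite are consistent with that choice.

## The phase response curve

`estimate_prc()` applies the classical pulse protocol to the
second-order oscillator: settle onto the free-running orbit, start at
one of 256 phases, apply the 1000-lux-equivalent drive ($u = 0.1731$)
for 30 minutes, integrate ten free-running periods, and read the
asymptotic phase shift off the timing of upward zero crossings of $x$
relative to an unperturbed twin.  Values are normalized per unit drive
and hour, so the phase model reproduces the calibration pulse by
construction.  Mapped to clock time through the reference cycle, the
curve is phase-advancing from about 7:30 am to 5 pm and phase-delaying
from 5 pm to 11:10 pm, which is the mechanistic driver of every
optimal schedule below.  The ten-period wait is our choice (the
protocol's settling time is not published); halving it moves the curve
by well under 1%.

## Hybrid integration

The integrator (compiled code) uses fixed-step classical RK4 with
`dt = 0.005` h.  A fixed step keeps runs bit-reproducible and avoids
the event-skipping pathologies adaptive steppers exhibit on hybrid
systems; the factor-60 time scale of Process L sets the step ceiling
(the retinal stage relaxes in ~15 min, so 0.005 h resolves it with
~60 steps per time constant).  Sleepiness-threshold crossings are
localized by bisection on the step length — far below the 1e-6 h event
tolerance, to machine precision, so that finite differences across
switching times remain clean — and integration stops exactly at light
breakpoints and scheduled switch times.  When a switch coincides with a
light breakpoint the switch is processed first so the light gating sees
the updated sleep state.  $\beta$ is right-continuous: the new mode
applies on $[t_s, \cdot)$.

## The minimum-time optimizer

The decision variable is piecewise-constant light on 0.1-h bins.
Internally each bin holds a normalized level $w \in [0,1]$ scaled in
*drive units* — $\alpha$ for the full model, $u$ for the reduced ones —
because the dynamics are linear in that unit, whereas
$d\alpha/dI \propto I^{-1/2}$ diverges at $I = 0$ and would cripple a
projected gradient at the dark bound.  Bang-off in $w$ is bang-off in
lux.

**Gradients.** For a fixed horizon the terminal residual is
differentiated with the adjoint method: integrate
$\dot\lambda = -(\partial F/\partial y)^\top\lambda$ backward along the
stored forward trajectory; at every state-triggered switch (guard
$B(y) = $ threshold) apply the jump
$$\lambda(t_s^-) = \lambda(t_s^+) -
  \frac{(F^- - F^+)^\top \lambda(t_s^+)}{\nabla B^\top F^-}\,\nabla B,$$
obtained from the first-order variation of the guard condition; if
$\nabla B^\top F^- \approx 0$ (grazing) the jump is skipped and
counted.  Scheduled switch times get the gradient
$\lambda^\top(F^- - F^+)$ and no jump.  Per-bin light gradients are
$\int \lambda^\top \partial F/\partial c\,dt$ (Simpson on the step
grid) and are exactly zero across sleep.  The test suite holds these
gradients to within 1% of central finite differences; in practice they
agree to ~1e-5 relative.

**Fixed horizon.** Projected gradient descent with Armijo backtracking
minimizes the residual, stopping early as soon as the horizon is
feasible.  For controllable sleep the switch times move along their
adjoint gradients and are then projected into their sleepiness windows
by short counterfactual simulations (hold the sleep state, find where
$B$ meets the bound) — projecting on the realized trajectory would look
in the wrong direction, since waking changes the sign of $\dot B$.
Warm-start schedules are inset ~6 min away from the spontaneous
thresholds: a scheduled switch sitting exactly on a threshold crossing
is shadowed by the automaton's own guard and loses its gradient.

**Horizon search.** Minimum-time entrainment is bistable: a $16$-h
shift can be corrected by advancing 8 h or delaying 16 h, and plain
descent cannot cross between the basins.  The outer loop therefore
seeds both: greedy *pumping* lights (light on, while awake, wherever
the PRC favors the chosen direction along the subject's own phase),
for controllable sleep additionally with the automaton thresholds
extended to the schedule bounds ($T_{sleep}$ at $B = 0.77$ for delay,
$T_{wake}$ at $B = 0.27$ for advance — exactly the two manoeuvres the
schedule constraints permit).  Because the extended automaton holds
$H$ slightly off the reference pattern, the pump alone may circle the
terminal set without entering it; the anchor therefore hands the
closest approach over to the reference light with the true spontaneous
automaton for the final leg.  Each verified anchor (best per direction)
is then polished by monotone horizon shrinking — truncate, re-descend,
halve the step on failure — down to a 0.02-h resolution.  The final
light is thresholded to bang-off $\{0, I_{max}\}$ and re-verified;
because the descent stops at feasibility it can leave soft "ramps" of
intermediate bins at block edges (sub-bin switch times), which are
rounded group-wise to a bang-off pattern with the same integrated drive
and accepted only if the verified crossing moves by less than
$\max(0.5\,\mathrm{h}, 3\%)$.
Everything is deterministic; there is no randomness anywhere in the
optimizer.

## Feedback controller

Optimal trajectories (controllable sleep, shifts 1–23 h by default) are
sampled at 0.01 h into records $(\theta, H, \theta_{ref})$ with the
applied light and the countdown to the next scheduled switch; past the
last optimized switch the countdown continues onto the entrained
reference schedule.  A 1-nearest-neighbour policy over the embedding
$(\cos\theta, \sin\theta, H, \cos\theta_{ref}, \sin\theta_{ref})$
(circularity-respecting, $H$ already in $[0,1]$, Euclidean metric,
ties to the lowest index) is queried every 0.1 h in closed loop; a
fresh query overrides the previous countdown, making the policy Markov
in the measured state, and the $B$-bound safety overrides stay active.
On its training cases the closed loop reproduces the optimal
entrainment time to well within 5%.

## What the scenarios do and do not show

The scenario runners reproduce the study conditions exactly as printed:
jet lag starts at 7 am destination time ($\Delta_{init} = 1$) from
$y(0) = Y_{REF}(\Delta_{shift} + 1)$; night shifts pin the subject
awake from 8 pm (or 10 pm) to 8 am under a constant `I_shift`, with
entrainment measured from 8 am against $Y_{REF}(t + 2)$ and the shift
excluded from the count.  All inputs are generated by the model itself
— there is no measured human data in the package — so agreement with
the published recovery times validates the implementation of the
model and optimizer, not the model's fidelity to any individual
sleeper.  Fixed parameters ignore inter-individual variability,
photoperiods are square 16–8 waves, light is scalar lux with no
spectral weighting, and sleep is a binary state without REM/NREM
structure.

## Problem sizes and costs

The test suite and the acceptance script run the full pipeline at the
published conditions: limit-cycle searches to $10^{-8}$, the 256-point
PRC, the four open-loop shift-work recoveries, both optimized
shift-work cases, the 16-h jet-lag pair at 1000 lux, and a six-shift
sweep (8–18 h, 10000 lux) for the ordering and asymmetry properties;
the sweep stands in for the full 23-shift training grid, whose
remaining cases add nothing methodologically.  A long optimization
(hundreds of hours of model time) takes tens of seconds; everything
else is seconds or less.

## Known limitations

* The inner optimizer is a local method; global optimality is only as
  good as the anchor set.  The two PRC-guided basins cover every case
  studied here, but exotic parameter sets might need more anchors.
* The terminal tolerance is a package default, not a published value;
  recovery times shorter than ~4 h are sensitive to it.
* Scheduled switch times are projected, not interior-point-constrained;
  bound satisfaction at convergence is to ~0.005 in $B$ rather than
  exact.
* The phase-reduced variant inherits the PRC table's interpolation; its
  optimal solutions transfer to the full model only qualitatively, as
  the cross-variant tests document.
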