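---
title: "Modelling synaptic tagging and capture in a dendritic compartment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling synaptic tagging and capture in a dendritic compartment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcsim)
```

## The phenomenon

Early long-term potentiation (e-LTP) of a synapse decays within about
three hours unless the synapse converts to late LTP (l-LTP), which
requires newly synthesised plasticity-related proteins (PRPs). Synaptic
tagging and capture (STC) explains how that conversion can happen without
each synapse synthesising its own proteins: a stimulated spine sets a
*tag*, PRPs synthesised in the nearby dendrite diffuse in a shared pool,
and tagged spines capture them. A weakly stimulated synapse can therefore
be rescued by a strong protocol at a neighbour — *late-associativity* —
provided the two stimulations fall within a temporal window. Because many
spines draw on one finite pool, capture is competitive, and the outcome
depends on how many spines compete, when each is stimulated, and how much
PRP is present at rest.

`stcsim` implements a deterministic kinetic model of this system in a
10-µm dendritic compartment carrying up to 20 spines (2 spines/µm).

## State variables and equations

Each spine $n$ carries five variables; the compartment adds three shared
ones:

| symbol | meaning | units |
|---|---|---|
| $U_s^{[n]}$ | stimulus-driven Ca²⁺-cascade activity | – (0–1) |
| $T_p^{[n]}$ | synaptic tag intensity | – (0–1) |
| $P_s^{[n]}$ | PRPs captured by the spine | scaled conc. |
| $Z^{[n]}$ | plasticity state (bistable; l-LTP when $Z = W$) | µm³ |
| $W^{[n]}$ | spine head volume | µm³ |
| $U_d$ | PRP-synthesis-cascade activity (shared) | – (0–1) |
| $M_d$ | mRNA available for PRP synthesis (shared) | scaled conc. |
| $P_d$ | dendritic PRP pool (shared) | scaled conc. |

All nonlinear steps use the Hill function
$\Theta[x, K, h] = x^h / (x^h + K^h)$. With $Y^{[n]}(t) \in \{0, 1\}$ the
stimulus and $\alpha_{Ud}(t)$ the drug-dependent gain, the dynamics are

$$\dot U_s^{[n]} = k_{Us} W^{[n]} Y^{[n]} (1 - U_s^{[n]}) - \beta_{Us} U_s^{[n]}$$
$$\dot U_d = k_{Ud}\,\Theta\!\Big[\textstyle\sum_n \alpha_{Ud} \beta_{Us} U_s^{[n]}, K_{Ud}, h_{Ud}\Big](1 - U_d) - \beta_{Ud} U_d$$
$$\dot M_d = -\frac{M_d - \mu_{Md}}{\tau_{Md}} - k_{Pd}\,\Theta[U_d, K_{Pd}, h_{Pd}]\, M_d$$
$$\dot P_d = -\frac{P_d - \mu_{Pd}}{\tau_{Pd}} + k_{Pd}\,\Theta[U_d, K_{Pd}, h_{Pd}]\, M_d - \sum_n k_{Ps}\,\Theta[P_d T_p^{[n]}, K_{Ps}, h_{Ps}] + \sum_n \beta_{Ps} P_s^{[n]}$$
$$\dot T_p^{[n]} = k_{TP} W^{[n]}\,\Theta[U_s^{[n]}, K_{TP}, h_{TP}]\,(1 - T_p^{[n]}) - \frac{T_p^{[n]} - \mu_{TP}}{\tau_{TP}}$$
$$\dot P_s^{[n]} = k_{Ps}\,\Theta[P_d T_p^{[n]}, K_{Ps}, h_{Ps}] - \beta_{Ps} P_s^{[n]} - k_Z\,\Theta[P_s^{[n]}, K_Z, h_Z]\,(W^{[n]} - Z^{[n]})$$
$$\dot Z^{[n]} = k_Z\,\Theta[P_s^{[n]}, K_Z, h_Z]\,(W^{[n]} - Z^{[n]})$$
$$\dot W^{[n]} = k_W\,\Theta[U_s^{[n]}, K_W, h_W]\,(1 + U_d) - \frac{W^{[n]}(W^{[n]} - Z^{[n]})}{\tau_W}$$

The structure encodes the biology directly: tags are set by the calcium
cascade in proportion to spine size; capture needs the *product* of pool
level and tag; captured PRPs are consumed to advance the plasticity state
$Z$ toward the transiently expanded volume $W$; and $W$ relaxes back to
$Z$, so a spine keeps its expansion only if $Z$ caught up — $W = Z$ is the
stable l-LTP configuration, and $W \ge Z$ holds along every trajectory.

`stc_params()` returns the standard values of every constant; each can be
overridden by name. Two deserve comment:

* `mu_Pd` (basal PRP level, standard $10^{-3}$) is the biological
  "hyperparameter" of the model: raising it emulates protein-rich slices
  in which l-LTP no longer needs fresh synthesis.
* `tau_TP` is $2.0 \times 10^4$ s. An hours-long tag lifetime is what
  makes the *left* side of the STC window (weak before strong) wide; a
  sub-second value would abolish it.
* `k_W` is interpreted as µm³ s⁻¹ so that the volume equation is
  dimensionally consistent.

## Stimulation protocols

Both protocols deliver 30 glutamate-uncaging pulses of 5 ms at 0.5 Hz
(`make_eltp_protocol()`), i.e. a 58.005-s train of unit-amplitude
rectangular pulses. The l-LTP protocol (`make_lltp_protocol()`) adds the
bath-applied PKA/D1R agonists (forskolin / SKF38393), modelled as a
multiplication of $\alpha_{Ud}$ by `lltp_gain = 100` during a drug
window. The window's duration is not part of the published protocol
description; we take it to span the pulse train by default (configurable
via `drug_duration_s`), on the grounds that the agonists act together
with the stimulation and that the slow decay of $U_d$
($\beta_{Ud} = 10^{-3}$ s⁻¹) carries the effect forward for tens of
minutes regardless.

`make_schedule()` assembles multi-spine experiments. Asynchronous onsets
recede from $t = 0$ (e.g. $s_{E1} = -10$, $ds_E = 5$ gives $-10, -15,
-20$ min): this is forced by the labelling convention that E1 is always
the E-spine stimulated closest to the strong protocol.

## Numerics

The right-hand side is smooth *between* pulse and drug-window edges, so
the integrator (`stc_integrate()`) advances segment by segment with LSODA
(via **deSolve**, RHS compiled in C), placing a mandatory breakpoint at
every edge. During a pulse the calcium cascade relaxes at
$k_{Us} W \approx 100$ s⁻¹, so silently stepping across a 5-ms pulse
would corrupt $U_s$; the breakpoints make that impossible. Defaults are
`rtol = 1e-8`, `atol = 1e-10`, output every 10 s plus a sample at every
spine's readout time.

Simulations start from the closed-form resting state
(`steady_state_baseline()`): with $Y \equiv 0$, capture and efflux cancel
exactly once $P_s$ sits at its conditional equilibrium, giving
$P_d = \mu_{Pd}$, $P_s = (k_{Ps}/\beta_{Ps})\,\Theta[\mu_{Pd}\mu_{TP},
K_{Ps}, h_{Ps}]$, $U_s = U_d = 0$, $M_d = \mu_{Md}$, $T_p = \mu_{TP}$ and
$W = Z = 0.10$ µm³. The constructor verifies stationarity against the
right-hand side, and the test suite additionally confirms that the state
drifts by less than $10^{-6}$ over $10^4$ s of free evolution. Starting
from this fixed point keeps the pre-stimulus trajectory flat, so the
180-min volume readout is free of initialisation transients.

Two independent implementations guard the production path: a pure-R
right-hand side (`stc_rhs()`) checked term by term against the compiled C
version on random states, and a brute-force fixed-step RK4 integrator
(`stc_integrate_rk4()`, $10^{-4}$ s during pulses, $10^{-2}$ s
elsewhere) that must agree with the adaptive path to $10^{-5}$ relative
on a 10-min single-spine run.

## The simulation experiments

**Readout.** Every outcome is `readout_W180()`: the spine head volume
exactly 180 min after *that spine's own* protocol onset (onset, not
offset, of the train; the 58-s difference is negligible at 180 min but
fixed for determinism). A value of 0.10 µm³ means the spine returned to
baseline (e-LTP failed to convert); anything above means
late-associativity worked.

**Temporal window** (`stc_window_sweep()`): l-LTP at L1 fixed at $t = 0$,
e-LTP at E1 swept over $s_{E1} \in [-180, 180]$ min. The default grid
step is 10 min — the resolution at which window widths of order 100 min
are meaningfully read — and `window_width()` reports the extent of the
maximal contiguous run of effective cells on one side of zero. A cell is
effective when $W_{180}(\mathrm{E1}) > W_0 + \varepsilon$ with
$\varepsilon = 0.005$ µm³. The threshold must exceed the $\approx 0.003$
µm³ residue that a lone e-LTP spine still carries at 180 min (the volume
decay is asymptotic), which is why substantially smaller $\varepsilon$
values degenerate the measure; the width is therefore reported at the
stated $\varepsilon$ rather than claimed threshold-free. The window is
asymmetric because its two sides are controlled by different time
constants: the left side by the hours-long tag lifetime, the right side
by the much shorter persistence of the synthesised PRP pool. The measured
widths for the standard parameter set are computed by
`scripts/acceptance.R`, not quoted here.

**Experiment I** (`experiment_I()`): synchronized e-LTP at E1…En plus
l-LTP at L1, over grids of $n_E$, $\mu_{Pd}$ and $s_{E1}$. Synchronously
driven spines are dynamically identical (the integrator reproduces this
symmetry to $10^{-10}$), so E1 represents the group.

**Experiment II** (`experiment_II()`): asynchronous e-LTP with equal
interval $ds_E$, onsets receding from zero. Summaries per basal-PRP
level: intragroup mean, intragroup standard deviation
$S_g = \sqrt{N^{-1}\sum_n (W_{180}^{[n]} - \bar W_{180})^2}$ (population
divisor), and an enhancement-type label. The published grid is
$\mu_{Pd} = 10^{-4} \ldots 10^{0}$ in steps of 0.2 in the exponent
(21 levels) with $ds_E \in \{1, 5, 10\}$ min.

**Type classification** (`classify_type()`). The four enhancement
tendencies are defined visually in the literature; the operational
classifier here is the package's own: flat (IV) when the volume range is
below `flat_tol = 0.05` of the group mean; otherwise monotone decreasing
(I), monotone increasing (III), or single-interior-minimum convex (II),
judged on a 3-point moving average with slack `trend_tol = 0.02` of the
mean to absorb single-cell jitter. It is validated against the ordering
property — scanning $\mu_{Pd}$ upward yields I → II → III → IV in the
left window and no III in the right window — rather than against per-cell
labels.

## Problem sizes

The bundled tests and the acceptance script use: the full 37-cell window
sweep (two spines each), the 21-level $\mu_{Pd}$ scans of Experiment II
at $n_E = 5$, $ds_E = 5$ for both windows (42 six-spine runs), and small
monotonicity grids ($n_E \in \{1, 5, 10\}$, $\mu_{Pd} \in \{10^{-3},
10^{-2}, 10^{-1}\}$). These sizes exercise every regime the model
distinguishes while keeping a complete run in the order of minutes on a
single CPU; all grids are arguments, so larger sweeps (e.g.
$n_E = 15$, all three $ds_E$ values) are one call away.

## What the model does and does not capture

The model is phenomenological: cascades, tags and PRPs are single scaled
variables, not molecular species. Within that scope it reproduces e-LTP
decay, l-LTP consolidation, conversion under high basal PRP levels,
late-associativity and its asymmetric temporal window, and the
competition phenomenology of Experiments I–II. It deliberately omits:
LTD and cross-tagging, AMPA-receptor trafficking, spatial nonuniformity
of PRPs within (or beyond) the compartment, stochastic channel or release
noise, and any mechanism of l-LTP *maintenance* beyond the absorbing
$W = Z$ state — consolidated volumes do not decay within the simulated
horizon, so conclusions are limited to the induction timescale (hours).
All trajectories are deterministic; there is no randomness anywhere in
the model, which is why repeated runs are byte-identical.
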