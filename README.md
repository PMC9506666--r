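# stcsim — synaptic tagging and capture in a dendritic compartment

`stcsim` is an R package for simulating **synaptic tagging and capture
(STC)** and **late-associativity**: the process by which a weakly
stimulated synapse, whose early LTP would otherwise decay within ~3 h,
is converted to long-lasting late LTP by capturing plasticity-related
proteins (PRPs) synthesised in response to a strong protocol at a
neighbouring synapse. It is aimed at computational neuroscientists
studying clustered plasticity — which synapses on a short stretch of
dendrite get integrated into a cluster, and why.

## The model

A 10-µm dendritic compartment carries up to 20 spines (2 spines/µm). Each
spine *n* has calcium-cascade activity $U_s^{[n]}$, tag intensity
$T_p^{[n]}$, captured PRPs $P_s^{[n]}$, a bistable plasticity state
$Z^{[n]}$ and a head volume $W^{[n]}$; the compartment shares a
PRP-synthesis cascade $U_d$, mRNA $M_d$ and a PRP pool $P_d$. Every
nonlinearity is a Hill function $\Theta[x,K,h] = x^h/(x^h + K^h)$. The
eight coupled ODEs (see `?stc_rhs` or the methods vignette,
`vignettes/stc-model.Rmd`) encode: pulse-driven cascade activation,
threshold-gated PRP synthesis from a finite mRNA store, tag setting in
proportion to spine size, capture proportional to
$\Theta[P_d T_p]$, consumption of captured PRPs to advance $Z$ toward
$W$, and relaxation of $W$ back to $Z$ — so $W = Z > W_0$ is the stable
l-LTP state and $W \geq Z$ always.

Stimulation protocols follow glutamate-uncaging experiments: 30 pulses of
5 ms at 0.5 Hz; the l-LTP variant adds bath-applied FSK/SKF agonists,
modelled as a ×100 gain on the synthesis-cascade input during the train.
The key biological dial is the basal PRP level `mu_Pd`: at its standard
value ($10^{-3}$) conversion needs de-novo synthesis; at 50× it does not.

Everything is deterministic — there is no randomness anywhere — so runs
are reproducible to the byte.

## Worked example: the classic two-pathway experiment

Weak (e-LTP) protocol at spine E1 thirty minutes *before* a strong
(l-LTP) protocol at spine L1:

```r
library(stcsim)

params <- stc_params(N = 2)                       # standard constants
sched  <- make_schedule(n_E = 1, s_E1_min = -30, lltp_at_min = 0)
sched
#> STC stimulation schedule: 2 spine(s)
#>   L1  lltp onset      0.0 min (30 pulses)
#>   E1  eltp onset    -30.0 min (30 pulses)
#>   drug window(s): [0.0, 58.0] s

traj <- stc_integrate(params, sched)
readout_W180(traj, "E1")   # 0.1372 um^3
readout_W180(traj, "L1")   # 0.2459 um^3
```

Both spines end above the 0.10 µm³ baseline 180 min after their own
stimulation: L1 consolidated (its volume settled near 0.25 µm³ with
$Z = W$), and E1 — which on its own would have relaxed back to ~0.103
µm³ — captured part of L1's PRPs and converted. Re-running with only the
e-LTP spine confirms the counterfactual:

```r
eltp <- stc_integrate(stc_params(N = 1), make_schedule(n_E = 1, s_E1_min = -30))
readout_W180(eltp, "E1")   # 0.1029 um^3 — back to baseline, no conversion
```

Higher-level drivers reproduce the full simulation experiments:
`stc_window_sweep()` / `window_width()` (the asymmetric STC temporal
window), `experiment_I()` (synchronized competition over spine count and
basal PRP level) and `experiment_II()` (asynchronous competition, with
intragroup statistics and Type I–IV enhancement-tendency classification
via `classify_type()`).

A command-line front end is installed with the package
(`exec/stcsim`; see `?run_cli`), e.g.

```sh
Rscript exec/stcsim window --step-min 10 --out-dir out/
Rscript exec/stcsim exp2 --n 15 --s-e1 -10 --ds 5 --out-dir out/
```

writing tidy CSV results plus a JSON metadata sidecar, atomically.

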