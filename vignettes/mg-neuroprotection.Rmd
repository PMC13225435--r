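---
title: "Methods: a conductance-based model of Mg2+ neuroprotection in retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mg2+ neuroprotection in RGCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcmg)
```

## The scientific problem

Retinal ganglion cells are exceptionally vulnerable to glutamate
excitotoxicity: sustained NMDA-receptor activation loads the soma with
Ca²⁺, which triggers degradative cascades and cell death. Because
extracellular Mg²⁺ blocks the NMDA receptor pore in a voltage-dependent
manner, raising Mg²⁺ is a candidate neuroprotective intervention — but the
block also removes the NMDA contribution to synaptic drive, so too much
Mg²⁺ silences the cell. `rgcmg` implements a single-compartment
biophysical model built to quantify that trade-off: for which Mg²⁺
concentrations, at which stimulation intensities, and at which intervention
times does Mg²⁺ protect without disabling?

## Model equations and assumptions

The cell is one isopotential compartment. This is an idealisation that the
compact dendritic arbor of an RGC makes defensible: somatic voltage is
taken as representative of the integrated synaptic response, and the Ca²⁺
pool is a whole-cell average. Dendritic Ca²⁺ microdomains, stochastic
channel gating, receptor desensitisation, glutamate clearance and network
feedback are all outside the model.

The membrane carries eight currents:

$$C_m \frac{dV}{dt} = -I_{Na} - I_{Kdr} - I_{KA} - I_{CaL} - I_{KCa}
  - I_{L} - I_{AMPA} - I_{NMDA}$$

* Transient Na⁺ ($g_{Na} m^3 h$), delayed-rectifier K⁺ ($g_{Kdr} n^4$) and
  A-type K⁺ ($g_{KA} a^3 b$) generate and pace spikes.
* A high-threshold L-type Ca²⁺ current ($g_{CaL} s^2$) admits Ca²⁺ during
  spikes.
* A Ca²⁺-activated K⁺ current with Hill-type activation
  $\mathrm{Ca}^2/(\mathrm{Ca}^2 + K_d^2)$, $K_d = 0.5\ \mu M$, couples the
  Ca²⁺ load back onto excitability — it is the main activity brake at high
  calcium.
* AMPA and NMDA receptor currents driven by the glutamate pulse train, with
  the NMDA conductance multiplied by the Jahr–Stevens block factor
  $B(V,[\mathrm{Mg}^{2+}]) = 1/(1 + \eta[\mathrm{Mg}^{2+}]e^{-\gamma V})$,
  $\eta = 0.28\ \mathrm{mM}^{-1}$, $\gamma = 0.062\ \mathrm{mV}^{-1}$.

Receptor gates follow
$ds/dt = \frac{[Glu]}{[Glu]+EC_{50}}\frac{1-s}{\tau_{rise}} -
\frac{s}{\tau_{decay}}$ with fast AMPA kinetics (0.3/3 ms, $EC_{50}$ =
0.5 mM) and slow, high-affinity NMDA kinetics (5/80 ms, $EC_{50}$ = 2 µM —
stored internally as 0.002 mM; all glutamate concentrations are in mM).
At cleft glutamate (1 mM) the NMDA activation term is ≈ 0.998, i.e.
saturated, so NMDA drive is governed by its slow time constants and the
Mg²⁺ block, while AMPA (activation 2/3) tracks individual pulses.

Intracellular Ca²⁺ is one well-mixed pool:

$$\frac{d[\mathrm{Ca}^{2+}]_i}{dt} = -k_{Ca,NMDA} f_{Ca} I_{NMDA}
  - k_{Ca,CaL} I_{CaL} - \frac{[\mathrm{Ca}^{2+}]_i -
  [\mathrm{Ca}^{2+}]_{rest}}{\tau_{Ca}}$$

with $f_{Ca} = 0.15$, $k_{Ca,NMDA} = 0.012$, $k_{Ca,CaL} = 0.003$,
rest 0.05 µM and τ = 200 ms. The scaling factors absorb the conversion from
current density (µA/cm²) to concentration rate (µM/ms) for the
single-compartment geometry; no further geometric conversion is applied.
All defaults are exposed through `rgc_params()` and validated (conductances
non-negative, time constants positive, $0 \le f_{Ca} \le 1$).

## Gating kinetics and their calibration

The rate functions of the six intrinsic gates are the genuinely open part
of this model family: the conductances and reversal potentials are fixed
numbers, but published kinetics come in several variants. `rgcmg` uses:

* **m, h, n** — the classical squid-axon rate equations expressed at a
  resting potential of −65 mV.
* **a, b** — the Connor–Stevens A-current (Dayan–Abbott parameterisation).
* **s (L-type)** — a Boltzmann activation with slope 7 mV and first-order
  kinetics, consistent with high-threshold L-type channels.

Four under-determined elements of this set were calibrated, once, against
the model's stated operating points, and then frozen:

1. **A-current inactivation midpoint, −63 mV** (canonical −53.3 mV). The
   A-current is the spike-latency control of this cell. At its canonical
   position it is strong enough at rest to pull the resting potential to
   ≈ −68 mV and to halve spike output under fast drive; fully inactivated
   it contributes nothing. The midpoint was placed so that the A-current
   shapes the latency of spikes under high-frequency drive while the
   complete current balance rests at the stated $V_{rest} = -65$ mV.
2. **Delayed-rectifier voltage offset, +1.1 mV**, the residual degree of
   freedom used to zero the net membrane current at exactly −65 mV given
   choice 1 (the resting n⁴ is what balances the leak).
3. **Na-activation voltage offset, +0.17 mV.** Under 80 Hz drive the cell
   fails spikes by phase slipping: each cycle the spike latency grows until
   one pulse is skipped. The locking ratio (e.g. 4 spikes per 5 pulses) is
   extraordinarily sensitive to spike threshold — about 0.5 mM of Mg²⁺
   shift in the dose-response landscape per 0.3 mV — which is why this
   offset carries two decimals.
4. **L-type activation midpoint −5 mV and τ = 1.75 ms**, which set the
   Ca²⁺ charge admitted per spike and thereby the high-Mg²⁺ floor of the
   dose-response curve, where the NMDA contribution is largely blocked.

With these four constants fixed, the model reproduces its reference
behaviour — resting stability at −65 mV, the 80 Hz spike-loss plateau with
its therapeutic window, and the peak-Ca²⁺ dose-response anchors — without
touching any tabulated parameter. The calibration is deliberately exposed:
`default_kinetics()` returns all rate functions as plain R functions, and
`rgc_integrate(kinetics = ...)` integrates any alternative set through the
pure-R path (the compiled fast path implements the defaults; the test suite
pins the two against each other to machine precision).

## Stimulation protocols

Glutamate arrives as ideal rectangular pulses: amplitude 1 mM, width 2 ms,
pulse $k$ starting at $t_k = t_{start} + k/f$, emitted only if it ends by
the stimulation stop. Pulse onsets align with the integration grid. The
extracellular Mg²⁺ schedule is piecewise constant; an intervention is an
instantaneous concentration step (no diffusion or pharmacokinetics — the
question is *when*, not *how*, Mg²⁺ arrives).

Three experiment drivers wrap the integrator:

* `run_dose_response()` — frequencies {10, 30, 60, 80, 90, 100} Hz ×
  Mg²⁺ 0.2–2.5 mM in 0.1 mM steps (144 cells), 3 s per cell, metrics on the
  steady-state window 500–3000 ms. The first 500 ms are excluded everywhere
  so initialisation transients cannot touch any metric.
* `run_timing_experiment()` — 80 Hz stress from 0.5 to 4.5 s in a 6 s run;
  Mg²⁺ stepped from 0.2 to 1.8 mM at delays 0–3 s after stress onset, plus
  the two references: untreated (0.2 mM throughout) and pre-treated
  (1.8 mM from $t = 0$, i.e. before the stress starts). Peak Ca²⁺ is read
  on the stress window 500–4500 ms.
* `convergence_report()` — forward-Euler runs at decreasing steps against
  an RK4 reference at 5 µs.

## Analysis metrics

* **Spikes** are upward crossings of −20 mV; the spike time is the first
  supra-threshold sample, and the voltage must fall below threshold before
  a new spike can be counted (de-bounce; the threshold alone would
  double-count at dt = 0.02 ms). Spike probability divides the count by the
  expected pulses in the window (onset-based counting; 200 at 80 Hz over
  2.5 s), capped at 1 so occasional burst doublets do not produce negative
  loss. Spike loss is $100(1-p)$; the therapeutic criterion uses loss
  relative to the 0.2 mM baseline at the same frequency.
* **Peak Ca²⁺** is the window maximum of the simulated pool.
* **Therapeutic window**: the maximal contiguous Mg²⁺ range satisfying
  both peak Ca²⁺ < 1.0 µM (toxicity threshold) and baseline-relative spike
  loss ≤ 20 %. Boundaries are reported at grid resolution (0.1 mM), with no
  interpolation. `threshold_sensitivity()` re-runs the classification for
  toxicity thresholds 0.6–1.4 µM.
* **Protection efficacy** scores an intervention linearly between the
  untreated (0 %) and pre-treated (100 %) peak-Ca²⁺ references.
* **Ca²⁺ progress** re-expresses intervention timing as the fraction of
  the *untreated* run's peak Ca²⁺ accumulation reached at the moment of
  intervention — a treatment-independent phase variable that transfers
  across timescales.
* **Mechanistic decompositions**: mean unblocked fraction ⟨B⟩ (time
  average of $B(V(t), \mathrm{Mg}(t))$) and integrated NMDA charge
  $Q_{NMDA} = \int |I_{NMDA}|\,dt$, both on the analysis window.

## Numerical choices

* **Forward Euler at dt = 0.02 ms** is the primary method; RK4 is the
  validation method. At dt = 0.02 ms the two agree on peak Ca²⁺ to well
  under 0.2 %, and the convergence report shows the expected first-order
  error decay against the 5 µs RK4 reference.
* **Stability limit**: the fast Na activation gate makes explicit Euler
  marginally unstable at dt ≥ 0.1 ms. Rather than silently clamping, any
  gating excursion beyond [0, 1] by more than 10⁻⁶ aborts with the variable
  name and time; excursions below that tolerance (harmless round-off) are
  clamped. The convergence report therefore uses 0.05/0.02/0.01 ms.
* **Blow-up guards**: |V| > 200 mV, Ca > 1000 µM or any non-finite state
  aborts with a diagnostic naming the first bad variable and the time.
* **Initial conditions**: gating variables at their steady states at
  $V_{rest}$, synaptic gates closed, Ca²⁺ at rest. Because the kinetics
  are calibrated to balance at −65 mV this is already a fixed point; an
  unstimulated 3 s run stays within a fraction of a millivolt of rest (the
  analysis windows exclude the first 500 ms regardless).
* **Determinism**: there is no randomness anywhere; repeated runs are
  bit-identical, and the test suite asserts this end to end.
* **Stimulus evaluation**: at the step start for Euler and at each stage
  time for RK4; rectangular pulses make both well defined. A 10⁻⁹ ms guard
  on pulse-edge comparisons keeps edge samples stable against floating-point
  drift in $t = i\,dt$.

## Problem sizes

The test suite runs the full 144-cell dose-response grid (3 s per cell),
the complete 13-run timing protocol (6 s per run) and the convergence
scan; with the compiled core the whole suite completes in well under a
minute, and `scripts/acceptance.R` in a few seconds. These are the same
problem sizes the analyses are defined on — nothing is scaled down.

## Known limitations

* The four calibrated kinetics constants are a model choice, not a
  measurement; other rate-function variants can reproduce the same
  operating points with different offsets. The phase-slip locking that
  produces the spike-loss plateau is knife-edge sensitive to them, which is
  faithful to how such mode-locked systems behave but means small kinetic
  changes move window boundaries by whole grid cells. The 10 Hz window
  lower bound, for instance, sits one 0.1 mM cell below the nominal value
  while the 80 Hz window is exact.
* Periodic deterministic pulse trains are a proxy for pathological
  glutamate exposure; irregular (Poisson-like) input, desensitisation and
  glial uptake would all smear the locking structure.
* The single Ca²⁺ pool has one clearance time constant; real somata have
  buffered, compartmentalised calcium with multiple timescales. The 1.0 µM
  toxicity threshold is a classification criterion, not a mechanism — no
  downstream death pathway is modelled.
* Abrupt stress onset makes the intervention-timing results seconds-scale;
  the Ca²⁺-progress reanalysis is the transferable statement, and mapping
  it to clinical timescales requires the (slower) in-vivo Ca²⁺ accumulation
  dynamics, which are outside the model.
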